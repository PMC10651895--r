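#' Piecewise-constant (nearest-knot) interpolation
#'
#' The simplest baseline: the interpolant takes the value of the nearest
#' knot. Distance ties at interval midpoints resolve to the earlier knot.
#'
#' @param series List with strictly increasing `t` and values `y` of equal
#'   length (>= 2).
#' @param t_query Query points within `[min(t), max(t)]`.
#' @return Interpolated values at `t_query`.
#' @export
pci_interpolate <- function(series, t_query) {
  check_series(series)
  check_range(series$t, t_query)
  idx <- vapply(t_query, function(tq) which.min(abs(series$t - tq)), 1L)
  series$y[idx]
}

#' Linear interpolation between bracketing knots
#'
#' @inheritParams pci_interpolate
#' @return Interpolated values at `t_query`.
#' @export
li_interpolate <- function(series, t_query) {
  check_series(series)
  check_range(series$t, t_query)
  stats::approx(series$t, series$y, xout = t_query)$y
}

check_series <- function(series) {
  if (!is.list(series) || is.null(series$t) || is.null(series$y)) {
    stop_arg("`series` must be a list with fields `t` and `y`")
  }
  if (length(series$t) != length(series$y) || length(series$t) < 2) {
    stop_arg("`t` and `y` must have equal length >= 2")
  }
  if (any(diff(series$t) <= 0)) stop_arg("`t` must be strictly increasing")
  invisible(series)
}

check_range <- function(t, t_query) {
  eps <- 1e-9 * max(1, diff(range(t)))
  if (any(t_query < min(t) - eps | t_query > max(t) + eps)) {
    stop_arg("query outside the knot range (no extrapolation)")
  }
}

# Solve the tridiagonal system with constant diagonals (1, 4, 1) for the
# interior second derivatives of a natural cubic spline on a uniform grid.
# rhs may be a matrix: one system per column, solved simultaneously
# (Thomas algorithm with vectorized sweeps).
solve_tridiag_141 <- function(rhs) {
  rhs <- as.matrix(rhs)
  m <- nrow(rhs)
  if (m == 1) return(rhs / 4)
  cp <- numeric(m)
  cp[1] <- 1 / 4
  for (i in 2:m) cp[i] <- 1 / (4 - cp[i - 1])
  d <- rhs
  d[1, ] <- d[1, ] / 4
  for (i in 2:m) d[i, ] <- (d[i, ] - d[i - 1, ]) * cp[i]
  x <- d
  for (i in (m - 1):1) x[i, ] <- d[i, ] - cp[i] * x[i + 1, ]
  x
}

# Vectorized spline fit for many series sharing one uniform knot axis:
# y is a (n_knots x n_series) matrix; returns M (same shape).
spline_second_derivs <- function(y, q) {
  y <- as.matrix(y)
  n <- nrow(y)
  M <- matrix(0, n, ncol(y))
  if (n >= 3) {
    rhs <- 6 * (y[3:n, , drop = FALSE] - 2 * y[2:(n - 1), , drop = FALSE] +
                  y[1:(n - 2), , drop = FALSE]) / q^2
    M[2:(n - 1), ] <- solve_tridiag_141(rhs)
  }
  M
}

#' Fit a natural cubic spline on uniformly spaced knots
#'
#' Solves the C2-continuity conditions for the knot second derivatives
#' `M_i` (natural ends `M_0 = M_n = 0`) and forms the per-interval closed
#' forms `A_i = (M_{i+1} - M_i)/(6q)`, `B_i = M_i/2`,
#' `C_i = (y_{i+1} - y_i)/q - ((M_{i+1} + 2 M_i)/6) q`, `D_i = y_i`, so that
#' on interval `i` the spline is
#' `f_i(x) = A_i (x - x_i)^3 + B_i (x - x_i)^2 + C_i (x - x_i) + D_i`.
#'
#' @param series List with uniformly spaced strictly increasing `t` (>= 3
#'   knots; spacing checked to 1e-9 relative tolerance) and values `y`.
#' @return A `cubic_spline` object with fields `knots` (data.frame `x`,
#'   `y`), `q`, `M`, and `coeffs` (data.frame `A`, `B`, `C`, `D`).
#' @export
fit_cubic_spline <- function(series) {
  check_series(series)
  x <- series$t; y <- series$y
  n <- length(x)
  if (n < 3) stop_arg("need at least 3 knots")
  q <- (x[n] - x[1]) / (n - 1)
  if (max(abs(diff(x) - q)) > 1e-9 * max(abs(q), 1)) {
    stop_arg("knots must be uniformly spaced (the closed forms assume one spacing q)")
  }
  M <- drop(spline_second_derivs(matrix(y, ncol = 1), q))
  i <- seq_len(n - 1)
  coeffs <- data.frame(
    A = (M[i + 1] - M[i]) / (6 * q),
    B = M[i] / 2,
    C = (y[i + 1] - y[i]) / q - ((M[i + 1] + 2 * M[i]) / 6) * q,
    D = y[i]
  )
  structure(
    list(knots = data.frame(x = x, y = y), q = q, M = M, coeffs = coeffs),
    class = "cubic_spline"
  )
}

#' Evaluate a fitted cubic spline
#'
#' Piecewise-cubic evaluation within the knot range; no extrapolation.
#'
#' @param spline A `cubic_spline` from [fit_cubic_spline()].
#' @param t_query Query points inside the knot range.
#' @return Spline values at `t_query`.
#' @export
eval_spline <- function(spline, t_query) {
  stopifnot(inherits(spline, "cubic_spline"))
  x <- spline$knots$x
  check_range(x, t_query)
  n <- length(x)
  i <- pmin(pmax(floor((t_query - x[1]) / spline$q) + 1, 1), n - 1)
  u <- t_query - x[i]
  cf <- spline$coeffs
  ((cf$A[i] * u + cf$B[i]) * u + cf$C[i]) * u + cf$D[i]
}

#' Grid upsampling configuration
#'
#' @param freq_factor,time_factor Integer upsampling factors (>= 1) along
#'   the frequency (row) and time (column) axes.
#' @param method `"csi"` (cubic spline), `"li"` (linear), or `"pci"`
#'   (nearest knot).
#' @return A `grid_upsample_config` list.
#' @export
grid_upsample_config <- function(freq_factor = 2, time_factor = 2,
                                 method = c("csi", "li", "pci")) {
  method <- match.arg(method)
  if (!is_count(freq_factor) || !is_count(time_factor)) {
    stop_arg("upsampling factors must be integers >= 1")
  }
  structure(list(freq_factor = as.integer(freq_factor),
                 time_factor = as.integer(time_factor), method = method),
            class = "grid_upsample_config")
}

# Upsample the rows of a matrix by an integer factor with one of the three
# interpolation methods. Knots stay at their original values.
upsample_rows <- function(vals, factor, method) {
  n <- nrow(vals)
  if (factor == 1) return(vals)
  n_out <- (n - 1) * factor + 1
  out <- matrix(0, n_out, ncol(vals))
  out[seq(1, n_out, by = factor), ] <- vals
  fracs <- seq_len(factor - 1) / factor
  if (method == "csi") {
    M <- spline_second_derivs(vals, 1)       # unit spacing along the index axis
    i <- seq_len(n - 1)
    A <- (M[i + 1, , drop = FALSE] - M[i, , drop = FALSE]) / 6
    B <- M[i, , drop = FALSE] / 2
    Cc <- (vals[i + 1, , drop = FALSE] - vals[i, , drop = FALSE]) -
      (M[i + 1, , drop = FALSE] + 2 * M[i, , drop = FALSE]) / 6
    D <- vals[i, , drop = FALSE]
    for (k in seq_along(fracs)) {
      u <- fracs[k]
      out[seq(1 + k, n_out, by = factor)[seq_len(n - 1)], ] <-
        ((A * u + B) * u + Cc) * u + D
    }
  } else if (method == "li") {
    i <- seq_len(n - 1)
    for (k in seq_along(fracs)) {
      u <- fracs[k]
      out[seq(1 + k, n_out, by = factor)[seq_len(n - 1)], ] <-
        (1 - u) * vals[i, , drop = FALSE] + u * vals[i + 1, , drop = FALSE]
    }
  } else { # pci: nearest knot, midpoint ties to the earlier knot
    i <- seq_len(n - 1)
    for (k in seq_along(fracs)) {
      u <- fracs[k]
      src <- if (u <= 0.5) i else i + 1
      out[seq(1 + k, n_out, by = factor)[seq_len(n - 1)], ] <-
        vals[src, , drop = FALSE]
    }
  }
  out
}

upsample_coords <- function(coords, factor) {
  if (factor == 1) return(coords)
  n <- length(coords)
  q <- (coords[n] - coords[1]) / (n - 1)
  seq(coords[1], coords[n], by = q / factor)
}

#' Upsample a spectrogram grid by separable per-axis interpolation
#'
#' Interpolates along the frequency axis first and then the time axis
#' (separable passes commute for exact spline surfaces on uniform grids).
#' For `method = "csi"`, negative spline overshoot is clipped to 0 so the
#' output remains a magnitude grid; original grid values are preserved at
#' their positions.
#'
#' @param grid A `spectrogram_grid` of size at least 3 x 3 with uniform axis
#'   spacing.
#' @param cfg A [grid_upsample_config()].
#' @return A `spectrogram_grid` with `(rows-1)*freq_factor + 1` rows and
#'   `(cols-1)*time_factor + 1` columns.
#' @export
csi_upsample_grid <- function(grid, cfg = grid_upsample_config()) {
  stopifnot(inherits(grid, "spectrogram_grid"))
  if (nrow(grid$values) < 3 || ncol(grid$values) < 3) {
    stop_arg("grid must be at least 3 x 3")
  }
  vals <- upsample_rows(grid$values, cfg$freq_factor, cfg$method)
  vals <- t(upsample_rows(t(vals), cfg$time_factor, cfg$method))
  if (cfg$method == "csi") vals <- pmax(vals, 0)
  spectrogram_grid(vals,
                   row_coords = upsample_coords(grid$row_coords, cfg$freq_factor),
                   col_coords = upsample_coords(grid$col_coords, cfg$time_factor),
                   kind = grid$kind)
}

#' STFT spectrogram with cubic-spline upsampling (STFT-CSI)
#'
#' The pipeline's interpolated spectrogram: the STFT magnitude grid passed
#' through [csi_upsample_grid()].
#'
#' @param record An [audio_record()].
#' @param stft_cfg An [stft_config()].
#' @param up_cfg A [grid_upsample_config()].
#' @return A `spectrogram_grid` of kind `"stft"`.
#' @export
stft_csi <- function(record, stft_cfg = stft_config(),
                     up_cfg = grid_upsample_config()) {
  csi_upsample_grid(stft_spectrogram(record, stft_cfg), up_cfg)
}
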