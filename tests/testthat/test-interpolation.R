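test_that("PCI returns the nearest knot with midpoint ties to the earlier knot", {
  ser <- list(t = c(0, 1, 2, 3), y = c(10, 20, 30, 40))
  expect_equal(pci_interpolate(ser, c(0, 0.4, 0.6, 2.9)), c(10, 10, 20, 40))
  expect_equal(pci_interpolate(ser, 0.5), 10)   # tie -> earlier knot
  expect_equal(pci_interpolate(ser, ser$t), ser$y)
})

test_that("LI is exact on straight lines and exact at knots", {
  ser <- list(t = 0:5, y = 3 * (0:5) - 1)
  tq <- seq(0, 5, by = 0.1)
  expect_equal(li_interpolate(ser, tq), 3 * tq - 1, tolerance = 1e-12)
  ser2 <- list(t = c(0, 2, 5), y = c(1, -4, 7))
  expect_equal(li_interpolate(ser2, ser2$t), ser2$y)
})

test_that("interpolators reject out-of-range queries and malformed series", {
  ser <- list(t = 0:3, y = rnorm(4))
  expect_error(pci_interpolate(ser, -0.1), "range|within")
  expect_error(li_interpolate(ser, 3.5), "range|within")
  expect_error(pci_interpolate(list(t = c(0, 0, 1), y = 1:3), 0.5),
               "increasing")
  expect_error(li_interpolate(list(t = 1, y = 1), 1), "length")
})

test_that("cubic spline matches an independent natural-spline oracle", {
  set.seed(6)
  for (rep in 1:5) {
    n <- sample(5:12, 1)
    ser <- list(t = seq(0, 10, length.out = n), y = rnorm(n))
    spl <- fit_cubic_spline(ser)
    tq <- seq(0, 10, length.out = 101)
    got <- eval_spline(spl, tq)
    ref <- stats::spline(ser$t, ser$y, xout = tq, method = "natural")$y
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("spline coefficients satisfy the closed forms of the derivation", {
  ser <- make_case_a_series()
  spl <- fit_cubic_spline(ser)
  q <- diff(ser$t)[1]
  M <- cetaclass:::spline_second_derivs(ser$y, q)
  n <- length(ser$t) - 1
  expect_equal(M[1], 0)              # natural end conditions
  expect_equal(M[n + 1], 0)
  for (i in seq_len(n)) {
    expect_equal(spl$coeffs$A[i], (M[i + 1] - M[i]) / (6 * q))
    expect_equal(spl$coeffs$B[i], M[i] / 2)
    expect_equal(spl$coeffs$C[i],
                 (ser$y[i + 1] - ser$y[i]) / q - ((M[i + 1] + 2 * M[i]) / 6) * q)
    expect_equal(spl$coeffs$D[i], ser$y[i])
  }
})

test_that("the fitted spline is C0/C1/C2-continuous at interior knots", {
  ser <- list(t = seq(0, 9, by = 1), y = sin(2 * seq(0, 9, by = 1)))
  spl <- fit_cubic_spline(ser)
  h <- 1e-6
  for (k in ser$t[c(-1, -length(ser$t))]) {
    f <- function(t) eval_spline(spl, t)
    expect_equal(f(k - h), f(k + h), tolerance = 1e-4)
    d_l <- (f(k) - f(k - h)) / h
    d_r <- (f(k + h) - f(k)) / h
    expect_equal(d_l, d_r, tolerance = 1e-3)
    dd_l <- (f(k) - 2 * f(k - h) + f(k - 2 * h)) / h^2
    dd_r <- (f(k + 2 * h) - 2 * f(k + h) + f(k)) / h^2
    expect_equal(dd_l, dd_r, tolerance = 1e-2)
  }
})

test_that("tridiagonal (1,4,1) solver agrees with dense solve()", {
  set.seed(8)
  n <- 12
  A <- diag(4, n)
  A[cbind(2:n, 1:(n - 1))] <- 1
  A[cbind(1:(n - 1), 2:n)] <- 1
  B <- matrix(rnorm(n * 3), n, 3)
  expect_equal(cetaclass:::solve_tridiag_141(B), solve(A, B),
               tolerance = 1e-12)
})

test_that("spline fitting requires uniform spacing and enough knots", {
  expect_error(fit_cubic_spline(list(t = c(0, 1, 3), y = 1:3)), "uniform")
  expect_error(fit_cubic_spline(list(t = c(0, 1), y = 1:2)), "3|knots")
  expect_error(eval_spline(fit_cubic_spline(list(t = 0:3, y = rnorm(4))),
                           4.2), "range|within")
})

test_that("separable CSI grid upsampling doubles both axes and keeps knots", {
  set.seed(10)
  g <- cetaclass:::spectrogram_grid(matrix(abs(rnorm(48)), 6, 8),
                                    row_coords = seq(0, 500, length.out = 6),
                                    col_coords = seq(0, 7, length.out = 8),
                                    kind = "stft")
  up <- csi_upsample_grid(g, grid_upsample_config(2, 2, "csi"))
  expect_equal(dim(up$values), c(11, 15))
  expect_equal(up$values[seq(1, 11, by = 2), seq(1, 15, by = 2)], g$values)
  expect_true(all(up$values >= 0))
  # li and pci methods also preserve knots
  for (m in c("li", "pci")) {
    upm <- csi_upsample_grid(g, grid_upsample_config(2, 2, m))
    expect_equal(upm$values[seq(1, 11, by = 2), seq(1, 15, by = 2)], g$values)
  }
})

test_that("stft_csi composes STFT and CSI upsampling", {
  fs <- 8000
  tt <- (0:(fs - 1)) / fs
  rec <- audio_record(sin(2 * pi * 1000 * tt), fs)
  base <- stft_spectrogram(rec, stft_config())
  up <- stft_csi(rec, stft_config(), grid_upsample_config(2, 2, "csi"))
  expect_equal(nrow(up$values), 2 * nrow(base$values) - 1)
  expect_equal(ncol(up$values), 2 * ncol(base$values) - 1)
  expect_equal(up$values[seq(1, nrow(up$values), by = 2),
                         seq(1, ncol(up$values), by = 2)],
               base$values)
})

test_that("CSI upsampling is more accurate than LI and PCI on a smooth grid", {
  # A smooth 2-D field sampled coarsely; finer truth known analytically.
  f <- function(u, v) sin(u) * cos(0.5 * v) + 0.1 * u
  uc <- seq(0, 2 * pi, length.out = 9)
  vc <- seq(0, 2 * pi, length.out = 9)
  g <- cetaclass:::spectrogram_grid(outer(uc, vc, f) + 2,
                                    row_coords = uc, col_coords = vc,
                                    kind = "stft")
  uf <- seq(0, 2 * pi, length.out = 17)
  truth <- outer(uf, uf, f) + 2
  err <- vapply(c("csi", "li", "pci"), function(m) {
    up <- csi_upsample_grid(g, grid_upsample_config(2, 2, m))
    sqrt(mean((up$values - truth)^2))
  }, 0)
  expect_lt(err[["csi"]], err[["li"]])
  expect_lt(err[["li"]], err[["pci"]])
})
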