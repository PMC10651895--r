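# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

#' Run an expression under a fixed RNG seed
#'
#' Thin wrapper around [withr::with_seed()] so every stochastic operation in
#' the package is a pure function of its arguments plus one integer seed.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a per-item 31-bit seed from a master seed and item indices.
# Deterministic and collision-unlikely at the dataset sizes used here.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 8191 + 1) %% 2147483647
  }
  as.integer(s)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

is_number <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)
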