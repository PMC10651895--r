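#' STFT configuration
#'
#' Defaults follow the spectrogram setup used throughout the pipeline: a
#' Hanning window, FFT size 256, and 75% overlap.
#'
#' @param window_kind Window name (currently `"hanning"`).
#' @param n_fft FFT size in samples (power of two, >= 16).
#' @param overlap_frac Fractional overlap in `[0, 1)`.
#' @return An `stft_config` list.
#' @export
stft_config <- function(window_kind = "hanning", n_fft = 256,
                        overlap_frac = 0.75) {
  window_kind <- match.arg(window_kind, "hanning")
  if (!is_count(n_fft) || n_fft < 16 || bitwAnd(n_fft, n_fft - 1L) != 0) {
    stop_arg("`n_fft` must be a power of two >= 16")
  }
  if (!is_number(overlap_frac) || overlap_frac < 0 || overlap_frac >= 1) {
    stop_arg("`overlap_frac` must be in [0, 1)")
  }
  structure(list(window_kind = window_kind, n_fft = as.integer(n_fft),
                 overlap_frac = overlap_frac),
            class = "stft_config")
}

#' Mel spectrogram configuration
#'
#' Defaults: 1024-sample analysis window and 64 mel bands.
#'
#' @param n_fft Analysis window / FFT size in samples.
#' @param n_mels Number of mel bands (>= 2).
#' @param f_min,f_max Band edges in Hz; `f_max = NULL` means Nyquist.
#' @param overlap_frac Fractional frame overlap (default 0.75, matching the
#'   STFT stage).
#' @return A `mel_config` list.
#' @export
mel_config <- function(n_fft = 1024, n_mels = 64, f_min = 0, f_max = NULL,
                       overlap_frac = 0.75) {
  if (!is_count(n_mels) || n_mels < 2) stop_arg("`n_mels` must be >= 2")
  if (!is_count(n_fft)) stop_arg("`n_fft` must be a positive integer")
  structure(list(n_fft = as.integer(n_fft), n_mels = as.integer(n_mels),
                 f_min = f_min, f_max = f_max, overlap_frac = overlap_frac),
            class = "mel_config")
}

#' Haar CWT scalogram configuration
#'
#' @param wavelet Wavelet name (currently `"haar"`).
#' @param window_len Analysis window length in samples (default 512); also
#'   the largest admissible scale.
#' @param n_scales Number of scales (>= 2), log-spaced in
#'   `[scale_min, scale_max]`.
#' @param scale_min,scale_max Scale range in samples.
#' @param hop Frame hop in samples (default `window_len / 4`).
#' @return A `cwt_config` list.
#' @export
cwt_config <- function(wavelet = "haar", window_len = 512, n_scales = 128,
                       scale_min = 2, scale_max = NULL, hop = NULL) {
  wavelet <- match.arg(wavelet, "haar")
  if (is.null(scale_max)) scale_max <- window_len
  if (!is_count(n_scales) || n_scales < 2) stop_arg("`n_scales` must be >= 2")
  if (scale_min < 2) stop_arg("`scale_min` must be >= 2")
  if (scale_max > window_len) stop_arg("`scale_max` must be <= window_len")
  if (is.null(hop)) hop <- max(1L, window_len %/% 4)
  structure(list(wavelet = wavelet, window_len = as.integer(window_len),
                 n_scales = as.integer(n_scales), scale_min = scale_min,
                 scale_max = scale_max, hop = as.integer(hop)),
            class = "cwt_config")
}

# Common container for 2-D time-frequency magnitude grids.
spectrogram_grid <- function(values, row_coords, col_coords, kind) {
  stopifnot(is.matrix(values), nrow(values) == length(row_coords),
            ncol(values) == length(col_coords))
  if (any(values < 0)) stop_arg("grid values must be non-negative")
  structure(list(values = values, row_coords = row_coords,
                 col_coords = col_coords, kind = kind),
            class = "spectrogram_grid")
}

#' @export
print.spectrogram_grid <- function(x, ...) {
  cat(sprintf("<spectrogram_grid:%s> %d x %d (bins x frames)\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' One-sided FFT magnitude spectrum
#'
#' With `scaling = "amplitude"` the magnitudes are scaled by `2/N` (`1/N`
#' for the DC bin), so a pure sinusoid of amplitude `a` spanning an integer
#' number of periods yields a peak of magnitude `a`.
#'
#' @param record An [audio_record()].
#' @param scaling `"amplitude"` (2/N) or `"magnitude"` (raw `|FFT|`).
#' @return A `spectrum_series` list with `freqs`, `magnitudes`, `scaling`.
#' @export
fft_spectrum <- function(record, scaling = c("amplitude", "magnitude")) {
  stopifnot(inherits(record, "audio_record"))
  scaling <- match.arg(scaling)
  x <- record$samples
  n <- length(x)
  if (n == 0) stop_arg("empty record")
  mag <- Mod(fft(x))
  n_keep <- n %/% 2 + 1
  mag <- mag[seq_len(n_keep)]
  if (scaling == "amplitude") {
    mag <- mag * 2 / n
    mag[1] <- mag[1] / 2
    if (n %% 2 == 0) mag[n_keep] <- mag[n_keep] / 2
  }
  structure(list(freqs = (seq_len(n_keep) - 1) * record$sample_rate / n,
                 magnitudes = mag, scaling = scaling),
            class = "spectrum_series")
}

# Frame a signal into columns of length n_fft at the given hop.
frame_signal <- function(x, n_fft, hop) {
  n <- length(x)
  if (n < n_fft) stop_arg("record shorter than one analysis window")
  n_frames <- 1L + (n - n_fft) %/% hop
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(n_fft), starts, `+`)
  matrix(x[idx], nrow = n_fft)
}

#' STFT magnitude spectrogram
#'
#' Hanning-windowed short-time Fourier transform. The grid has
#' `n_fft/2 + 1` frequency rows; the hop is `n_fft * (1 - overlap_frac)`
#' and the frame count `1 + floor((N - n_fft)/hop)`.
#'
#' @param record An [audio_record()].
#' @param cfg An [stft_config()].
#' @return A `spectrogram_grid` of kind `"stft"` (magnitude, not power).
#' @export
stft_spectrogram <- function(record, cfg = stft_config()) {
  stopifnot(inherits(record, "audio_record"))
  hop <- as.integer(round(cfg$n_fft * (1 - cfg$overlap_frac)))
  hop <- max(hop, 1L)
  frames <- frame_signal(record$samples, cfg$n_fft, hop)
  win <- signal::hanning(cfg$n_fft)
  mag <- Mod(mvfft(frames * win))
  n_keep <- cfg$n_fft %/% 2 + 1L
  fs <- record$sample_rate
  starts <- (seq_len(ncol(frames)) - 1L) * hop
  spectrogram_grid(mag[seq_len(n_keep), , drop = FALSE],
                   row_coords = (seq_len(n_keep) - 1) * fs / cfg$n_fft,
                   col_coords = (starts + cfg$n_fft / 2) / fs,
                   kind = "stft")
}

#' The mel frequency scale
#'
#' `mel(f) = 2595 log10(1 + f/700)` and its inverse.
#'
#' @param f Frequency in Hz.
#' @param m Mel value.
#' @return Mel value(s) / Hz value(s).
#' @export
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)

#' @rdname hz_to_mel
#' @export
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank (n_mels x n_bins), rows area-normalized.
mel_filterbank <- function(n_fft, n_mels, f_min, f_max, sample_rate) {
  n_bins <- n_fft %/% 2 + 1
  bin_freqs <- (seq_len(n_bins) - 1) * sample_rate / n_fft
  edges <- mel_to_hz(seq(hz_to_mel(f_min), hz_to_mel(f_max),
                         length.out = n_mels + 2))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; ce <- edges[m + 1]; hi <- edges[m + 2]
    up <- (bin_freqs - lo) / max(ce - lo, 1e-12)
    down <- (hi - bin_freqs) / max(hi - ce, 1e-12)
    w <- pmax(0, pmin(up, down))
    s <- sum(w)
    if (s > 0) w <- w / s
    fb[m, ] <- w
  }
  list(weights = fb, centers = edges[2:(n_mels + 1)])
}

#' Mel spectrogram
#'
#' Frames the signal, computes the power spectrum per frame, and pools it
#' through a triangular, area-normalized filterbank built on the
#' `mel(f) = 2595 log10(1 + f/700)` scale.
#'
#' @param record An [audio_record()].
#' @param cfg A [mel_config()].
#' @return A `spectrogram_grid` of kind `"mel"` with `n_mels` rows;
#'   `row_coords` are the band center frequencies in Hz.
#' @export
mel_spectrogram <- function(record, cfg = mel_config()) {
  stopifnot(inherits(record, "audio_record"))
  fs <- record$sample_rate
  f_max <- cfg$f_max %||% (fs / 2)
  if (f_max > fs / 2 + 1e-9) stop_arg("`f_max` exceeds Nyquist")
  if (cfg$f_min >= f_max) stop_arg("need f_min < f_max")
  hop <- max(1L, as.integer(round(cfg$n_fft * (1 - cfg$overlap_frac))))
  frames <- frame_signal(record$samples, cfg$n_fft, hop)
  win <- signal::hanning(cfg$n_fft)
  pow <- Mod(mvfft(frames * win))^2
  n_keep <- cfg$n_fft %/% 2 + 1L
  fb <- mel_filterbank(cfg$n_fft, cfg$n_mels, cfg$f_min, f_max, fs)
  vals <- fb$weights %*% pow[seq_len(n_keep), , drop = FALSE]
  starts <- (seq_len(ncol(frames)) - 1L) * hop
  spectrogram_grid(vals, row_coords = fb$centers,
                   col_coords = (starts + cfg$n_fft / 2) / fs,
                   kind = "mel")
}

#' The Haar mother wavelet
#'
#' Piecewise constant: `1` on `[0, 1/2)`, `-1` on `[1/2, 1)`, `0` elsewhere.
#'
#' @param t Numeric vector.
#' @return `psi(t)` evaluated elementwise.
#' @export
haar_wavelet <- function(t) {
  out <- numeric(length(t))
  out[t >= 0 & t < 0.5] <- 1
  out[t >= 0.5 & t < 1] <- -1
  out
}

#' Haar CWT scalogram
#'
#' Discretizes the continuous wavelet transform with the Haar mother
#' wavelet as a finite rectangle-rule sum with `1/sqrt(lambda)`
#' normalization (`lambda` in samples), then squares the coefficients.
#' Because the Haar wavelet is a difference of two box averages, each
#' coefficient reduces to a cumulative-sum difference, which is what the
#' implementation computes.
#'
#' @param record An [audio_record()].
#' @param cfg A [cwt_config()].
#' @return A `spectrogram_grid` of kind `"scalogram"`; `row_coords` are the
#'   scales in samples, ascending.
#' @export
haar_cwt_scalogram <- function(record, cfg = cwt_config()) {
  stopifnot(inherits(record, "audio_record"))
  x <- record$samples
  n <- length(x)
  if (n < cfg$scale_max) stop_arg("record shorter than the largest scale")
  scales <- exp(seq(log(cfg$scale_min), log(cfg$scale_max),
                    length.out = cfg$n_scales))
  cs <- c(0, cumsum(x))
  max_len <- as.integer(round(cfg$scale_max))
  starts <- seq(1L, n - max_len + 1L, by = cfg$hop)
  vals <- matrix(0, cfg$n_scales, length(starts))
  for (s in seq_along(scales)) {
    lam <- max(2L, as.integer(round(scales[s])))
    half <- lam %/% 2
    # sum over [tau, tau+half) minus sum over [tau+half, tau+lam)
    a <- cs[starts + half] - cs[starts]
    b <- cs[starts + lam] - cs[starts + half]
    vals[s, ] <- ((a - b) / sqrt(lam))^2
  }
  fs <- record$sample_rate
  spectrogram_grid(vals, row_coords = scales,
                   col_coords = (starts - 1 + cfg$window_len / 2) / fs,
                   kind = "scalogram")
}
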