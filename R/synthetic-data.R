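#' Define a synthetic acoustic class
#'
#' A `class_spec` describes one synthetic sound class: its call type, its
#' frequency band, how often calls occur, and the signal-to-noise ratio at
#' which calls sit over the colored background noise. Call kinds mirror the
#' broad structure of passive-sonar sources: narrowband FM whistles
#' (dolphin-like), pulse/click trains, long low-frequency moans (whale-like),
#' and blade-rate amplitude-modulated broadband noise (propeller-like).
#'
#' @param name Class label.
#' @param call_kind One of `"fm_whistle"`, `"pulse_train"`, `"moan"`,
#'   `"broadband_am"`.
#' @param f_lo,f_hi Band of the call in Hz (`f_lo <= f_hi`).
#' @param call_rate Calls (or AM cycles) per second.
#' @param amplitude Linear peak amplitude in (0, 1].
#' @param snr_db Signal-to-noise ratio in dB; `Inf` disables noise.
#' @return A `class_spec` object.
#' @export
class_spec <- function(name, call_kind, f_lo, f_hi, call_rate = 1,
                       amplitude = 0.8, snr_db = 20) {
  call_kind <- match.arg(call_kind,
                         c("fm_whistle", "pulse_train", "moan", "broadband_am"))
  if (!is_number(f_lo) || !is_number(f_hi) || f_lo < 0 || f_lo > f_hi) {
    stop_arg("need 0 <= f_lo <= f_hi")
  }
  if (!is_number(amplitude) || amplitude <= 0 || amplitude > 1) {
    stop_arg("`amplitude` must be in (0, 1]")
  }
  if (length(snr_db) != 1 || is.na(snr_db)) stop_arg("`snr_db` must be a number")
  if (!is_number(call_rate) || call_rate <= 0) stop_arg("`call_rate` must be > 0")
  structure(
    list(name = name, call_kind = call_kind, f_lo = f_lo, f_hi = f_hi,
         call_rate = call_rate, amplitude = amplitude, snr_db = snr_db),
    class = "class_spec"
  )
}

#' Default synthetic class specifications
#'
#' Six classes: four biotic (two whistle classes in distinct bands, one
#' low-frequency moan, one click train) loosely mimicking two dolphin and
#' two whale classes, plus two propeller-like broadband classes with
#' different blade rates. `n_classes = 4` returns the biotic subset.
#'
#' @param n_classes 4 (biotic only) or 6 (biotic + propeller-like).
#' @param snr_db SNR applied to every class.
#' @return A named list of [class_spec()]s.
#' @export
default_class_specs <- function(n_classes = 4, snr_db = 20) {
  specs <- list(
    class_spec("whistle_hi", "fm_whistle", 4000, 7000, call_rate = 2,
               snr_db = snr_db),
    class_spec("whistle_lo", "fm_whistle", 1500, 3000, call_rate = 2,
               snr_db = snr_db),
    class_spec("moan", "moan", 150, 400, call_rate = 0.5, snr_db = snr_db),
    class_spec("clicks", "pulse_train", 3000, 6000, call_rate = 8,
               snr_db = snr_db),
    class_spec("propeller_a", "broadband_am", 100, 2000, call_rate = 5,
               snr_db = snr_db),
    class_spec("propeller_b", "broadband_am", 500, 4000, call_rate = 12,
               snr_db = snr_db)
  )
  if (!n_classes %in% c(4, 6)) stop_arg("`n_classes` must be 4 or 6")
  specs <- specs[seq_len(n_classes)]
  setNames(specs, vapply(specs, `[[`, "", "name"))
}

# 1/f ("ocean-like") colored Gaussian noise with unit variance.
colored_noise <- function(n, sample_rate) {
  w <- rnorm(n)
  spec <- fft(w)
  f <- c(1, seq_len(n - 1))            # avoid divide-by-zero at DC
  f <- pmin(f, n - f + 1)              # mirror for the negative frequencies
  shape <- 1 / sqrt(f)
  x <- Re(fft(spec * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

# One call waveform of length n at sample rate fs for the given spec.
call_waveform <- function(spec, n, fs) {
  t <- (seq_len(n) - 1) / fs
  dur <- n / fs
  fc <- (spec$f_lo + spec$f_hi) / 2
  bw <- spec$f_hi - spec$f_lo
  switch(
    spec$call_kind,
    fm_whistle = {
      # smooth up-down sweep across [f_lo, f_hi] with a Hann envelope,
      # which keeps spectral splatter outside the band negligible
      f_inst <- spec$f_lo + bw * (0.5 - 0.5 * cos(2 * pi * t / dur))
      phase <- 2 * pi * cumsum(f_inst) / fs
      env <- 0.5 - 0.5 * cos(2 * pi * t / dur)
      env * sin(phase)
    },
    moan = {
      # slow narrowband rise with a gentle taper
      f_inst <- spec$f_lo + bw * t / dur
      phase <- 2 * pi * cumsum(f_inst) / fs
      taper_n <- max(2L, min(n %/% 10, as.integer(0.05 * fs)))
      env <- rep(1, n)
      ramp <- seq(0, 1, length.out = taper_n)
      env[seq_len(taper_n)] <- ramp
      env[(n - taper_n + 1):n] <- rev(ramp)
      env * sin(phase)
    },
    pulse_train = {
      # Gaussian-windowed tone burst at band center; sigma_t chosen so the
      # -inf..inf Gaussian bandwidth (~= 1/(2 pi sigma_t) std in Hz) keeps
      # most energy inside the band
      sigma_t <- 2 / (pi * bw)
      center <- dur / 2
      exp(-((t - center)^2) / (2 * sigma_t^2)) * sin(2 * pi * fc * (t - center))
    },
    broadband_am = {
      # band-passed Gaussian noise; band edges enforced in the spectrum with
      # a raised-cosine rolloff
      w <- rnorm(n)
      spec_w <- fft(w)
      freqs <- (seq_len(n) - 1) * fs / n
      freqs <- ifelse(freqs > fs / 2, fs - freqs, freqs)
      roll <- 0.05 * max(bw, 1)
      gain <- rep(0, n)
      inside <- freqs >= spec$f_lo & freqs <= spec$f_hi
      gain[inside] <- 1
      lo_edge <- freqs >= spec$f_lo - roll & freqs < spec$f_lo
      gain[lo_edge] <- 0.5 + 0.5 * cos(pi * (spec$f_lo - freqs[lo_edge]) / roll)
      hi_edge <- freqs > spec$f_hi & freqs <= spec$f_hi + roll
      gain[hi_edge] <- 0.5 + 0.5 * cos(pi * (freqs[hi_edge] - spec$f_hi) / roll)
      x <- Re(fft(spec_w * gain, inverse = TRUE)) / n
      x / max(abs(x), 1e-12)
    }
  )
}

#' Generate one synthetic labeled call record
#'
#' Produces a record of the exact requested length whose spectral energy is
#' concentrated in the spec's band, embedded in 1/f colored background noise
#' at the spec's SNR. Deterministic given `seed`.
#'
#' @param spec A [class_spec()].
#' @param duration_s Record duration in seconds (> 0).
#' @param sample_rate Sampling rate in Hz; the call band must stay below
#'   Nyquist (`f_hi <= sample_rate / 2`).
#' @param seed Integer seed.
#' @return A labeled [audio_record()].
#' @export
generate_call <- function(spec, duration_s, sample_rate = 16000, seed = 1) {
  stopifnot(inherits(spec, "class_spec"))
  if (!is_number(duration_s) || duration_s <= 0) {
    stop_arg("`duration_s` must be > 0")
  }
  if (spec$f_hi > sample_rate / 2) {
    stop_arg("call band exceeds Nyquist: f_hi must be <= sample_rate / 2")
  }
  n <- as.integer(round(duration_s * sample_rate))
  with_seed(seed, {
    x <- numeric(n)
    if (spec$call_kind == "broadband_am") {
      # continuous broadband source with blade-rate amplitude modulation
      carrier <- call_waveform(spec, n, sample_rate)
      t <- (seq_len(n) - 1) / sample_rate
      am <- 1 + 0.6 * sin(2 * pi * spec$call_rate * t)
      x <- carrier * am / max(abs(carrier * am), 1e-12)
    } else {
      # discrete calls placed at roughly call_rate per second with jitter
      n_calls <- max(1L, as.integer(round(spec$call_rate * duration_s)))
      call_len <- as.integer(round(min(
        duration_s / max(n_calls, 1) * 0.8,
        if (spec$call_kind == "pulse_train") 0.04 else 1.2
      ) * sample_rate))
      call_len <- max(call_len, 32L)
      slots <- floor(seq(0, n - call_len, length.out = n_calls + 1))
      for (k in seq_len(n_calls)) {
        lo <- slots[k]
        hi <- max(lo, min(slots[k + 1], n - call_len))
        start <- lo + as.integer(floor(runif(1) * max(1, hi - lo + 1)))
        idx <- (start + 1):(start + call_len)
        x[idx] <- x[idx] + call_waveform(spec, call_len, sample_rate)
      }
    }
    x <- spec$amplitude * x / max(abs(x), 1e-12)
    if (is.finite(spec$snr_db)) {
      noise <- colored_noise(n, sample_rate)
      p_sig <- mean(x^2)
      p_noise_target <- p_sig / 10^(spec$snr_db / 10)
      x <- x + noise * sqrt(p_noise_target)
      peak <- max(abs(x))
      if (peak > 1) x <- x / peak
    }
    audio_record(x, sample_rate, label = spec$name)
  })
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes `n_per_class` PCM-16 WAV files per class under `out_dir` plus a
#' manifest CSV (`path,label,duration_s`). Per-record seeds are derived
#' deterministically from `seed`, so the same call is bit-identical across
#' runs.
#'
#' @param specs Non-empty list of [class_spec()]s with distinct names.
#' @param n_per_class Records per class (>= 1).
#' @param duration_s Either a single duration or a vector of per-class
#'   durations in seconds (biotic classes typically 5 s, propeller-like
#'   classes 200 s).
#' @param sample_rate Hz.
#' @param out_dir Output directory (created if needed).
#' @param seed Master integer seed.
#' @return A `dataset_manifest`: data.frame `entries` (path, label,
#'   duration_s), `class_counts`, and the `seed`.
#' @export
generate_dataset <- function(specs, n_per_class, duration_s = 5,
                             sample_rate = 16000, out_dir, seed = 1) {
  if (length(specs) == 0) stop_arg("`specs` must be non-empty")
  if (inherits(specs, "class_spec")) specs <- list(specs)
  nms <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nms)) stop_arg("class names must be distinct")
  if (!is_count(n_per_class)) stop_arg("`n_per_class` must be >= 1")
  durations <- rep_len(duration_s, length(specs))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_arg("cannot create output directory: ", out_dir)

  rows <- vector("list", length(specs) * n_per_class)
  r <- 0L
  for (ci in seq_along(specs)) {
    for (k in seq_len(n_per_class)) {
      rec <- generate_call(specs[[ci]], durations[ci], sample_rate,
                           seed = derive_seed(seed, ci, k))
      fname <- sprintf("%s_%03d.wav", nms[ci], k)
      path <- file.path(out_dir, fname)
      write_wav(rec, path)
      r <- r + 1L
      rows[[r]] <- data.frame(path = path, label = nms[ci],
                              duration_s = durations[ci],
                              stringsAsFactors = FALSE)
    }
  }
  entries <- do.call(rbind, rows)
  manifest <- dataset_manifest(entries, seed = seed)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Construct a dataset manifest
#'
#' @param entries data.frame with columns `path`, `label`, `duration_s`.
#' @param seed The seed the dataset was generated with (or `NA`).
#' @return A `dataset_manifest` object.
#' @export
dataset_manifest <- function(entries, seed = NA_integer_) {
  stopifnot(is.data.frame(entries),
            all(c("path", "label", "duration_s") %in% names(entries)))
  if (anyDuplicated(entries$path)) stop_arg("manifest paths must be unique")
  counts <- table(entries$label)
  structure(
    list(entries = entries,
         class_counts = setNames(as.integer(counts), names(counts)),
         seed = seed),
    class = "dataset_manifest"
  )
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("<dataset_manifest> %d records, %d classes\n",
              nrow(x$entries), length(x$class_counts)))
  print(x$class_counts)
  invisible(x)
}

#' Write / read a manifest CSV (`path,label,duration_s`)
#'
#' @param manifest A [dataset_manifest()].
#' @param path CSV path.
#' @return `path` invisibly (write) or a [dataset_manifest()] (read).
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest$entries, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  dataset_manifest(read.csv(path, stringsAsFactors = FALSE))
}

#' The two-sine worked-example signal
#'
#' The composite test signal `1.8 sin(2 pi 6 t) + 0.6 sin(2 pi 18 t)` used
#' to compare interpolation methods on a spectrum with two known lines.
#'
#' @param sample_rate Hz (>= 100, well above both components).
#' @param duration_s Seconds.
#' @return An [audio_record()].
#' @export
make_case_b_signal <- function(sample_rate = 1000, duration_s = 2) {
  if (!is_number(sample_rate) || sample_rate < 100) {
    stop_arg("`sample_rate` must be >= 100 Hz")
  }
  if (!is_number(duration_s) || duration_s <= 0) stop_arg("`duration_s` must be > 0")
  t <- seq(0, duration_s - 1 / sample_rate, by = 1 / sample_rate)
  audio_record(1.8 * sin(2 * pi * 6 * t) + 0.6 * sin(2 * pi * 18 * t),
               sample_rate)
}

#' The single-sine worked-example series
#'
#' Uniform samples of `sin(2 t)` on `[0, 11]`, the one-component case used
#' to illustrate piecewise-constant, linear, and cubic-spline interpolation.
#'
#' @param n_points Number of samples (>= 2).
#' @return A list with fields `t` and `y`.
#' @export
make_case_a_series <- function(n_points = 12) {
  if (!is_count(n_points) || n_points < 2) stop_arg("`n_points` must be >= 2")
  t <- seq(0, 11, length.out = n_points)
  list(t = t, y = sin(2 * t))
}
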