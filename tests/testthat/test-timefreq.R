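test_that("one-sided FFT spectrum recovers amplitudes of a two-tone signal", {
  sig <- make_case_b_signal()
  sp <- fft_spectrum(sig)
  expect_equal(sp$freqs[2] - sp$freqs[1], 0.5)
  i6 <- which.min(abs(sp$freqs - 6))
  i18 <- which.min(abs(sp$freqs - 18))
  expect_equal(sp$magnitudes[i6], 1.8, tolerance = 1e-10)
  expect_equal(sp$magnitudes[i18], 0.6, tolerance = 1e-10)
  # everything else is numerically zero (integer periods fit exactly)
  rest <- sp$magnitudes[-c(i6, i18)]
  expect_lt(max(rest), 1e-10)
})

test_that("frame_signal produces the documented frame count and hop", {
  x <- seq_len(1000)
  fr <- cetaclass:::frame_signal(x, n_fft = 256, hop = 64)
  expect_equal(ncol(fr), 1 + (1000 - 256) %/% 64)
  expect_equal(fr[, 1], x[1:256])
  expect_equal(fr[, 2], x[65:(64 + 256)])
  expect_error(cetaclass:::frame_signal(x[1:100], 256, 64), "shorter")
})

test_that("STFT localizes a chirp's instantaneous frequency over time", {
  fs <- 8000
  tt <- (0:(2 * fs - 1)) / fs
  f0 <- 500; f1 <- 3000
  x <- sin(2 * pi * (f0 * tt + (f1 - f0) / (2 * 2) * tt^2))
  grid <- stft_spectrogram(audio_record(x, fs), stft_config())
  expect_s3_class(grid, "spectrogram_grid")
  expect_equal(nrow(grid$values), 256 / 2 + 1)
  peak_f <- grid$row_coords[apply(grid$values, 2, which.max)]
  inst_f <- f0 + (f1 - f0) * grid$col_coords / 2
  expect_lt(stats::median(abs(peak_f - inst_f)), 2 * fs / 256)
  expect_gt(stats::cor(grid$col_coords, peak_f), 0.95)
})

test_that("STFT default hop honours the 75% overlap contract", {
  fs <- 4000
  rec <- audio_record(rnorm(fs), fs)
  grid <- stft_spectrogram(rec, stft_config())
  hop_s <- grid$col_coords[2] - grid$col_coords[1]
  expect_equal(hop_s, (256 * 0.25) / fs, tolerance = 1e-12)
})

test_that("mel scale matches the reference formula and is invertible", {
  expect_equal(hz_to_mel(0), 0)
  expect_equal(hz_to_mel(700), 2595 * log10(2))
  expect_equal(hz_to_mel(1000), 2595 * log10(1 + 1000 / 700))
  f <- c(0, 150, 700, 3000, 7999)
  expect_equal(mel_to_hz(hz_to_mel(f)), f, tolerance = 1e-9)
  expect_true(all(diff(hz_to_mel(seq(0, 8000, by = 10))) > 0))
})

test_that("mel filterbank rows are triangular, normalized and ordered", {
  fb <- cetaclass:::mel_filterbank(n_fft = 1024, n_mels = 64, f_min = 0,
                                   f_max = 8000, sample_rate = 16000)
  expect_equal(dim(fb$weights), c(64, 513))
  expect_true(all(fb$weights >= 0))
  expect_equal(unname(rowSums(fb$weights)), rep(1, 64), tolerance = 1e-12)
  expect_length(fb$centers, 64)
  expect_true(all(diff(fb$centers) > 0))
  # centers are uniformly spaced on the mel axis
  expect_equal(diff(diff(hz_to_mel(fb$centers))), rep(0, 62),
               tolerance = 1e-9)
})

test_that("mel spectrogram concentrates energy in the right band", {
  fs <- 16000
  tt <- (0:(fs - 1)) / fs
  rec <- audio_record(sin(2 * pi * 3000 * tt), fs)
  grid <- mel_spectrogram(rec, mel_config())
  expect_equal(nrow(grid$values), 64)
  peak_band_hz <- grid$row_coords[which.max(rowMeans(grid$values))]
  expect_lt(abs(peak_band_hz - 3000), 500)
})

test_that("the Haar mother wavelet matches its closed form", {
  expect_equal(haar_wavelet(c(0, 0.25, 0.49)), c(1, 1, 1))
  expect_equal(haar_wavelet(c(0.5, 0.75, 0.99)), c(-1, -1, -1))
  expect_equal(haar_wavelet(c(-0.1, 1, 2)), c(0, 0, 0))
})

test_that("fast Haar CWT equals the brute-force wavelet inner product", {
  set.seed(4)
  x <- rnorm(600)
  fs <- 600
  cfg <- cwt_config(window_len = 512, n_scales = 6,
                    scale_min = 2, scale_max = 64)
  grid <- haar_cwt_scalogram(audio_record(x, fs), cfg)
  expect_equal(dim(grid$values), c(6, length(grid$col_coords)))
  for (si in seq_along(grid$row_coords)) {
    lam <- max(2L, as.integer(round(grid$row_coords[si])))
    if (lam %% 2 != 0) next   # psi(j/lam) equals the box split for even lam
    psi <- haar_wavelet((seq_len(lam) - 1) / lam)
    ref <- (sum(x[1:lam] * psi) / sqrt(lam))^2
    expect_equal(grid$values[si, 1], ref, tolerance = 1e-10)
  }
})

test_that("Haar scalogram peaks near the period of a square wave", {
  fs <- 1024
  period <- 64
  x <- rep(c(rep(1, period / 2), rep(-1, period / 2)), length.out = 2048)
  cfg <- cwt_config(window_len = 512, n_scales = 40,
                    scale_min = 8, scale_max = 256)
  grid <- haar_cwt_scalogram(audio_record(x, fs), cfg)
  best <- grid$row_coords[which.max(rowMeans(grid$values))]
  expect_gt(best, period / 2)
  expect_lt(best, period * 2)
})

test_that("transform configs validate their arguments", {
  expect_error(stft_config(n_fft = 100), "power of two")
  expect_error(stft_config(overlap_frac = 1), "overlap")
  expect_error(mel_config(n_mels = 1), "n_mels")
  expect_error(cwt_config(scale_min = 1), "scale_min")
  expect_error(cwt_config(window_len = 512, scale_max = 1024), "scale_max")
})
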