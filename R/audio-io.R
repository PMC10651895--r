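#' Construct an audio record
#'
#' An `audio_record` is a mono sampled waveform with its sample rate and an
#' optional class label. It is the common currency passed between the
#' generator, the segmenter, and the time-frequency transforms.
#'
#' @param samples Numeric vector of finite sample values.
#' @param sample_rate Sampling rate in Hz.
#' @param label Optional class label (single string) or `NULL`.
#' @return An object of class `audio_record` with fields `samples`,
#'   `sample_rate`, `duration_s`, and `label`.
#' @export
audio_record <- function(samples, sample_rate, label = NULL) {
  if (!is.numeric(samples) || length(samples) == 0) {
    stop_arg("`samples` must be a non-empty numeric vector")
  }
  if (!all(is.finite(samples))) stop_arg("`samples` must be finite")
  if (!is_number(sample_rate) || sample_rate <= 0) {
    stop_arg("`sample_rate` must be a positive number")
  }
  if (!is.null(label) && (length(label) != 1 || !is.character(label))) {
    stop_arg("`label` must be NULL or a single string")
  }
  structure(
    list(
      samples = as.double(samples),
      sample_rate = sample_rate,
      duration_s = length(samples) / sample_rate,
      label = label
    ),
    class = "audio_record"
  )
}

#' @export
print.audio_record <- function(x, ...) {
  cat(sprintf(
    "<audio_record> %d samples @ %g Hz (%.3f s)%s\n",
    length(x$samples), x$sample_rate, x$duration_s,
    if (is.null(x$label)) "" else paste0(" label=", x$label)
  ))
  invisible(x)
}

#' Read a RIFF/WAV PCM file as a mono audio record
#'
#' Multi-channel files are averaged down to mono; integer PCM samples are
#' rescaled to `[-1, 1]`. Supports PCM-16 (the package's own output format)
#' plus PCM-8/24/32 and IEEE float WAV.
#'
#' @param path Path to a `.wav` file.
#' @param label Optional class label to attach.
#' @return An [audio_record()].
#' @export
read_wav <- function(path, label = NULL) {
  if (!file.exists(path)) stop_arg("WAV file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_arg("not a RIFF/WAV file: ", path)
  readBin(con, "integer", 1, 4, endian = "little") # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_arg("not a RIFF/WAV file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz) # skip unknown chunk
    }
    if (sz %% 2 == 1) readBin(con, "raw", 1) # chunk padding byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop_arg("malformed WAV (missing fmt/data chunk): ", path)
  }

  x <- switch(
    as.character(fmt$bits),
    "8"  = (as.double(readBin(data_raw, "integer", length(data_raw), 1,
                              signed = FALSE)) - 128) / 128,
    "16" = readBin(data_raw, "integer", length(data_raw) %/% 2, 2,
                   signed = TRUE, endian = "little") / 32768,
    "24" = {
      n <- length(data_raw) %/% 3
      b <- matrix(as.integer(data_raw), nrow = 3)[, seq_len(n), drop = FALSE]
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = if (fmt$audio_format == 3) {
      readBin(data_raw, "double", length(data_raw) %/% 4, 4, endian = "little")
    } else {
      readBin(data_raw, "integer", length(data_raw) %/% 4, 4,
              endian = "little") / 2147483648
    },
    stop_arg("unsupported WAV bit depth: ", fmt$bits, " in ", path)
  )

  nc <- fmt$n_channels
  if (nc > 1) {
    n <- length(x) %/% nc
    x <- colMeans(matrix(x[seq_len(n * nc)], nrow = nc))
  }
  audio_record(x, fmt$sample_rate, label = label)
}

#' Write an audio record as PCM-16 WAV
#'
#' Samples are clipped to `[-1, 1]` and quantized to 16-bit PCM.
#'
#' @param record An [audio_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(record, path) {
  stopifnot(inherits(record, "audio_record"))
  x <- clamp(record$samples, -1, 1)
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  fs <- as.integer(round(record$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")   # PCM
  writeBin(1L, con, 2, endian = "little")   # mono
  writeBin(fs, con, 4, endian = "little")
  writeBin(fs * 2L, con, 4, endian = "little")  # byte rate
  writeBin(2L, con, 2, endian = "little")   # block align
  writeBin(16L, con, 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

#' Segmentation configuration
#'
#' @param segment_s Seconds per output record (default 5, the biotic record
#'   length; propeller-like classes typically use 200).
#' @param drop_last_partial Drop a trailing segment shorter than `segment_s`
#'   (default `TRUE`).
#' @param resample_to Optional target sample rate in Hz; `NULL` keeps the
#'   native rate. Resampling uses polyphase filtering.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(segment_s = 5, drop_last_partial = TRUE,
                                resample_to = NULL) {
  if (!is_number(segment_s) || segment_s <= 0) {
    stop_arg("`segment_s` must be > 0")
  }
  structure(
    list(segment_s = segment_s, drop_last_partial = drop_last_partial,
         resample_to = resample_to),
    class = "segmentation_config"
  )
}

#' Cut a record into fixed-length contiguous segments
#'
#' Segments are non-overlapping, inherit the parent label, and partition the
#' input: no sample is reused or skipped before the (optionally dropped)
#' tail.
#'
#' @param record An [audio_record()].
#' @param cfg A [segmentation_config()].
#' @return A list of [audio_record()]s, each exactly `segment_s` long.
#' @export
segment_record <- function(record, cfg = segmentation_config()) {
  stopifnot(inherits(record, "audio_record"))
  if (length(record$samples) == 0) stop_arg("empty record")
  if (!is.null(cfg$resample_to) && cfg$resample_to != record$sample_rate) {
    y <- signal::resample(record$samples, p = cfg$resample_to,
                          q = record$sample_rate)
    record <- audio_record(y, cfg$resample_to, label = record$label)
  }
  seg_len <- as.integer(round(cfg$segment_s * record$sample_rate))
  n_full <- length(record$samples) %/% seg_len
  out <- vector("list", n_full)
  for (i in seq_len(n_full)) {
    idx <- ((i - 1) * seg_len + 1):(i * seg_len)
    out[[i]] <- audio_record(record$samples[idx], record$sample_rate,
                             label = record$label)
  }
  if (!cfg$drop_last_partial && length(record$samples) %% seg_len != 0) {
    idx <- (n_full * seg_len + 1):length(record$samples)
    out <- c(out, list(audio_record(record$samples[idx], record$sample_rate,
                                    label = record$label)))
  }
  out
}
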