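#' Featurization configuration for the RGB stack
#'
#' Bundles the per-transform configurations plus the image geometry used by
#' [featurize_record()]. The image defaults to 128 x 128 (the encoder's
#' native input); 224 is a common alternative for plain-CNN baselines.
#'
#' @param image_size Output image side in pixels.
#' @param db_floor dB floor applied before per-image min-max normalization.
#' @param stft,mel,cwt,upsample Stage configurations.
#' @return A `featurize_config` list.
#' @export
featurize_config <- function(image_size = 128, db_floor = -80,
                             stft = stft_config(), mel = mel_config(),
                             cwt = cwt_config(),
                             upsample = grid_upsample_config()) {
  if (!is_count(image_size) || image_size < 8) {
    stop_arg("`image_size` must be an integer >= 8")
  }
  if (!is_number(db_floor) || db_floor >= 0) {
    stop_arg("`db_floor` must be a negative number of decibels")
  }
  structure(list(image_size = as.integer(image_size), db_floor = db_floor,
                 stft = stft, mel = mel, cwt = cwt, upsample = upsample),
            class = "featurize_config")
}

#' Convert a spectrogram grid to a normalized square image channel
#'
#' Magnitudes go through `20 log10` with a floor at `db_floor` (relative to
#' the grid maximum), per-image min-max normalization to `[0, 1]`, and a
#' bilinear resize to `image_size x image_size`. Row 1 of the returned pixel
#' matrix is the top of the image; low frequencies (grid row 1) end up at
#' the bottom row. An all-constant grid maps to all zeros.
#'
#' @param grid A `spectrogram_grid`.
#' @param image_size Output side in pixels.
#' @param db_floor dB floor (negative).
#' @return An `image_channel`: list with `pixels` (matrix in `[0,1]`) and
#'   `source_kind`.
#' @export
grid_to_channel <- function(grid, image_size = 128, db_floor = -80) {
  stopifnot(inherits(grid, "spectrogram_grid"))
  v <- grid$values
  ref <- max(v)
  if (ref <= 0) {
    px <- matrix(0, image_size, image_size)
  } else {
    db <- 20 * log10(pmax(v / ref, 10^(db_floor / 20)))
    rng <- range(db)
    norm <- if (diff(rng) <= 0) db * 0 else (db - rng[1]) / diff(rng)
    resized <- EBImage::imageData(EBImage::resize(
      EBImage::as.Image(norm), w = image_size, h = image_size
    ))
    px <- clamp(resized[image_size:1, , drop = FALSE], 0, 1) # low freq at bottom
  }
  kind <- switch(grid$kind, stft = "stft_csi", mel = "mel",
                 scalogram = "scalogram", grid$kind)
  structure(list(pixels = px, source_kind = kind), class = "image_channel")
}

#' Stack three image channels into an RGB feature spectrogram
#'
#' Channel assignment is fixed: R = Mel spectrogram, G = spline-interpolated
#' STFT, B = Haar scalogram. Pixel values are passed through unchanged.
#'
#' @param mel_ch,stftcsi_ch,scal_ch `image_channel`s of identical shape.
#' @param label Optional class label.
#' @param source_path Optional provenance string.
#' @return An `rgb_spectrogram`: `pixels` is an `H x W x 3` array.
#' @export
stack_rgb <- function(mel_ch, stftcsi_ch, scal_ch, label = NULL,
                      source_path = NULL) {
  chs <- list(mel_ch, stftcsi_ch, scal_ch)
  dims <- lapply(chs, function(ch) dim(ch$pixels))
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    stop_arg("channels must have identical shapes")
  }
  px <- array(0, c(dims[[1]], 3L))
  px[, , 1] <- mel_ch$pixels
  px[, , 2] <- stftcsi_ch$pixels
  px[, , 3] <- scal_ch$pixels
  structure(list(pixels = px, label = label, source_path = source_path),
            class = "rgb_spectrogram")
}

#' @export
print.rgb_spectrogram <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_spectrogram> %d x %d x %d%s\n", d[1], d[2], d[3],
              if (is.null(x$label)) "" else paste0(" label=", x$label)))
  invisible(x)
}

#' Featurize an audio record into the RGB spectrogram stack
#'
#' Runs the three transforms (Mel, STFT + cubic-spline upsampling, Haar
#' scalogram), converts each to a normalized channel, and stacks them as
#' (R, G, B) = (mel, stft_csi, scalogram). Deterministic and side-effect
#' free; the record's label is propagated.
#'
#' @param record An [audio_record()].
#' @param cfg A [featurize_config()].
#' @param source_path Optional provenance string.
#' @return An `rgb_spectrogram`.
#' @export
featurize_record <- function(record, cfg = featurize_config(),
                             source_path = NULL) {
  mel_ch <- grid_to_channel(mel_spectrogram(record, cfg$mel),
                            cfg$image_size, cfg$db_floor)
  stft_ch <- grid_to_channel(stft_csi(record, cfg$stft, cfg$upsample),
                             cfg$image_size, cfg$db_floor)
  scal_ch <- grid_to_channel(haar_cwt_scalogram(record, cfg$cwt),
                             cfg$image_size, cfg$db_floor)
  stack_rgb(mel_ch, stft_ch, scal_ch, label = record$label,
            source_path = source_path)
}

#' Write / read an RGB spectrogram as 8-bit PNG
#'
#' @param image An `rgb_spectrogram`.
#' @param path PNG path.
#' @return `path` invisibly (write); an `rgb_spectrogram` (read).
#' @export
write_rgb_png <- function(image, path) {
  stopifnot(inherits(image, "rgb_spectrogram"))
  png::writePNG(clamp(image$pixels, 0, 1), path)
  invisible(path)
}

#' @rdname write_rgb_png
#' @export
read_rgb_png <- function(path, label = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  structure(list(pixels = px[, , 1:3, drop = FALSE], label = label,
                 source_path = path),
            class = "rgb_spectrogram")
}
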