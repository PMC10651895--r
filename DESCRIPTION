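Package: cetaclass
Title: Marine Mammal Acoustic Classification with Spline-Interpolated
    Spectrograms and a Siamese Variational Auto-Encoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage pipeline for classifying marine bioacoustic
    recordings from passive sonar. Stage one converts fixed-length audio
    records into three aligned time-frequency images (a cubic-spline
    interpolated STFT spectrogram, a Mel spectrogram, and a Haar
    continuous-wavelet scalogram) stacked as RGB channels. Stage two embeds
    the stacked images with a Siamese variational auto-encoder trained under
    a combined triplet, reconstruction, and Kullback-Leibler objective with
    semi-hard triplet mining, using structurally re-parameterizable
    convolution blocks that fuse multi-branch training weights into a single
    3x3 convolution for inference. Includes a seeded synthetic call
    generator (whistles, pulse trains, moans, and propeller-like noise) so
    the full pipeline is testable end to end, plus dataset splitting,
    K-fold utilities, and confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    png,
    EBImage,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
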