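# cetaclass

Classification of marine bioacoustic signals — whistles, moans, click
trains, and propeller noise — from passive acoustic recordings, using
spline-interpolated time-frequency images and a Siamese variational
auto-encoder (SNN-VAE).

## What it does

Passive acoustic monitoring produces long, noisy hydrophone recordings in
which the calls of different species (and anthropogenic sources such as
ship propellers) must be told apart. `cetaclass` implements a two-stage
pipeline:

1. **Feature stage.** Each fixed-length audio record is converted into
   three aligned time-frequency representations:
   - a short-time Fourier transform (STFT) spectrogram (Hanning window,
     256 samples, 75% overlap), **upsampled with a natural cubic spline**
     along both axes so that fine spectral ridges survive the later resize,
   - a Mel spectrogram (1024-sample window, 64 triangular bands on the
     `mel(f) = 2595 log10(1 + f/700)` scale), and
   - a Haar continuous-wavelet scalogram (512-sample window, log-spaced
     scales).

   The three images are normalized to `[0, 1]`, resized to a square, and
   stacked as the (R, G, B) channels of one feature image, so one picture
   carries three complementary views of the same sound.

2. **Model stage.** A convolutional variational auto-encoder embeds the
   RGB image into a latent vector. Training is Siamese: semi-hard mined
   (anchor, positive, negative) triplets pass through three weight-shared
   encoder copies and the loss is

   `total = triplet + reconstruction + beta * KL`

   — a hinge on squared embedding distances with margin `alpha`, a pixel
   mean-squared reconstruction error, and the Kullback–Leibler pull of the
   latent posterior towards the standard normal. Encoder blocks are
   multi-branch (3×3 + 1×1 + identity, each with batch normalization)
   during training and are **fused into a single 3×3 convolution** for
   inference, exactly preserving the function while cutting inference
   cost. Classification is nearest-centroid in the latent space.

Because real hydrophone corpora cannot be bundled, the package ships a
seeded synthetic call generator (frequency-modulated whistles, moans,
Gaussian-windowed click trains, and band-passed amplitude-modulated noise
over a 1/f background) so every stage is testable end to end.

## Worked example

The interpolation comparison uses a two-component bench signal
`x(t) = 1.8 sin(2π·6t) + 0.6 sin(2π·18t)` sampled at 1 kHz for 2 s. Its
amplitude-scaled FFT recovers both components exactly:

```r
library(cetaclass)

sig <- make_case_b_signal(sample_rate = 1000, duration_s = 2)
sp <- fft_spectrum(sig, scaling = "amplitude")
keep <- sp$freqs > 0
ord <- order(sp$magnitudes[keep], decreasing = TRUE)
sp$freqs[keep][ord[1:2]]
#> [1]  6 18
sp$magnitudes[keep][ord[1:2]]
#> [1] 1.8 0.6
```

Interpolating a coarse sampling of this signal's (Hann-windowed) spectrum
back onto a fine grid ranks the three interpolants as the design intends —
cubic spline (CSI) beats linear (LI) beats piecewise-constant (PCI):

```r
# root-mean-square reconstruction errors on the same coarse grid
#> CSI 0.0081   LI 0.0163   PCI 0.0401
```

A complete desk-scale run — generate 40 synthetic records in 4 classes,
split 70/20/10, featurize, train the SNN-VAE for 30 epochs, evaluate:

```r
res <- run_pipeline(default_run_config(out_dir = "run1", seed = 1))
#> [cetaclass] generating 4 classes x 10 records
#> [cetaclass] splitting 40 records 70/20/10
#> [cetaclass] featurizing
#> [cetaclass] training (30 epochs)
#> [cetaclass] evaluating on 4 test records
#> [cetaclass] done: test accuracy 1.000

tail(res$fit$history[, c("epoch", "reconstruction", "kl", "val_accuracy")], 1)
#>    epoch reconstruction       kl val_accuracy
#> 30    30          0.070    8.488        0.875
```

The run takes roughly two minutes on one CPU core and writes the audio,
manifests, training history, confusion matrices, resolved configuration,
and a `summary.json` under `out_dir`.

Lower-level entry points mirror the stages: `generate_dataset()`,
`read_wav()` / `segment_record()`, `stft_spectrogram()` /
`mel_spectrogram()` / `haar_cwt_scalogram()`, `stft_csi()`,
`featurize_record()`, `train_snnvae()`, `fuse_model()`, `classify()`,
`evaluate_model()`. A command-line front end is installed at
`inst/cli/cetaclass.R` (subcommands `demo`, `run`, `generate`,
`featurize`, `eval`).

## Vignette

`vignettes/cetaclass-methods.Rmd` describes the generative model for the
synthetic calls, every transform and its parameters, the SNN-VAE
architecture and loss reductions, and the numerical design decisions.
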