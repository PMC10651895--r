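fake_manifest <- function(labels) {
  dataset_manifest(data.frame(
    path = sprintf("rec_%03d.wav", seq_along(labels)),
    label = labels,
    duration_s = 5,
    stringsAsFactors = FALSE
  ))
}

tiny_images <- function(labels, size = 16, scale = 4) {
  # Linearly separable toy images: each class lights up its own block.
  classes <- sort(unique(labels))
  lapply(seq_along(labels), function(i) {
    k <- match(labels[i], classes)
    px <- array(withr::with_seed(1000 + i, runif(size * size * 3, 0, 0.1)),
                c(size, size, 3))
    rows <- ((k - 1) * scale + 1):(k * scale)
    px[rows, , ] <- px[rows, , ] + 0.8
    structure(list(pixels = pmin(px, 1), label = labels[i],
                   source_path = NULL), class = "rgb_spectrogram")
  })
}

test_that("apportion implements largest-remainder 70/20/10 splitting", {
  expect_equal(cetaclass:::apportion(10, c(0.7, 0.2, 0.1)), c(7, 2, 1))
  expect_equal(cetaclass:::apportion(40, c(0.7, 0.2, 0.1)), c(28, 8, 4))
  expect_equal(sum(cetaclass:::apportion(13, c(0.7, 0.2, 0.1))), 13)
  expect_equal(cetaclass:::apportion(5, c(0.7, 0.2, 0.1)), c(4, 1, 0))
})

test_that("stratified split is disjoint, exhaustive and per-class 70/20/10", {
  man <- fake_manifest(rep(c("a", "b", "c", "d"), each = 10))
  sp <- split_dataset(man, split_config(seed = 3))
  expect_named(sp, c("train", "val", "test"))
  expect_equal(nrow(sp$train$entries), 28)
  expect_equal(nrow(sp$val$entries), 8)
  expect_equal(nrow(sp$test$entries), 4)
  all_paths <- c(sp$train$entries$path, sp$val$entries$path,
                 sp$test$entries$path)
  expect_setequal(all_paths, man$entries$path)
  expect_equal(anyDuplicated(all_paths), 0L)
  for (g in sp) {
    expect_equal(as.vector(table(g$entries$label)),
                 rep(nrow(g$entries) %/% 4, 4))
  }
  # deterministic under the seed, different under another
  sp2 <- split_dataset(man, split_config(seed = 3))
  expect_identical(sp$train$entries$path, sp2$train$entries$path)
  sp3 <- split_dataset(man, split_config(seed = 4))
  expect_false(identical(sp$train$entries$path, sp3$train$entries$path))
})

test_that("kfold yields k folds covering each record exactly once", {
  man <- fake_manifest(rep(c("a", "b"), each = 11))
  folds <- kfold(man, split_config(k = 5, seed = 2))
  expect_length(folds, 5)
  val_paths <- unlist(lapply(folds, function(f) f$val$entries$path))
  expect_setequal(val_paths, man$entries$path)
  expect_equal(anyDuplicated(val_paths), 0L)
  sizes <- vapply(folds, function(f) nrow(f$val$entries), 0L)
  expect_lte(max(sizes) - min(sizes), 1L)
  for (f in folds) {
    expect_equal(nrow(f$train$entries) + nrow(f$val$entries), 22)
    expect_length(intersect(f$train$entries$path, f$val$entries$path), 0)
  }
  expect_error(kfold(fake_manifest(c("a", "b")), split_config(k = 5)),
               "fewer records")
})

test_that("confusion matrix and metrics follow the reference formulas", {
  truth <- c("a", "a", "a", "b", "b", "c")
  pred  <- c("a", "a", "b", "b", "b", "a")
  cm <- confusion_matrix(truth, pred)
  expect_equal(unname(cm$counts["a", "a"]), 2)
  expect_equal(unname(cm$counts["a", "b"]), 1)
  expect_equal(unname(cm$counts["c", "a"]), 1)
  expect_equal(sum(cm$counts), 6)
  m <- metrics_from_confusion(cm)
  expect_equal(m$accuracy, 4 / 6)
  # class a: TP = 2, FP = 1, FN = 1
  expect_equal(unname(m$precision["a"]), 2 / 3)
  expect_equal(unname(m$recall["a"]), 2 / 3)
  # class c: never predicted -> precision undefined, reported as 0
  expect_equal(unname(m$precision["c"]), 0)
  expect_equal(unname(m$recall["c"]), 0)
  expect_true(unname(m$undefined_precision["c"]))
  expect_false(any(m$undefined_precision[c("a", "b")]))
})

test_that("training on separable toy images reaches high accuracy quickly", {
  labels <- rep(c("p", "q"), each = 8)
  imgs <- tiny_images(labels)
  cfg <- encoder_config(n_stages = 2, stage_widths = c(4, 8), latent_dim = 4,
                        image_size = 16)
  fit <- train_snnvae(imgs, labels, imgs, labels, cfg = cfg,
                      hyper = train_hyper(epochs = 4), seed = 5)
  expect_s3_class(fit, "snnvae_fit")
  expect_equal(nrow(fit$history), 4)
  expect_equal(fit$history$total,
               fit$history$triplet + fit$history$reconstruction +
                 fit$history$kl, tolerance = 1e-12)
  expect_true(all(is.finite(fit$history$total)))
  expect_equal(fit$history$val_accuracy[4], 1)
  expect_equal(predict_labels(fit, imgs), labels)
  ev <- evaluate_model(fit, imgs, labels)
  expect_equal(ev$metrics$accuracy, 1)
  expect_equal(unname(diag(ev$confusion$counts)), c(8, 8))
})

test_that("single-class training data raises a mining error", {
  labels <- rep("only", 4)
  imgs <- tiny_images(labels)
  cfg <- encoder_config(n_stages = 2, stage_widths = c(4, 8), latent_dim = 4,
                        image_size = 16)
  expect_error(train_snnvae(imgs, labels, cfg = cfg,
                            hyper = train_hyper(epochs = 1)),
               "mining error")
})

test_that("training is reproducible under a fixed seed", {
  labels <- rep(c("p", "q"), each = 4)
  imgs <- tiny_images(labels)
  cfg <- encoder_config(n_stages = 2, stage_widths = c(4, 8), latent_dim = 4,
                        image_size = 16)
  f1 <- train_snnvae(imgs, labels, cfg = cfg,
                     hyper = train_hyper(epochs = 2), seed = 11)
  f2 <- train_snnvae(imgs, labels, cfg = cfg,
                     hyper = train_hyper(epochs = 2), seed = 11)
  expect_equal(f1$history, f2$history, tolerance = 1e-12)
  expect_equal(f1$centroids, f2$centroids, tolerance = 1e-12)
})

test_that("run config YAML round-trips and rejects unknown keys", {
  cfg <- default_run_config(out_dir = "unused", seed = 9)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_equal(back$seed, 9)
  expect_equal(back$generation, cfg$generation)
  expect_equal(back$training, cfg$training)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 1", "generaton: {n_classes: 4}"), bad)
  expect_error(read_run_config(bad), "unknown config key")
  bad2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("training:", "  epochz: 3"), bad2)
  expect_error(read_run_config(bad2), "training.epochz")
})

test_that("run_pipeline dry run validates without touching audio", {
  out <- withr::local_tempdir()
  cfg <- default_run_config(out_dir = out, seed = 1)
  res <- run_pipeline(cfg, dry_run = TRUE, verbose = FALSE)
  expect_named(res, "config")
  expect_length(list.files(out), 0)
})
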