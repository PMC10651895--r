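#' Default pipeline run configuration
#'
#' A nested configuration covering generation, segmentation, featurization,
#' model, training, and evaluation, serializable to/from YAML. Unknown keys
#' are rejected on load.
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Global integer seed.
#' @return A `run_config` list.
#' @export
default_run_config <- function(out_dir = tempfile("cetaclass_run_"),
                               seed = 1) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    generation = list(n_classes = 4, n_per_class = 10, duration_s = 5,
                      sample_rate = 16000, snr_db = 20),
    segmentation = list(segment_s = 5, drop_last_partial = TRUE),
    features = list(image_size = 64, db_floor = -80, freq_factor = 2,
                    time_factor = 2, method = "csi"),
    model = list(n_stages = 4, stage_widths = c(8, 16, 32, 64),
                 latent_dim = 32),
    training = list(epochs = 30, batch_triplets = 16, lr = 1e-3,
                    alpha = 0.2, beta = 1.0),
    split = list(train = 0.7, val = 0.2, test = 0.1)
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `run_config`.
#' @return A `run_config` (read); `path` invisibly (write).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop_arg("config file must be a YAML mapping")
  base <- unclass(default_run_config())
  check_keys <- function(x, ref, prefix = "") {
    extra <- setdiff(names(x), names(ref))
    if (length(extra) > 0) {
      stop_arg("unknown config key(s): ",
               paste0(prefix, extra, collapse = ", "))
    }
    for (nm in names(x)) {
      if (is.list(ref[[nm]]) && is.list(x[[nm]])) {
        check_keys(x[[nm]], ref[[nm]], paste0(prefix, nm, "."))
      }
    }
  }
  check_keys(raw, base)
  out <- utils::modifyList(base, raw)
  class(out) <- "run_config"
  out
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

run_config_to_objects <- function(config) {
  fc <- featurize_config(
    image_size = config$features$image_size,
    db_floor = config$features$db_floor,
    upsample = grid_upsample_config(config$features$freq_factor,
                                    config$features$time_factor,
                                    config$features$method)
  )
  ec <- encoder_config(
    n_stages = config$model$n_stages,
    stage_widths = config$model$stage_widths,
    latent_dim = config$model$latent_dim,
    image_size = config$features$image_size
  )
  hy <- train_hyper(epochs = config$training$epochs,
                    batch_triplets = config$training$batch_triplets,
                    lr = config$training$lr, alpha = config$training$alpha,
                    beta = config$training$beta)
  sc <- split_config(ratios = unlist(config$split), seed = config$seed)
  list(features = fc, encoder = ec, hyper = hy, split = sc)
}

#' Run the full pipeline: generate, featurize, split, train, evaluate
#'
#' Executes every stage on synthetic data under one seed and writes the
#' artifacts (WAV records + manifest, split manifests, training history CSV,
#' confusion matrix CSV, resolved config snapshot, and a summary JSON with
#' the final metrics and loss breakdown) under `config$out_dir`.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param dry_run Validate the configuration and return without touching
#'   audio.
#' @param verbose Print stage progress.
#' @return Invisibly, a list with `fit`, `evaluation`, and `summary`.
#' @export
run_pipeline <- function(config = default_run_config(), dry_run = FALSE,
                         verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  objs <- run_config_to_objects(config)
  if (dry_run) {
    if (verbose) cat("configuration valid (dry run)\n")
    return(invisible(list(config = config)))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(config$out_dir, "config.yaml"))
  say <- function(...) if (verbose) cat("[cetaclass] ", sprintf(...), "\n", sep = "")

  say("generating %d classes x %d records",
      config$generation$n_classes, config$generation$n_per_class)
  specs <- default_class_specs(config$generation$n_classes,
                               snr_db = config$generation$snr_db)
  manifest <- generate_dataset(specs, config$generation$n_per_class,
                               duration_s = config$generation$duration_s,
                               sample_rate = config$generation$sample_rate,
                               out_dir = file.path(config$out_dir, "audio"),
                               seed = config$seed)

  say("splitting %d records 70/20/10", nrow(manifest$entries))
  splits <- split_dataset(manifest, objs$split)
  for (nm in names(splits)) {
    write_manifest(splits[[nm]],
                   file.path(config$out_dir, paste0(nm, "_manifest.csv")))
  }

  say("featurizing")
  tr <- featurize_manifest(splits$train, objs$features)
  va <- featurize_manifest(splits$val, objs$features)
  te <- featurize_manifest(splits$test, objs$features)

  say("training (%d epochs)", objs$hyper$epochs)
  fit <- train_snnvae(tr$features, tr$labels, va$features, va$labels,
                      cfg = objs$encoder, hyper = objs$hyper,
                      seed = config$seed)
  write.csv(fit$history, file.path(config$out_dir, "history.csv"),
            row.names = FALSE)

  say("evaluating on %d test records", length(te$features))
  ev <- evaluate_model(fit, te$features, te$labels)
  write.csv(ev$confusion$counts,
            file.path(config$out_dir, "confusion.csv"))
  write.csv(round(ev$normalized, 4),
            file.path(config$out_dir, "confusion_normalized.csv"))

  last <- fit$history[nrow(fit$history), ]
  summary <- list(
    seed = config$seed,
    test_accuracy = ev$metrics$accuracy,
    val_accuracy = last$val_accuracy,
    loss = list(triplet = last$triplet, reconstruction = last$reconstruction,
                kl = last$kl, total = last$total)
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done: test accuracy %.3f", ev$metrics$accuracy)
  invisible(list(fit = fit, evaluation = ev, summary = summary,
                 splits = splits, manifest = manifest))
}
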