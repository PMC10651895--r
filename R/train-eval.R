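#' Dataset split configuration
#'
#' @param ratios Train/validation/test fractions summing to 1 (default
#'   0.70/0.20/0.10).
#' @param k Number of cross-validation folds (default 5).
#' @param seed Integer seed.
#' @param stratified Stratify the three-way split by class (default `TRUE`).
#' @return A `split_config` list.
#' @export
split_config <- function(ratios = c(train = 0.7, val = 0.2, test = 0.1),
                         k = 5, seed = 1, stratified = TRUE) {
  if (length(ratios) != 3 || abs(sum(ratios) - 1) > 1e-9 || any(ratios < 0)) {
    stop_arg("`ratios` must be three non-negative fractions summing to 1")
  }
  if (!is_count(k) || k < 2) stop_arg("`k` must be >= 2")
  structure(list(ratios = ratios, k = as.integer(k), seed = as.integer(seed),
                 stratified = stratified),
            class = "split_config")
}

# Largest-remainder apportionment of n records to the three ratios.
apportion <- function(n, ratios) {
  raw <- n * ratios
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Split a manifest into train/validation/test manifests
#'
#' Produces a disjoint, exhaustive partition; with stratification the
#' per-class proportions are within one record of the requested ratios.
#' Deterministic for a given seed.
#'
#' @param manifest A [dataset_manifest()].
#' @param cfg A [split_config()].
#' @return A list of three `dataset_manifest`s: `train`, `val`, `test`.
#' @export
split_dataset <- function(manifest, cfg = split_config()) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  entries <- manifest$entries
  assign_group <- function(idx) {
    counts <- apportion(length(idx), cfg$ratios)
    rep(c("train", "val", "test"), counts)
  }
  with_seed(cfg$seed, {
    group <- character(nrow(entries))
    if (cfg$stratified) {
      for (cl in unique(entries$label)) {
        idx <- which(entries$label == cl)
        if (length(idx) < sum(cfg$ratios > 0)) {
          stop_arg("class ", cl, " has too few records to stratify")
        }
        group[sample(idx)] <- assign_group(idx)
      }
    } else {
      group[sample.int(nrow(entries))] <- assign_group(seq_len(nrow(entries)))
    }
    lapply(c(train = "train", val = "val", test = "test"), function(g) {
      dataset_manifest(entries[group == g, , drop = FALSE],
                       seed = manifest$seed)
    })
  })
}

#' K-fold cross-validation folds
#'
#' Randomly divides the records into `k` subsets whose sizes differ by at
#' most one; each record is validation exactly once.
#'
#' @param manifest A [dataset_manifest()].
#' @param cfg A [split_config()] (uses `k` and `seed`).
#' @return A list of `k` lists, each with `train` and `val` manifests.
#' @export
kfold <- function(manifest, cfg = split_config()) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  n <- nrow(manifest$entries)
  if (n < cfg$k) stop_arg("fewer records than folds")
  with_seed(cfg$seed, {
    fold_id <- rep(seq_len(cfg$k), length.out = n)[sample.int(n)]
    lapply(seq_len(cfg$k), function(f) {
      list(train = dataset_manifest(
             manifest$entries[fold_id != f, , drop = FALSE], manifest$seed),
           val = dataset_manifest(
             manifest$entries[fold_id == f, , drop = FALSE], manifest$seed))
    })
  })
}

#' Training hyperparameters
#'
#' Desk-scale defaults (batch 32 images => 10 triplets per step is typical,
#' 30 epochs); `full_scale = TRUE` switches to the full configuration
#' (batch 256, 200 epochs).
#'
#' @param epochs Training epochs.
#' @param batch_triplets Triplets per optimizer step.
#' @param lr Adam learning rate.
#' @param alpha Triplet margin.
#' @param beta KL weight.
#' @param full_scale Use the full-scale batch/epoch configuration.
#' @return A `train_hyper` list.
#' @export
train_hyper <- function(epochs = 30, batch_triplets = 16, lr = 1e-3,
                        alpha = 0.2, beta = 1.0, full_scale = FALSE) {
  if (full_scale) {
    epochs <- 200
    batch_triplets <- 256 %/% 3
  }
  structure(list(epochs = as.integer(epochs),
                 batch_triplets = as.integer(batch_triplets), lr = lr,
                 alpha = alpha, beta = beta),
            class = "train_hyper")
}

# One optimizer step on a batch of triplets. Returns per-term losses (as
# logged: triplet batch-summed, reconstruction and KL averaged over the
# three branch inputs), parameter grads, and BN running-stat updates.
snnvae_batch <- function(model, XA, XP, XN, alpha, beta, eps_mat) {
  B <- dim(XA)[4]
  d <- dim(XA)
  X <- array(0, c(d[1], d[2], d[3], 3 * B))
  X[, , , seq_len(B)] <- XA
  X[, , , B + seq_len(B)] <- XP
  X[, , , 2 * B + seq_len(B)] <- XN
  enc <- enc_forward(model, X, mode = "train")
  Mu <- enc$mean
  LV <- enc$logvar
  V <- exp(LV)
  iA <- seq_len(B); iP <- B + iA; iN <- 2 * B + iA

  # triplet term on the latent means (batch sum)
  dAP <- rowSums((Mu[iA, , drop = FALSE] - Mu[iP, , drop = FALSE])^2)
  dAN <- rowSums((Mu[iA, , drop = FALSE] - Mu[iN, , drop = FALSE])^2)
  active <- (dAP - dAN + alpha) > 0
  l_triplet <- sum(pmax(dAP - dAN + alpha, 0))
  dMu <- Mu * 0
  if (any(active)) {
    a <- which(active)
    dMu[iA[a], ] <- dMu[iA[a], ] +
      2 * (Mu[iN[a], , drop = FALSE] - Mu[iP[a], , drop = FALSE])
    dMu[iP[a], ] <- dMu[iP[a], ] -
      2 * (Mu[iA[a], , drop = FALSE] - Mu[iP[a], , drop = FALSE])
    dMu[iN[a], ] <- dMu[iN[a], ] +
      2 * (Mu[iA[a], , drop = FALSE] - Mu[iN[a], , drop = FALSE])
  }

  # KL term, averaged over the 3B branch images
  n_im <- 3 * B
  l_kl <- mean(0.5 * rowSums(V - LV - 1 + Mu^2))
  dMu <- dMu + beta * Mu / n_im
  dLV <- beta * 0.5 * (V - 1) / n_im

  # reconstruction of each branch's own input through the sampled latent
  Z <- Mu + eps_mat * sqrt(V)
  dec <- dec_forward(model, Z)
  resid <- dec$out - X
  l_recon <- mean(resid^2)
  dXhat <- 2 * resid / length(resid)
  dbk <- dec_backward(model, dec$cache, dXhat)
  dMu <- dMu + dbk$dz
  dLV <- dLV + dbk$dz * eps_mat * 0.5 * sqrt(V)

  ebk <- enc_backward(model, enc$cache, dMu, dLV)
  list(losses = c(triplet = l_triplet, reconstruction = l_recon, kl = l_kl),
       grads = list(encoder = ebk$grads, decoder = dbk$grads),
       bn_updates = enc$updates)
}

apply_bn_updates <- function(model, updates) {
  for (i in seq_along(updates)) {
    u <- updates[[i]]
    if (is.null(u)) next
    for (nm in names(u)) {
      if (is.null(u[[nm]])) next
      model$encoder$blocks[[i]][[nm]]$running_mean <- u[[nm]]$running_mean
      model$encoder$blocks[[i]][[nm]]$running_var <- u[[nm]]$running_var
    }
  }
  model
}

#' Train the Siamese VAE on featurized records
#'
#' Each epoch embeds the training images, mines semi-hard triplets, and
#' takes Adam steps on the combined objective
#' `triplet + reconstruction + beta * KL`. Validation accuracy is computed
#' per epoch by nearest-centroid classification in the latent space. Fully
#' seeded; raises a mining error before epoch 1 if the training set has a
#' single class.
#'
#' @param train_features List of `rgb_spectrogram`s (training set).
#' @param train_labels Class label per training feature.
#' @param val_features,val_labels Optional validation set.
#' @param cfg An [encoder_config()].
#' @param hyper A [train_hyper()].
#' @param seed Integer seed.
#' @param verbose Print per-epoch losses.
#' @return A `snnvae_fit`: the trained `model`, fitted `centroids`, and a
#'   `history` data.frame with columns epoch, triplet, reconstruction, kl,
#'   total, val_accuracy.
#' @export
train_snnvae <- function(train_features, train_labels, val_features = NULL,
                         val_labels = NULL, cfg = desk_encoder_config(),
                         hyper = train_hyper(), seed = 1, verbose = FALSE) {
  n <- length(train_features)
  if (n != length(train_labels)) stop_arg("features/labels length mismatch")
  if (length(unique(train_labels)) < 2) {
    stop("mining error: training set has a single class", call. = FALSE)
  }
  model <- snnvae(cfg, seed = seed)
  X_all <- stack_batch(train_features)
  X_val <- if (!is.null(val_features) && length(val_features) > 0) {
    stack_batch(val_features)
  }
  adam_state <- NULL
  t_step <- 0
  L <- cfg$latent_dim
  history <- vector("list", hyper$epochs)

  for (ep in seq_len(hyper$epochs)) {
    emb <- enc_forward(model, X_all, mode = "train")$mean
    triplets <- mine_semi_hard(emb, train_labels, alpha = hyper$alpha,
                               seed = derive_seed(seed, ep))
    order_idx <- with_seed(derive_seed(seed, ep, 7), sample.int(nrow(triplets)))
    triplets <- triplets[order_idx, , drop = FALSE]
    n_tr <- nrow(triplets)
    batch_starts <- seq(1, n_tr, by = hyper$batch_triplets)
    ep_losses <- c(triplet = 0, reconstruction = 0, kl = 0)
    for (bs in seq_along(batch_starts)) {
      idx <- batch_starts[bs]:min(batch_starts[bs] + hyper$batch_triplets - 1,
                                  n_tr)
      tb <- triplets[idx, , drop = FALSE]
      XA <- X_all[, , , tb$anchor, drop = FALSE]
      XP <- X_all[, , , tb$positive, drop = FALSE]
      XN <- X_all[, , , tb$negative, drop = FALSE]
      eps_mat <- with_seed(derive_seed(seed, ep, bs),
                           matrix(rnorm(3 * length(idx) * L),
                                  3 * length(idx), L))
      step <- snnvae_batch(model, XA, XP, XN, hyper$alpha, hyper$beta, eps_mat)
      model <- apply_bn_updates(model, step$bn_updates)
      t_step <- t_step + 1
      upd <- adam_step(list(encoder = model$encoder, decoder = model$decoder),
                       step$grads, adam_state, hyper$lr, t_step)
      model$encoder <- upd$p$encoder
      model$decoder <- upd$p$decoder
      adam_state <- upd$s
      w <- length(idx) / n_tr
      ep_losses <- ep_losses + c(step$losses["triplet"],
                                 step$losses["reconstruction"] * w,
                                 step$losses["kl"] * w)
    }
    emb_tr <- enc_forward(model, X_all, mode = "infer")$mean
    centroids <- fit_centroids(emb_tr, train_labels)
    val_acc <- NA_real_
    if (!is.null(X_val)) {
      emb_val <- enc_forward(model, X_val, mode = "infer")$mean
      pred <- vapply(seq_len(nrow(emb_val)),
                     function(i) classify(emb_val[i, ], centroids)$label, "")
      val_acc <- mean(pred == val_labels)
    }
    lb <- total_loss(ep_losses["triplet"], ep_losses["reconstruction"],
                     ep_losses["kl"], beta = hyper$beta, alpha = hyper$alpha)
    history[[ep]] <- data.frame(epoch = ep, triplet = lb$triplet,
                                reconstruction = lb$reconstruction,
                                kl = lb$kl, total = lb$total,
                                val_accuracy = val_acc)
    if (verbose) {
      cat(sprintf("epoch %3d  triplet %.4f  recon %.4f  kl %.4f  total %.4f  val %.3f\n",
                  ep, lb$triplet, lb$reconstruction, lb$kl, lb$total, val_acc))
    }
  }
  emb_tr <- enc_forward(model, X_all, mode = "infer")$mean
  structure(
    list(model = model, centroids = fit_centroids(emb_tr, train_labels),
         history = do.call(rbind, history), seed = seed, hyper = hyper),
    class = "snnvae_fit"
  )
}

#' @export
print.snnvae_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<snnvae_fit> %d epochs, final total loss %.4f, val acc %s\n",
              nrow(x$history), last$total,
              ifelse(is.na(last$val_accuracy), "NA",
                     sprintf("%.3f", last$val_accuracy))))
  invisible(x)
}

#' Predict class labels for featurized records
#'
#' @param fit An `snnvae_fit`.
#' @param features List of `rgb_spectrogram`s (or a batch array).
#' @return Character vector of predicted labels.
#' @export
predict_labels <- function(fit, features) {
  stopifnot(inherits(fit, "snnvae_fit"))
  emb <- embed_batch(fit$model, features)
  vapply(seq_len(nrow(emb)),
         function(i) classify(emb[i, ], fit$centroids)$label, "")
}

#' Evaluate a fitted model on labeled features
#'
#' @param fit An `snnvae_fit`.
#' @param features List of `rgb_spectrogram`s.
#' @param labels True class label per feature.
#' @return A list with the raw `confusion` matrix (rows = true class), the
#'   row-stochastic `normalized` matrix, and the `metrics` report.
#' @export
evaluate_model <- function(fit, features, labels) {
  if (any(is.na(labels)) || is.null(labels)) stop_arg("labels required")
  pred <- predict_labels(fit, features)
  cm <- confusion_matrix(labels, pred,
                         class_names = sort(unique(c(labels,
                                                     rownames(fit$centroids)))))
  rs <- rowSums(cm$counts)
  normalized <- cm$counts / ifelse(rs == 0, 1, rs)
  list(confusion = cm, normalized = normalized,
       metrics = metrics_from_confusion(cm))
}

#' Build a confusion matrix
#'
#' @param truth True labels.
#' @param pred Predicted labels.
#' @param class_names Class universe (default: union of labels).
#' @return A `confusion_matrix` with integer `counts` (rows = true class,
#'   columns = predicted class) and `class_names`.
#' @export
confusion_matrix <- function(truth, pred, class_names = NULL) {
  if (length(truth) != length(pred)) stop_arg("truth/pred length mismatch")
  if (is.null(class_names)) class_names <- sort(unique(c(truth, pred)))
  counts <- table(factor(truth, levels = class_names),
                  factor(pred, levels = class_names))
  counts <- matrix(as.integer(counts), nrow = length(class_names),
                   dimnames = list(true = class_names, pred = class_names))
  structure(list(counts = counts, class_names = class_names),
            class = "confusion_matrix")
}

#' Accuracy, precision, and recall from a confusion matrix
#'
#' Accuracy is `trace/total`; per-class precision `TP/(TP+FP)` and recall
#' `TP/(TP+FN)` come from one-vs-rest marginalization. A class never
#' predicted has undefined precision, reported as 0 with a warning flag.
#'
#' @param cm A [confusion_matrix()].
#' @return A `metrics_report` with `accuracy`, `precision`, `recall`, and
#'   `undefined_precision` flags.
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  counts <- cm$counts
  total <- sum(counts)
  if (total == 0) stop_arg("empty confusion matrix")
  tp <- diag(counts)
  col_tot <- colSums(counts)
  row_tot <- rowSums(counts)
  undefined <- col_tot == 0
  precision <- ifelse(undefined, 0, tp / pmax(col_tot, 1))
  recall <- ifelse(row_tot == 0, 0, tp / pmax(row_tot, 1))
  structure(list(accuracy = sum(tp) / total,
                 precision = setNames(precision, cm$class_names),
                 recall = setNames(recall, cm$class_names),
                 undefined_precision = setNames(undefined, cm$class_names)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> accuracy %.4f\n", x$accuracy))
  print(data.frame(precision = round(x$precision, 4),
                   recall = round(x$recall, 4)))
  invisible(x)
}

#' Featurize every record in a manifest
#'
#' @param manifest A [dataset_manifest()].
#' @param cfg A [featurize_config()].
#' @return List with `features` (list of `rgb_spectrogram`s) and `labels`.
#' @export
featurize_manifest <- function(manifest, cfg = featurize_config()) {
  feats <- lapply(seq_len(nrow(manifest$entries)), function(i) {
    rec <- read_wav(manifest$entries$path[i],
                    label = manifest$entries$label[i])
    featurize_record(rec, cfg, source_path = manifest$entries$path[i])
  })
  list(features = feats, labels = manifest$entries$label)
}
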