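#' Encoder configuration for the Siamese VAE
#'
#' The encoder is a stack of re-parameterizable convolution stages: during
#' training each block runs parallel 3x3, 1x1, and (for stride-1 blocks with
#' equal channel counts) identity branches, each followed by batch
#' normalization, summed and passed through ReLU; for inference the branches
#' fuse into a single 3x3 convolution ([fuse_branches()]). The first block
#' of every stage uses stride 2 and there is no pooling, so each stage
#' halves the spatial size. A dense head maps the final feature map to the
#' latent mean and log-variance.
#'
#' @param n_stages Number of stride-2 stages; `image_size` must be divisible
#'   by `2^n_stages`.
#' @param stage_widths Channel count per stage (length `n_stages`).
#' @param latent_dim Latent dimension (default 128).
#' @param image_size Input image side in pixels.
#' @param blocks_per_stage Blocks per stage; blocks after the first use
#'   stride 1 and carry an identity branch.
#' @param mode `"train_multibranch"` or `"inference_fused"`.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(n_stages = 4, stage_widths = c(16, 32, 64, 128),
                           latent_dim = 128, image_size = 128,
                           blocks_per_stage = 1,
                           mode = c("train_multibranch", "inference_fused")) {
  mode <- match.arg(mode)
  if (length(stage_widths) != n_stages || any(stage_widths < 1)) {
    stop_arg("`stage_widths` must have `n_stages` positive entries")
  }
  if (!is_count(latent_dim) || latent_dim < 2) stop_arg("`latent_dim` must be >= 2")
  if (image_size %% 2^n_stages != 0) {
    stop_arg("`image_size` must be divisible by 2^n_stages")
  }
  structure(list(n_stages = n_stages, stage_widths = as.integer(stage_widths),
                 latent_dim = as.integer(latent_dim),
                 image_size = as.integer(image_size),
                 blocks_per_stage = as.integer(blocks_per_stage), mode = mode),
            class = "encoder_config")
}

#' A small desk-scale encoder configuration
#'
#' 64-pixel inputs, narrow stages, and a 32-dimensional latent space:
#' enough capacity to separate the synthetic classes while training in
#' seconds on one CPU.
#'
#' @return An `encoder_config`.
#' @export
desk_encoder_config <- function() {
  encoder_config(n_stages = 4, stage_widths = c(8, 16, 32, 64),
                 latent_dim = 32, image_size = 64)
}

.bn_eps <- 1e-5

new_block <- function(in_ch, out_ch, stride) {
  has_id <- stride == 1 && in_ch == out_ch
  list(fused = FALSE, in_ch = in_ch, out_ch = out_ch, stride = stride,
       has_id = has_id,
       conv3 = list(W = he_init(c(3, 3, in_ch, out_ch), 9 * in_ch),
                    b = rep(0, out_ch)),
       bn3 = bn_init(out_ch),
       conv1 = list(W = he_init(c(1, 1, in_ch, out_ch), in_ch),
                    b = rep(0, out_ch)),
       bn1 = bn_init(out_ch),
       bnid = if (has_id) bn_init(out_ch) else NULL)
}

#' Construct an untrained Siamese VAE
#'
#' Builds the shared encoder (multi-branch convolution stages + latent
#' heads) and the mirrored decoder (dense projection, nearest-neighbor
#' upsampling + 3x3 convolutions, sigmoid output). All Siamese branches
#' share these weights by construction.
#'
#' @param cfg An [encoder_config()].
#' @param seed Integer seed for weight initialization.
#' @return An `snnvae` model object.
#' @export
snnvae <- function(cfg = encoder_config(), seed = 1) {
  stopifnot(inherits(cfg, "encoder_config"))
  with_seed(seed, {
    blocks <- list()
    in_ch <- 3L
    for (s in seq_len(cfg$n_stages)) {
      for (b in seq_len(cfg$blocks_per_stage)) {
        stride <- if (b == 1) 2L else 1L
        blocks[[length(blocks) + 1]] <- new_block(in_ch, cfg$stage_widths[s],
                                                  stride)
        in_ch <- cfg$stage_widths[s]
      }
    }
    f_side <- cfg$image_size %/% 2^cfg$n_stages
    D <- f_side^2 * cfg$stage_widths[cfg$n_stages]
    L <- cfg$latent_dim
    enc_head <- list(W = matrix(rnorm(D * 2 * L, sd = 1 / sqrt(D)), D, 2 * L),
                     b = rep(0, 2 * L))
    dec_head <- list(W = matrix(rnorm(L * D, sd = 1 / sqrt(L)), L, D),
                     b = rep(0, D))
    dec_in <- rev(cfg$stage_widths)
    dec_out <- c(rev(cfg$stage_widths)[-1], 3L)
    dec_convs <- lapply(seq_len(cfg$n_stages), function(s) {
      list(W = he_init(c(3, 3, dec_in[s], dec_out[s]), 9 * dec_in[s]),
           b = rep(0, dec_out[s]))
    })
    structure(
      list(cfg = cfg, f_side = f_side,
           encoder = list(blocks = blocks, head = enc_head),
           decoder = list(head = dec_head, convs = dec_convs)),
      class = "snnvae"
    )
  })
}

#' @export
print.snnvae <- function(x, ...) {
  cat(sprintf(
    "<snnvae> %d-stage encoder (%s), latent %d, image %d, mode %s\n",
    x$cfg$n_stages, paste(x$cfg$stage_widths, collapse = ","),
    x$cfg$latent_dim, x$cfg$image_size, x$cfg$mode
  ))
  invisible(x)
}

block_forward <- function(block, x, mode = "train") {
  if (block$fused) {
    cv <- conv_forward(x, block$W, block$b, stride = block$stride, pad = 1)
    rl <- relu_forward(cv$out)
    return(list(out = rl$out,
                cache = list(fused = TRUE, conv = cv$cache, relu = rl$cache),
                updates = NULL))
  }
  c3 <- conv_forward(x, block$conv3$W, block$conv3$b, block$stride, pad = 1)
  b3 <- bn_forward(c3$out, block$bn3, mode, eps = .bn_eps)
  c1 <- conv_forward(x, block$conv1$W, block$conv1$b, block$stride, pad = 0)
  b1 <- bn_forward(c1$out, block$bn1, mode, eps = .bn_eps)
  s <- b3$out + b1$out
  bid <- NULL
  if (block$has_id) {
    bid <- bn_forward(x, block$bnid, mode, eps = .bn_eps)
    s <- s + bid$out
  }
  rl <- relu_forward(s)
  list(out = rl$out,
       cache = list(fused = FALSE, c3 = c3$cache, b3 = b3$cache,
                    c1 = c1$cache, b1 = b1$cache,
                    bid = if (is.null(bid)) NULL else bid$cache,
                    relu = rl$cache),
       updates = list(bn3 = b3$updates, bn1 = b1$updates,
                      bnid = if (is.null(bid)) NULL else bid$updates))
}

block_backward <- function(block, cache, dout) {
  ds <- relu_backward(dout, cache$relu)
  if (cache$fused) {
    cb <- conv_backward(ds, block$W, cache$conv)
    return(list(dx = cb$dx, grads = list(W = cb$dW, b = cb$db)))
  }
  g <- list()
  bb3 <- bn_backward(ds, block$bn3, cache$b3)
  cb3 <- conv_backward(bb3$dx, block$conv3$W, cache$c3)
  bb1 <- bn_backward(ds, block$bn1, cache$b1)
  cb1 <- conv_backward(bb1$dx, block$conv1$W, cache$c1)
  dx <- cb3$dx + cb1$dx
  g$conv3 <- list(W = cb3$dW, b = cb3$db)
  g$bn3 <- list(gamma = bb3$dgamma, beta = bb3$dbeta)
  g$conv1 <- list(W = cb1$dW, b = cb1$db)
  g$bn1 <- list(gamma = bb1$dgamma, beta = bb1$dbeta)
  if (block$has_id) {
    bbid <- bn_backward(ds, block$bnid, cache$bid)
    dx <- dx + bbid$dx
    g$bnid <- list(gamma = bbid$dgamma, beta = bbid$dbeta)
  }
  list(dx = dx, grads = g)
}

# Full encoder pass. x: (H, W, 3, N). Returns mean/logvar (N x latent) plus
# caches for the backward pass and any batch-norm running-stat updates.
enc_forward <- function(model, x, mode = "train") {
  caches <- list()
  updates <- list()
  h <- x
  for (i in seq_along(model$encoder$blocks)) {
    r <- block_forward(model$encoder$blocks[[i]], h, mode)
    caches[[i]] <- r$cache
    updates[[i]] <- r$updates
    h <- r$out
  }
  d <- dim(h)
  flat <- t(matrix(h, prod(d[1:3]), d[4]))
  hd <- dense_forward(flat, model$encoder$head$W, model$encoder$head$b)
  L <- model$cfg$latent_dim
  raw_lv <- hd$out[, L + seq_len(L), drop = FALSE]
  list(mean = hd$out[, seq_len(L), drop = FALSE],
       logvar = clamp(raw_lv, -10, 10),
       cache = list(blocks = caches, dense = hd$cache, fdims = d,
                    lv_open = raw_lv > -10 & raw_lv < 10),
       updates = updates)
}

enc_backward <- function(model, cache, dmean, dlogvar) {
  dout <- cbind(dmean, dlogvar * cache$lv_open)
  db <- dense_backward(dout, model$encoder$head$W, cache$dense)
  grads <- list(head = list(W = db$dW, b = db$db), blocks = list())
  dh <- array(t(db$dx), cache$fdims)
  for (i in rev(seq_along(model$encoder$blocks))) {
    bb <- block_backward(model$encoder$blocks[[i]], cache$blocks[[i]], dh)
    grads$blocks[[i]] <- bb$grads
    dh <- bb$dx
  }
  list(grads = grads, dx = dh)
}

# Decoder pass. z: (N x latent). Returns xhat (H, W, 3, N) + caches.
dec_forward <- function(model, z) {
  hd <- dense_forward(z, model$decoder$head$W, model$decoder$head$b)
  f <- model$f_side
  C <- model$cfg$stage_widths[model$cfg$n_stages]
  N <- nrow(z)
  h <- array(t(hd$out), c(f, f, C, N))
  rl0 <- relu_forward(h)
  h <- rl0$out
  caches <- list()
  n_up <- model$cfg$n_stages
  for (s in seq_len(n_up)) {
    up <- upsample2_forward(h)
    cv <- conv_forward(up, model$decoder$convs[[s]]$W,
                       model$decoder$convs[[s]]$b, stride = 1, pad = 1)
    if (s < n_up) {
      act <- relu_forward(cv$out)
    } else {
      act <- sigmoid_forward(cv$out)
    }
    caches[[s]] <- list(conv = cv$cache, act = act$cache)
    h <- act$out
  }
  list(out = h, cache = list(dense = hd$cache, relu0 = rl0$cache,
                             stages = caches, f = f, C = C, N = N))
}

dec_backward <- function(model, cache, dout) {
  n_up <- model$cfg$n_stages
  grads <- list(convs = list())
  dh <- dout
  for (s in rev(seq_len(n_up))) {
    dact <- if (s < n_up) relu_backward(dh, cache$stages[[s]]$act)
            else sigmoid_backward(dh, cache$stages[[s]]$act)
    cb <- conv_backward(dact, model$decoder$convs[[s]]$W,
                        cache$stages[[s]]$conv)
    grads$convs[[s]] <- list(W = cb$dW, b = cb$db)
    dh <- upsample2_backward(cb$dx)
  }
  dh <- relu_backward(dh, cache$relu0)
  dflat <- t(matrix(dh, cache$f * cache$f * cache$C, cache$N))
  db <- dense_backward(dflat, model$decoder$head$W, cache$dense)
  grads$head <- list(W = db$dW, b = db$db)
  list(grads = grads, dz = db$dx)
}

as_pixel_array <- function(image, image_size = NULL) {
  px <- if (inherits(image, "rgb_spectrogram")) image$pixels else image
  if (length(dim(px)) == 3) dim(px) <- c(dim(px), 1L)
  if (length(dim(px)) != 4 || dim(px)[3] != 3) {
    stop_arg("expected an H x W x 3 image (or a batch of them)")
  }
  if (!is.null(image_size) &&
      (dim(px)[1] != image_size || dim(px)[2] != image_size)) {
    stop_arg("image size ", dim(px)[1], "x", dim(px)[2],
             " does not match the configured size ", image_size)
  }
  px
}

#' Encode an image to its latent distribution
#'
#' Runs the shared encoder in inference mode (batch-norm running statistics,
#' no sampling), returning the diagonal Gaussian the VAE places over the
#' latent space: a mean vector and a strictly positive variance vector, the
#' latter produced through an exponentiated (clamped) log-variance head.
#'
#' @param model An [snnvae()] model.
#' @param image An `rgb_spectrogram` or `H x W x 3` array matching the
#'   configured image size.
#' @return A `latent_distribution` with fields `mean` and `variance`.
#' @export
encode <- function(model, image) {
  stopifnot(inherits(model, "snnvae"))
  x <- as_pixel_array(image, model$cfg$image_size)
  r <- enc_forward(model, x, mode = "infer")
  latent_distribution(drop(r$mean), exp(drop(r$logvar)))
}

#' Construct a latent distribution
#'
#' @param mean Numeric mean vector.
#' @param variance Strictly positive variance vector of the same length.
#' @return A `latent_distribution`.
#' @export
latent_distribution <- function(mean, variance) {
  if (length(mean) != length(variance)) stop_arg("mean/variance length mismatch")
  if (!all(is.finite(mean)) || !all(is.finite(variance))) {
    stop_arg("latent moments must be finite")
  }
  if (any(variance <= 0)) stop_arg("variance must be strictly positive")
  structure(list(mean = as.double(mean), variance = as.double(variance)),
            class = "latent_distribution")
}

#' Sample a latent vector by the reparameterization trick
#'
#' `z = mean + eps * sqrt(variance)` elementwise, with
#' `eps ~ N(0, I)` drawn under `seed` when not supplied.
#'
#' @param dist A [latent_distribution()].
#' @param eps Optional standard-normal vector shaped like `mean`.
#' @param seed Seed used to draw `eps` when it is not supplied.
#' @return A latent vector `z`.
#' @export
sample_latent <- function(dist, eps = NULL, seed = 1) {
  stopifnot(inherits(dist, "latent_distribution"))
  if (is.null(eps)) {
    eps <- with_seed(seed, rnorm(length(dist$mean)))
  }
  if (length(eps) != length(dist$mean)) stop_arg("`eps` shape mismatch")
  dist$mean + eps * sqrt(dist$variance)
}

#' Kullback-Leibler divergence to the standard normal
#'
#' For a diagonal Gaussian with mean `E(z)` and variance `V(z)`:
#' `KL = 1/2 sum_i (V_i - log V_i - 1 + E_i^2)`, which is non-negative and
#' zero exactly at the standard normal.
#'
#' @param dist A [latent_distribution()].
#' @return A non-negative scalar.
#' @export
kl_divergence <- function(dist) {
  stopifnot(inherits(dist, "latent_distribution"))
  0.5 * sum(dist$variance - log(dist$variance) - 1 + dist$mean^2)
}

#' Reconstruction loss (mean squared error)
#'
#' The `||x - xhat||^2` term of the VAE objective, under mean reduction over
#' all pixels and channels.
#'
#' @param x,x_hat Images (`rgb_spectrogram` or arrays) of identical shape.
#' @return A non-negative scalar.
#' @export
reconstruction_loss <- function(x, x_hat) {
  a <- if (inherits(x, "rgb_spectrogram")) x$pixels else x
  b <- if (inherits(x_hat, "rgb_spectrogram")) x_hat$pixels else x_hat
  if (!identical(dim(a), dim(b))) stop_arg("shape mismatch")
  mean((a - b)^2)
}

#' Triplet hinge loss over embedding batches
#'
#' `sum_i max(||f(A_i)-f(P_i)||^2 - ||f(A_i)-f(N_i)||^2 + alpha, 0)`,
#' using squared Euclidean distances on the embeddings.
#'
#' @param fA,fP,fN Embedding vectors, or matrices with one triplet per row.
#' @param alpha Non-negative margin.
#' @return The batch-summed hinge value.
#' @export
triplet_loss <- function(fA, fP, fN, alpha = 0.2) {
  if (is.null(dim(fA))) fA <- matrix(fA, 1)
  if (is.null(dim(fP))) fP <- matrix(fP, 1)
  if (is.null(dim(fN))) fN <- matrix(fN, 1)
  if (!identical(dim(fA), dim(fP)) || !identical(dim(fA), dim(fN))) {
    stop_arg("embedding shape mismatch")
  }
  if (alpha < 0) stop_arg("`alpha` must be >= 0")
  d_ap <- rowSums((fA - fP)^2)
  d_an <- rowSums((fA - fN)^2)
  sum(pmax(d_ap - d_an + alpha, 0))
}

#' Combine the SNN-VAE loss terms
#'
#' `total = triplet + reconstruction + beta * kl`, reported with its
#' breakdown.
#'
#' @param triplet,reconstruction,kl Non-negative component values.
#' @param beta KL weight.
#' @param alpha Triplet margin (carried for reporting).
#' @return A `loss_breakdown` list with fields `triplet`, `reconstruction`,
#'   `kl`, `beta`, `alpha`, `total`.
#' @export
total_loss <- function(triplet, reconstruction, kl, beta = 1, alpha = 0.2) {
  if (any(c(triplet, reconstruction, kl) < 0)) {
    stop_arg("loss components must be >= 0")
  }
  structure(list(triplet = triplet, reconstruction = reconstruction, kl = kl,
                 beta = beta, alpha = alpha,
                 total = triplet + reconstruction + beta * kl),
            class = "loss_breakdown")
}

#' Mine semi-hard triplets from labeled embeddings
#'
#' For each anchor with at least one same-class partner, the positive is a
#' seeded random same-class sample and the negative is chosen inside the
#' semi-hard window `d(A,P) < d(A,N) < d(A,P) + alpha` (the closest such
#' negative); when no negative falls in the window, the hardest (closest)
#' negative is used instead.
#'
#' @param embeddings Matrix with one embedding per row.
#' @param labels Class label per row.
#' @param alpha Triplet margin.
#' @param seed Seed for positive selection.
#' @return A `triplet_batch`: data.frame with columns `anchor`, `positive`,
#'   `negative` (row indices) and `label`.
#' @export
mine_semi_hard <- function(embeddings, labels, alpha = 0.2, seed = 1) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  if (length(labels) != n) stop_arg("labels/embeddings mismatch")
  tab <- table(labels)
  if (length(tab) < 2 || max(tab) < 2) {
    stop("mining error: need >= 2 classes and a class with >= 2 samples",
         call. = FALSE)
  }
  sq <- rowSums(embeddings^2)
  D <- outer(sq, sq, `+`) - 2 * tcrossprod(embeddings)
  D <- pmax(D, 0)
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(n)) {
      same <- which(labels == labels[i])
      same <- setdiff(same, i)
      if (length(same) == 0) next
      p <- same[sample.int(length(same), 1)]
      neg <- which(labels != labels[i])
      d_ap <- D[i, p]
      d_an <- D[i, neg]
      window <- d_an > d_ap & d_an < d_ap + alpha
      j <- if (any(window)) {
        cand <- neg[window]
        cand[which.min(D[i, cand])]
      } else {
        neg[which.min(d_an)]
      }
      rows[[length(rows) + 1]] <- data.frame(anchor = i, positive = p,
                                             negative = j,
                                             label = labels[i],
                                             stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    class(out) <- c("triplet_batch", class(out))
    out
  })
}

#' Fuse a multi-branch block into a single 3x3 convolution
#'
#' Folds each branch's batch normalization (running statistics) into its
#' convolution weights, zero-pads the 1x1 kernel into the center of a 3x3
#' kernel, expresses the identity branch as a Dirac kernel, and sums. The
#' fused convolution reproduces the multi-branch inference output for every
#' input up to float tolerance. Fusing an already-fused block is a no-op.
#'
#' @param block A block from an [snnvae()] encoder.
#' @return The fused block (single `W`, `b`, `stride`).
#' @export
fuse_branches <- function(block) {
  if (isTRUE(block$fused)) return(block)
  Cin <- block$in_ch; Cout <- block$out_ch
  fold <- function(W, b, bn) {
    scale <- bn$gamma / sqrt(bn$running_var + .bn_eps)
    Ws <- sweep(W, 4, scale, `*`)
    bs <- bn$beta + (b - bn$running_mean) * scale
    list(W = Ws, b = bs)
  }
  f3 <- fold(block$conv3$W, block$conv3$b, block$bn3)
  W1pad <- array(0, c(3, 3, Cin, Cout))
  W1pad[2, 2, , ] <- block$conv1$W[1, 1, , ]
  f1 <- fold(W1pad, block$conv1$b, block$bn1)
  W <- f3$W + f1$W
  b <- f3$b + f1$b
  if (block$has_id) {
    Wid <- array(0, c(3, 3, Cin, Cout))
    for (c in seq_len(Cin)) Wid[2, 2, c, c] <- 1
    fid <- fold(Wid, rep(0, Cout), block$bnid)
    W <- W + fid$W
    b <- b + fid$b
  }
  list(fused = TRUE, in_ch = Cin, out_ch = Cout, stride = block$stride,
       W = W, b = b)
}

#' Fuse every encoder block for single-branch inference
#'
#' @param model An [snnvae()] model.
#' @return The model with all blocks fused and `mode = "inference_fused"`.
#' @export
fuse_model <- function(model) {
  stopifnot(inherits(model, "snnvae"))
  model$encoder$blocks <- lapply(model$encoder$blocks, fuse_branches)
  model$cfg$mode <- "inference_fused"
  model
}

#' Decode a latent vector to an image
#'
#' @param model An [snnvae()] model.
#' @param z Latent vector of length `latent_dim`.
#' @return An `rgb_spectrogram` with pixels in `[0, 1]` (sigmoid output).
#' @export
decode <- function(model, z) {
  stopifnot(inherits(model, "snnvae"))
  if (length(z) != model$cfg$latent_dim) stop_arg("latent length mismatch")
  r <- dec_forward(model, matrix(z, 1))
  structure(list(pixels = array(r$out, dim(r$out)[1:3]), label = NULL,
                 source_path = NULL),
            class = "rgb_spectrogram")
}

#' Embed an image
#'
#' The embedding `f(.)` compared by the Siamese distances is the latent
#' mean, which is deterministic (no sampling at inference).
#'
#' @param model An [snnvae()] model.
#' @param image An `rgb_spectrogram` or `H x W x 3` array.
#' @return A numeric vector of length `latent_dim`.
#' @export
embed <- function(model, image) {
  encode(model, image)$mean
}

# Batch embedding: images as (H, W, 3, N) or list of rgb_spectrograms.
embed_batch <- function(model, images, mode = "infer") {
  x <- if (is.list(images) && !is.array(images)) {
    stack_batch(images)
  } else {
    as_pixel_array(images)
  }
  enc_forward(model, x, mode = mode)$mean
}

stack_batch <- function(images) {
  pxs <- lapply(images, function(im) as_pixel_array(im))
  d <- dim(pxs[[1]])
  out <- array(0, c(d[1], d[2], 3L, length(pxs)))
  for (i in seq_along(pxs)) out[, , , i] <- pxs[[i]][, , , 1]
  out
}

#' Fit per-class centroids in embedding space
#'
#' @param embeddings Matrix with one embedding per row.
#' @param labels Class label per row.
#' @return A matrix of per-class mean embeddings, rows ordered and named by
#'   sorted class name.
#' @export
fit_centroids <- function(embeddings, labels) {
  embeddings <- as.matrix(embeddings)
  classes <- sort(unique(labels))
  out <- t(vapply(classes, function(cl) {
    colMeans(embeddings[labels == cl, , drop = FALSE])
  }, numeric(ncol(embeddings))))
  rownames(out) <- classes
  out
}

#' Nearest-centroid classification with similarity scores
#'
#' Assigns the class of the nearest centroid (Euclidean distance); the score
#' is a softmin over centroid distances, in `[0, 1]`. Exact distance ties
#' break deterministically by class-name order.
#'
#' @param embedding Embedding vector (or matrix of rows).
#' @param centroids Centroid matrix from [fit_centroids()].
#' @return For a single embedding, a list with `label`, `score`, and the
#'   full `scores` vector; for a matrix, a character vector of labels.
#' @export
classify <- function(embedding, centroids) {
  if (is.null(centroids) || nrow(centroids) == 0) {
    stop("no fitted centroids available", call. = FALSE)
  }
  if (!is.null(dim(embedding)) && nrow(embedding) > 1) {
    return(apply(embedding, 1, function(e) classify(e, centroids)$label))
  }
  e <- as.numeric(embedding)
  d <- sqrt(rowSums(sweep(centroids, 2, e, `-`)^2))
  scores <- exp(-d) / sum(exp(-d))
  # rownames are sorted; which.min returns the first (earliest name) on ties
  k <- which.min(d)
  list(label = rownames(centroids)[k], score = scores[k],
       scores = setNames(scores, rownames(centroids)))
}
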