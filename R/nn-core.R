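# Minimal dense/convolutional layer kernels with explicit backprop, used by
# the Siamese VAE. Batches are arrays of dim (H, W, C, N); convolutions run
# through im2col gather + BLAS matrix multiply. All layers are plain R
# functions returning (output, cache) so the model module can assemble exact
# gradients for the combined objective.

.im2col_cache <- new.env(parent = emptyenv())

# Gather-index matrix (out_positions x k*k*C) into a zero-padded image,
# ordered to match matrix(W, k*k*C, Cout) flattening of (k, k, Cin, Cout).
im2col_indices <- function(H, W, C, k, stride, pad) {
  key <- paste(H, W, C, k, stride, pad, sep = "_")
  if (!is.null(.im2col_cache[[key]])) return(.im2col_cache[[key]])
  Hp <- H + 2 * pad
  Wp <- W + 2 * pad
  outH <- (Hp - k) %/% stride + 1L
  outW <- (Wp - k) %/% stride + 1L
  base <- c(outer(seq(1, by = stride, length.out = outH),
                  (seq(0, by = stride, length.out = outW)) * Hp, `+`))
  off <- c(outer(outer(0:(k - 1), (0:(k - 1)) * Hp, `+`),
                 (0:(C - 1)) * Hp * Wp, `+`))
  G <- outer(base, off, `+`)
  res <- list(G = G, outH = outH, outW = outW, Hp = Hp, Wp = Wp)
  .im2col_cache[[key]] <- res
  res
}

pad_batch <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

# x: (H, W, C, N); W: (k, k, Cin, Cout); returns (outH, outW, Cout, N).
conv_forward <- function(x, W, b, stride = 1, pad = 0) {
  d <- dim(x)
  k <- dim(W)[1]
  Cin <- dim(W)[3]
  Cout <- dim(W)[4]
  stopifnot(d[3] == Cin)
  ii <- im2col_indices(d[1], d[2], Cin, k, stride, pad)
  xp <- pad_batch(x, pad)
  N <- d[4]
  L <- ii$Hp * ii$Wp * Cin
  Xmat <- matrix(xp, L, N)
  outpos <- nrow(ii$G)
  kkC <- ncol(ii$G)
  P <- matrix(0, outpos * N, kkC)
  for (j in seq_len(kkC)) P[, j] <- Xmat[ii$G[, j], ]
  Wmat <- matrix(W, kkC, Cout)
  out <- P %*% Wmat
  out <- sweep(out, 2, b, `+`)
  out <- aperm(array(out, c(outpos, N, Cout)), c(1, 3, 2))
  dim(out) <- c(ii$outH, ii$outW, Cout, N)
  list(out = out,
       cache = list(P = P, dims = d, k = k, stride = stride, pad = pad,
                    Cout = Cout, ii = ii))
}

conv_backward <- function(dout, W, cache) {
  ii <- cache$ii
  d <- cache$dims
  Cin <- d[3]; N <- d[4]
  outpos <- ii$outH * ii$outW
  Cout <- cache$Cout
  dmat <- aperm(array(dout, c(outpos, Cout, N)), c(1, 3, 2))
  dim(dmat) <- c(outpos * N, Cout)
  kkC <- ncol(ii$G)
  dW <- crossprod(cache$P, dmat)
  dim(dW) <- c(cache$k, cache$k, Cin, Cout)
  db <- colSums(dmat)
  dP <- dmat %*% t(matrix(W, kkC, Cout))
  L <- ii$Hp * ii$Wp * Cin
  dXmat <- matrix(0, L, N)
  for (j in seq_len(kkC)) {
    dXmat[ii$G[, j], ] <- dXmat[ii$G[, j], ] + matrix(dP[, j], outpos, N)
  }
  dX <- array(dXmat, c(ii$Hp, ii$Wp, Cin, N))
  if (cache$pad > 0) {
    p <- cache$pad
    dX <- dX[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
  }
  list(dx = dX, dW = dW, db = db)
}

bn_init <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C),
       running_mean = rep(0, C), running_var = rep(1, C))
}

# Batch norm over (H, W, N) per channel; eps matches the fusion formulas.
bn_forward <- function(x, bn, mode = "train", momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  C <- d[3]
  xm <- aperm(x, c(1, 2, 4, 3))
  dim(xm) <- c(d[1] * d[2] * d[4], C)
  if (mode == "train") {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    v <- pmax(v, 0)
    upd <- list(running_mean = (1 - momentum) * bn$running_mean + momentum * mu,
                running_var = (1 - momentum) * bn$running_var + momentum * v)
  } else {
    mu <- bn$running_mean
    v <- bn$running_var
    upd <- NULL
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu, `-`), 2, invstd, `*`)
  ym <- sweep(sweep(xhat, 2, bn$gamma, `*`), 2, bn$beta, `+`)
  y <- array(ym, c(d[1], d[2], d[4], C))
  y <- aperm(y, c(1, 2, 4, 3))
  list(out = y,
       cache = list(xhat = xhat, invstd = invstd, dims = d, mode = mode),
       updates = upd)
}

bn_backward <- function(dout, bn, cache) {
  d <- cache$dims
  C <- d[3]
  m <- d[1] * d[2] * d[4]
  dm <- aperm(dout, c(1, 2, 4, 3))
  dim(dm) <- c(m, C)
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  dxhat <- sweep(dm, 2, bn$gamma, `*`)
  if (cache$mode == "train") {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dxm <- sweep(
      dxhat - sweep(cache$xhat, 2, s2 / m, `*`) -
        matrix(s1 / m, m, C, byrow = TRUE),
      2, cache$invstd, `*`
    )
  } else {
    dxm <- sweep(dxhat, 2, cache$invstd, `*`)
  }
  dx <- array(dxm, c(d[1], d[2], d[4], C))
  dx <- aperm(dx, c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(dout, cache) dout * cache

sigmoid_forward <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(out = s, cache = s)
}
sigmoid_backward <- function(dout, cache) dout * cache * (1 - cache)

dense_forward <- function(x, W, b) {
  list(out = sweep(x %*% W, 2, b, `+`), cache = x)
}
dense_backward <- function(dout, W, cache) {
  list(dx = dout %*% t(W), dW = crossprod(cache, dout), db = colSums(dout))
}

# Nearest-neighbor 2x upsampling of (H, W, C, N).
upsample2_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}
upsample2_backward <- function(dout) {
  d <- dim(dout)
  odd_r <- seq(1, d[1], by = 2); odd_c <- seq(1, d[2], by = 2)
  dout[odd_r, odd_c, , , drop = FALSE] +
    dout[odd_r + 1, odd_c, , , drop = FALSE] +
    dout[odd_r, odd_c + 1, , , drop = FALSE] +
    dout[odd_r + 1, odd_c + 1, , , drop = FALSE]
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

# Recursively apply an Adam step to nested parameter lists. state carries
# (m, v) mirrors of the parameter structure; returns updated params/state.
adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p)) {
      out_p <- p
      out_s <- s %||% vector("list", length(p))
      for (nm in names(p)) {
        res <- walk(p[[nm]], g[[nm]], s[[nm]])
        out_p[[nm]] <- res$p
        out_s[[nm]] <- res$s
      }
      return(list(p = out_p, s = out_s))
    }
    if (is.null(g)) return(list(p = p, s = s))
    if (is.null(s)) s <- list(m = p * 0, v = p * 0)
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }
  walk(params, grads, state)
}

# Elementwise sum of two grad structures (for accumulating branch grads).
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- grad_add(a[[nm]], b[[nm]])
    return(a)
  }
  a + b
}
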