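tiny_cfg <- function() {
  encoder_config(n_stages = 2, stage_widths = c(4, 8), latent_dim = 6,
                 image_size = 16)
}

rand_image <- function(seed, size = 16) {
  withr::with_seed(seed, array(runif(size * size * 3), c(size, size, 3)))
}

test_that("snnvae construction and encode/decode shapes are consistent", {
  m <- snnvae(tiny_cfg(), seed = 1)
  expect_s3_class(m, "snnvae")
  x <- rand_image(1)
  dist <- encode(m, x)
  expect_s3_class(dist, "latent_distribution")
  expect_length(dist$mean, 6)
  expect_length(dist$variance, 6)
  expect_true(all(dist$variance > 0))
  z <- sample_latent(dist, seed = 3)
  expect_length(z, 6)
  xh <- decode(m, z)
  expect_s3_class(xh, "rgb_spectrogram")
  expect_equal(dim(xh$pixels), c(16, 16, 3))
  expect_true(all(xh$pixels >= 0 & xh$pixels <= 1))  # sigmoid output head
  expect_length(embed(m, x), 6)
  expect_equal(embed(m, x), dist$mean)
})

test_that("encoding is deterministic; different weights give different codes", {
  m1 <- snnvae(tiny_cfg(), seed = 1)
  m2 <- snnvae(tiny_cfg(), seed = 2)
  x <- rand_image(5)
  expect_identical(embed(m1, x), embed(m1, x))
  expect_false(isTRUE(all.equal(embed(m1, x), embed(m2, x))))
})

test_that("reparameterized samples follow the encoded moments", {
  dist <- latent_distribution(mean = c(0.5, -1.2, 2.0),
                              variance = c(1.0, 0.6, 1.5))
  n <- 20000
  Z <- withr::with_seed(17, {
    t(vapply(seq_len(n), function(i) sample_latent(dist, eps = rnorm(3)),
             numeric(3)))
  })
  se_mu <- sqrt(dist$variance / n)
  se_v <- dist$variance * sqrt(2 / n)
  expect_true(all(abs(colMeans(Z) - dist$mean) < 4 * se_mu))
  expect_true(all(abs(apply(Z, 2, var) - dist$variance) < 4 * se_v))
  # eps = 0 recovers the mean exactly
  expect_equal(sample_latent(dist, eps = c(0, 0, 0)), dist$mean)
})

test_that("KL divergence has its closed-form values and properties", {
  d0 <- latent_distribution(rep(0, 4), rep(1, 4))
  expect_equal(kl_divergence(d0), 0)
  d1 <- latent_distribution(1, 1)
  expect_equal(kl_divergence(d1), 0.5)
  d2 <- latent_distribution(0.3, 0.8)
  expect_equal(kl_divergence(d2),
               0.5 * (0.8 - log(0.8) - 1 + 0.09), tolerance = 1e-12)
  expect_gt(kl_divergence(latent_distribution(rnorm(5), runif(5, 0.1, 3))), 0)
  expect_error(latent_distribution(0, -1), "positive")
})

test_that("triplet loss matches its hinge closed form", {
  a <- c(0, 0); p <- c(1, 0); n <- c(3, 0)
  # d_ap = 1, d_an = 9 -> hinge inactive
  expect_equal(triplet_loss(a, p, n, alpha = 0.2), 0)
  # swapped: d_ap = 9, d_an = 1 -> 9 - 1 + 0.2
  expect_equal(triplet_loss(a, n, p, alpha = 0.2), 8.2)
  # degenerate triplet: loss = alpha
  expect_equal(triplet_loss(a, p, p, alpha = 0.7), 0.7)
  # batch reduction is a sum over rows
  A <- rbind(a, a); P <- rbind(n, p); N <- rbind(p, n)
  expect_equal(triplet_loss(A, P, N, alpha = 0.2), 8.2 + 0)
})

test_that("total_loss reports the documented combination", {
  lb <- total_loss(1.5, 0.25, 2, beta = 0.5)
  expect_s3_class(lb, "loss_breakdown")
  expect_equal(lb$total, 1.5 + 0.25 + 0.5 * 2)
  expect_error(total_loss(-1, 0, 0), ">= 0")
})

test_that("semi-hard mining picks in-window negatives and errors sanely", {
  # 1-D embeddings engineered so the semi-hard window is unambiguous
  emb <- matrix(c(0, 1, 1.8, 5), ncol = 1)
  labels <- c("a", "a", "b", "b")
  tb <- mine_semi_hard(emb, labels, alpha = 1.5, seed = 2)
  expect_s3_class(tb, "triplet_batch")
  # anchor 1: P = 2 (d_ap = 1); negatives at d = 3.24 and 25;
  # window (1, 2.5) contains neither -> hardest negative 3
  r1 <- tb[tb$anchor == 1, ]
  expect_equal(r1$positive, 2)
  expect_equal(r1$negative, 3)
  # anchor 2: P = 1 (d_ap = 1); negative 3 at d = 0.64, negative 4 at 16;
  # window (1, 2.5): neither inside -> hardest = 3
  r2 <- tb[tb$anchor == 2, ]
  expect_equal(r2$negative, 3)
  # a semi-hard (in-window) negative beats a closer below-window negative
  emb2 <- matrix(c(0, 1, 0.5, 1.2), ncol = 1)
  tb2 <- mine_semi_hard(emb2, labels, alpha = 1.5, seed = 2)
  # anchor 1: d_ap = 1; negatives at d = 0.25 (below window) and 1.44
  # (inside (1, 2.5)) -> the in-window negative 4 wins over the hardest 3
  expect_equal(tb2[tb2$anchor == 1, ]$negative, 4)
  expect_error(mine_semi_hard(emb, c("a", "a", "a", "a")), "mining error")
  expect_error(mine_semi_hard(emb, c("a", "b", "c", "d")), "mining error")
  # determinism under a fixed seed
  expect_identical(mine_semi_hard(emb, labels, seed = 9),
                   mine_semi_hard(emb, labels, seed = 9))
})

test_that("fused model reproduces multi-branch inference", {
  m <- snnvae(tiny_cfg(), seed = 7)
  mf <- fuse_model(m)
  expect_equal(mf$cfg$mode, "inference_fused")
  for (s in 1:20) {
    x <- rand_image(100 + s)
    expect_equal(embed(mf, x), embed(m, x), tolerance = 1e-8)
  }
  # idempotent
  mff <- fuse_model(mf)
  x <- rand_image(999)
  expect_equal(embed(mff, x), embed(mf, x))
})

test_that("centroid fitting and classification behave as documented", {
  emb <- rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2))
  cents <- fit_centroids(emb, c("x", "x", "y", "y"))
  expect_equal(rownames(cents), c("x", "y"))
  expect_equal(unname(cents["x", ]), c(0, 1))
  expect_equal(unname(cents["y", ]), c(10, 1))
  res <- classify(c(1, 1), cents)
  expect_equal(res$label, "x")
  expect_gt(res$score, 0.5)
  expect_equal(sum(res$scores), 1)
  # equidistant point -> deterministic first-name tie-break
  expect_equal(classify(c(5, 1), cents)$label, "x")
  # batch mode returns a label per row
  expect_equal(classify(emb, cents), c("x", "x", "y", "y"))
  expect_error(classify(c(0, 0), NULL), "centroids")
})

test_that("image size mismatches are rejected at the model boundary", {
  m <- snnvae(tiny_cfg(), seed = 1)
  expect_error(encode(m, rand_image(1, size = 32)), "size|shape|dim")
  expect_error(decode(m, rep(0, 5)), "latent")
})
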