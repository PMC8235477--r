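# Variational embedding: architecture symmetry, chromosome-blocked first
# layer, reparameterisation, and the closed-form loss terms.

test_that("decoders mirror the per-block input dimensions", {
  set.seed(1)
  emb <- build_embedding(c(50, 30), latent_dim = 8)
  rec <- decode_latent(emb, rnorm(8))
  expect_equal(vapply(rec, ncol, 1L), c(50, 30))
  expect_true(all(unlist(rec) > 0 & unlist(rec) < 1))
})

test_that("chromosome-blocked first layer is structurally sparse", {
  set.seed(2)
  chr <- rep(c("chrA", "chrB"), each = 5)
  emb <- build_embedding(10, latent_dim = 3, hidden_per_block = 4,
                         chromosome_blocks = list(chr))
  W <- emb$params$enc1_W
  mask <- emb$masks$enc1_W
  expect_equal(ncol(W) %% 2, 0)
  expect_true(all(W[mask == 0] == 0))
  # zeroing chrA features leaves chrB sub-layer pre-activations unchanged
  x <- matrix(runif(10), 1, 10)
  x0 <- x; x0[, chr == "chrA"] <- 0
  pre <- x %*% W
  pre0 <- x0 %*% W
  b_cols <- which(colSums(mask[chr == "chrB", , drop = FALSE]) > 0)
  a_cols <- setdiff(seq_len(ncol(W)), b_cols)
  expect_equal(pre[, b_cols], pre0[, b_cols])
  expect_false(isTRUE(all.equal(pre[, a_cols], pre0[, a_cols])))
})

test_that("first-layer weight gradients vanish for zeroed chromosome inputs", {
  set.seed(3)
  chr <- rep(c("chrA", "chrB"), each = 4)
  model <- build_model(8, list(t1 = list(type = "regression", label = "y")),
                       latent_dim = 2, hidden_per_block = 4, hidden_fusion = 4,
                       head_hidden = 3, chromosome_blocks = list(chr))
  X <- matrix(runif(5 * 8), 5, 8)
  X[, chr == "chrA"] <- 0
  cache <- omixtask:::mt_forward(model, list(X), eps = 0)
  lg <- omixtask:::mt_losses_grads(model, cache, list(rnorm(5)), 1, 1, 0.1)
  gW <- lg$grads$enc1_W
  expect_true(all(gW[chr == "chrA", ] == 0))
  expect_gt(sum(abs(gW[chr == "chrB", ])), 0)
})

test_that("features cannot belong to two chromosome blocks and dims must match", {
  expect_error(build_embedding(10, 3, chromosome_blocks = list(rep("c", 7))),
               "length")
})

test_that("encoding is deterministic, shaped B x p, and per-sample independent", {
  set.seed(4)
  emb <- build_embedding(c(12, 8), latent_dim = 5)
  X <- list(matrix(runif(6 * 12), 6, 12), matrix(runif(6 * 8), 6, 8))
  c1 <- encode_omics(emb, X)
  c2 <- encode_omics(emb, X)
  expect_identical(c1$mu, c2$mu)
  expect_equal(dim(c1$mu), c(6, 5))
  perm <- c(3, 1, 6, 2, 5, 4)
  cp <- encode_omics(emb, lapply(X, function(x) x[perm, , drop = FALSE]))
  expect_equal(cp$mu, c1$mu[perm, ], tolerance = 1e-12)
  expect_error(encode_omics(emb, list(X[[1]], X[[1]])), "features")
})

test_that("a 2-dimensional latent exports visualisation-ready coordinates", {
  set.seed(5)
  emb <- build_embedding(c(10, 6), latent_dim = 2)
  X <- list(matrix(runif(40), 4, 10), matrix(runif(24), 4, 6))
  rownames(X[[1]]) <- rownames(X[[2]]) <- paste0("S", 1:4)
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- latent_table(emb, X, f)
  expect_identical(names(df), c("sample_id", "latent_1", "latent_2"))
  back <- read.delim(f)
  expect_equal(back$latent_1, df$latent_1, tolerance = 1e-9)
})

test_that("reparameterisation follows z = mu + exp(logvar/2) * eps", {
  code <- list(mu = c(1, -2), logvar = c(0, 0))
  expect_equal(reparameterise(code, eps = 0), c(1, -2))
  expect_equal(reparameterise(code, eps = 1), c(2, -1))
  code2 <- list(mu = 0.5, logvar = log(4))
  expect_equal(reparameterise(code2, eps = 2), 0.5 + 2 * 2)
})

test_that("reparameterised draws have the right moments (Monte Carlo)", {
  set.seed(6)
  mu <- c(1.5, -0.5); lv <- c(log(0.25), log(4))
  n <- 1e5
  draws <- vapply(1:2, function(j) {
    reparameterise(list(mu = rep(mu[j], n), logvar = rep(lv[j], n)))
  }, numeric(n))
  for (j in 1:2) {
    se_mean <- sqrt(exp(lv[j]) / n)
    expect_lt(abs(mean(draws[, j]) - mu[j]), 3 * se_mean)
    se_var <- exp(lv[j]) * sqrt(2 / (n - 1))
    expect_lt(abs(var(draws[, j]) - exp(lv[j])), 3 * se_var)
  }
})

test_that("KL divergence matches the closed form and numerical quadrature", {
  expect_equal(kl_divergence(list(mu = 0, logvar = 0)), 0)
  expect_equal(kl_divergence(list(mu = 1, logvar = 0)), 0.5)
  # KL >= 0, zero only at the prior
  set.seed(7)
  for (i in 1:20) {
    code <- list(mu = rnorm(4), logvar = rnorm(4))
    expect_gte(kl_divergence(code), 0)
  }
  # quadrature oracle: KL factorises over dimensions for diagonal Gaussians
  code <- list(mu = c(0.7, -1.2, 0.3), logvar = c(0.5, -0.8, 0.1))
  kq <- sum(vapply(1:3, function(j) {
    s2 <- exp(code$logvar[j]); m <- code$mu[j]
    integrand <- function(z) {
      q <- dnorm(z, m, sqrt(s2))
      q * (dnorm(z, m, sqrt(s2), log = TRUE) - dnorm(z, log = TRUE))
    }
    integrate(integrand, -30, 30, rel.tol = 1e-10)$value
  }, 0))
  expect_equal(kl_divergence(code), kq, tolerance = 1e-4)
})

test_that("reconstruction loss matches closed forms and averages over blocks", {
  d <- 7
  x <- matrix(0.5, 2, d)
  expect_equal(reconstruction_loss(x, x), d * log(2))
  # near-perfect binary reconstruction approaches zero
  xb <- matrix(c(0, 1, 1, 0), 1, 4)
  xh <- abs(xb - 1e-9)
  expect_lt(reconstruction_loss(xb, xh), 1e-6)
  # two blocks: (L1 + L2) / 2
  x1 <- matrix(runif(6), 2, 3); x2 <- matrix(runif(10), 2, 5)
  h1 <- matrix(runif(6, 0.1, 0.9), 2, 3); h2 <- matrix(runif(10, 0.1, 0.9), 2, 5)
  L1 <- reconstruction_loss(x1, h1); L2 <- reconstruction_loss(x2, h2)
  expect_equal(reconstruction_loss(list(x1, x2), list(h1, h2)), (L1 + L2) / 2)
  expect_error(reconstruction_loss(matrix(1.5, 1, 1), matrix(0.5, 1, 1)),
               "\\[0,1\\]")
})

test_that("embedding loss is the sum of its parts and matches hand arithmetic", {
  x <- matrix(c(0.2, 0.8), 1, 2)
  xh <- matrix(c(0.3, 0.6), 1, 2)
  code <- list(mu = matrix(1, 1, 1), logvar = matrix(0, 1, 1))
  bce <- -(0.2 * log(0.3) + 0.8 * log(0.7) + 0.8 * log(0.6) + 0.2 * log(0.4))
  expect_equal(embedding_loss(x, xh, code), bce + 0.5, tolerance = 1e-12)
  code0 <- list(mu = matrix(0, 1, 1), logvar = matrix(0, 1, 1))
  expect_equal(embedding_loss(x, xh, code0), reconstruction_loss(x, xh))
})

test_that("one small gradient step decreases the embedding loss (descent sanity)", {
  wins <- 0
  for (seed in 1:20) {
    set.seed(seed)
    model <- build_model(c(10, 6), list(t = list(type = "regression",
                                                 label = "y")),
                         latent_dim = 3, hidden_per_block = 6,
                         hidden_fusion = 5, head_hidden = 3)
    X <- list(matrix(runif(80), 8, 10), matrix(runif(48), 8, 6))
    eps <- matrix(rnorm(24), 8, 3)
    cache <- omixtask:::mt_forward(model, X, eps = eps)
    lg <- omixtask:::mt_losses_grads(model, cache, list(rnorm(8)), 1, 1, 0)
    before <- lg$losses$embed
    for (nm in model$groups$embedding) {
      model$params[[nm]] <- model$params[[nm]] - 1e-3 * lg$grads[[nm]]
    }
    cache2 <- omixtask:::mt_forward(model, X, eps = eps)
    after <- omixtask:::mt_losses_grads(model, cache2, list(rnorm(8)), 1, 1, 0,
                                        want_grads = FALSE)$losses$embed
    if (after < before) wins <- wins + 1
  }
  expect_gte(wins, 11)   # majority over 20 seeds
})
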