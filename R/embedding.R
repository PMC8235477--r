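# Variational deep-embedding module: per-omics encoders whose outputs are
# concatenated and fused into a shared hidden layer, bottleneck maps giving the
# mean vector mu and the log-variance vector, the reparameterised latent z, and
# mirror-image decoders ending in sigmoid outputs so every reconstruction lies
# in (0,1) as binary cross-entropy requires.

#' Build a variational multi-omics embedding network
#'
#' Constructs the fully connected embedding architecture: one encoder hidden
#' layer per omics block (optionally split into disjoint per-chromosome
#' sub-layers for methylation), a shared fusion layer, linear maps to the
#' latent mean and log-variance, and decoders mirroring the encoder so each
#' block is reconstructed at its input dimension.
#'
#' @param omics_dims integer vector, number of features per omics block.
#' @param latent_dim dimension p of the latent code; typically far smaller
#'   than the total feature count. Set to 2 or 3 for direct visualisation.
#' @param hidden_per_block width of each block's encoder hidden layer
#'   (recycled across blocks).
#' @param hidden_fusion width of the shared fusion layer.
#' @param chromosome_blocks optional list (one entry per omics block, or
#'   `NULL` for blocks without grouping): a factor/character vector of length
#'   `omics_dims[b]` assigning every feature of that block to exactly one
#'   chromosome. The block's first layer is then block-diagonal: features of
#'   one chromosome connect only to that chromosome's sub-layer units.
#' @return an object of class `omix_embedding`: parameter list, architecture
#'   description, and the total parameter count.
#' @examples
#' set.seed(1)
#' emb <- build_embedding(c(50, 30), latent_dim = 8)
#' emb$n_parameters
#' @export
build_embedding <- function(omics_dims, latent_dim,
                            hidden_per_block = 64, hidden_fusion = 64,
                            chromosome_blocks = NULL) {
  stopifnot(all(omics_dims >= 1), latent_dim >= 1)
  M <- length(omics_dims)
  hidden_per_block <- rep_len(hidden_per_block, M)

  params <- list()
  masks <- list()
  enc_widths <- integer(M)
  for (b in seq_len(M)) {
    d <- omics_dims[b]
    chr <- if (!is.null(chromosome_blocks)) chromosome_blocks[[b]] else NULL
    if (is.null(chr)) {
      h <- hidden_per_block[b]
      lay <- new_linear(d, h)
      mask <- NULL
    } else {
      if (length(chr) != d) {
        stop("chromosome annotation length must equal the block's feature count")
      }
      chr <- as.factor(chr)
      groups <- split(seq_len(d), chr)
      n_chr <- length(groups)
      per <- max(1L, ceiling(hidden_per_block[b] / n_chr))
      h <- per * n_chr
      mask <- matrix(0, d, h)
      for (g in seq_len(n_chr)) {
        cols <- ((g - 1L) * per + 1L):(g * per)
        mask[groups[[g]], cols] <- 1
      }
      lay <- new_linear(d, h)
      lay$W <- lay$W * mask
    }
    params[[paste0("enc", b, "_W")]] <- lay$W
    params[[paste0("enc", b, "_b")]] <- lay$b
    masks[[paste0("enc", b, "_W")]] <- mask
    enc_widths[b] <- ncol(lay$W)
  }
  H <- sum(enc_widths)
  fus <- new_linear(H, hidden_fusion)
  params$fus_W <- fus$W; params$fus_b <- fus$b
  mu <- new_linear(hidden_fusion, latent_dim)
  params$mu_W <- mu$W; params$mu_b <- mu$b
  lv <- new_linear(hidden_fusion, latent_dim)
  # log-variance head started near 0 => sigma near 1
  lv$W <- lv$W * 0.01
  params$lv_W <- lv$W; params$lv_b <- lv$b

  dec0 <- new_linear(latent_dim, hidden_fusion)
  params$dec0_W <- dec0$W; params$dec0_b <- dec0$b
  for (b in seq_len(M)) {
    dh <- new_linear(hidden_fusion, enc_widths[b])
    params[[paste0("dec", b, "h_W")]] <- dh$W
    params[[paste0("dec", b, "h_b")]] <- dh$b
    dout <- new_linear(enc_widths[b], omics_dims[b])
    params[[paste0("dec", b, "o_W")]] <- dout$W
    params[[paste0("dec", b, "o_b")]] <- dout$b
  }

  obj <- list(
    params = params,
    masks = masks,
    omics_dims = as.integer(omics_dims),
    enc_widths = enc_widths,
    hidden_fusion = hidden_fusion,
    latent_dim = as.integer(latent_dim),
    n_blocks = M,
    n_parameters = sum(vapply(params, length, 1L))
  )
  class(obj) <- "omix_embedding"
  obj
}

#' @export
print.omix_embedding <- function(x, ...) {
  cat("Variational multi-omics embedding\n")
  cat("  blocks:", paste(x$omics_dims, collapse = " + "),
      "features -> hidden", paste(x$enc_widths, collapse = " + "), "\n")
  cat("  fusion:", x$hidden_fusion, " latent dim:", x$latent_dim, "\n")
  cat("  parameters:", x$n_parameters, "\n")
  invisible(x)
}

# Forward pass of the encoder half; X_blocks is a list of samples x features
# matrices. Returns all intermediates needed for backprop.
embed_encode_forward <- function(emb, X_blocks) {
  p <- emb$params
  M <- emb$n_blocks
  stopifnot(length(X_blocks) == M)
  for (b in seq_len(M)) {
    if (ncol(X_blocks[[b]]) != emb$omics_dims[b]) {
      stop(sprintf("block %d has %d features, model expects %d",
                   b, ncol(X_blocks[[b]]), emb$omics_dims[b]))
    }
  }
  A1 <- vector("list", M); H1 <- vector("list", M)
  for (b in seq_len(M)) {
    A1[[b]] <- sweep(X_blocks[[b]] %*% p[[paste0("enc", b, "_W")]], 2,
                     p[[paste0("enc", b, "_b")]], "+")
    H1[[b]] <- lrelu(A1[[b]])
  }
  Hc <- do.call(cbind, H1)
  A2 <- sweep(Hc %*% p$fus_W, 2, p$fus_b, "+")
  Hf <- lrelu(A2)
  MU <- sweep(Hf %*% p$mu_W, 2, p$mu_b, "+")
  LV <- sweep(Hf %*% p$lv_W, 2, p$lv_b, "+")
  list(X = X_blocks, A1 = A1, Hc = Hc, A2 = A2, Hf = Hf, MU = MU, LV = LV)
}

#' Encode omics profiles into the latent code
#'
#' Deterministic mapping from multi-omics input to the parameters of the
#' variational distribution q(z|x): the latent mean `mu` and log-variance
#' `logvar`. Use [reparameterise()] to draw z, or use `mu` directly as the
#' deterministic latent representation.
#'
#' @param emb an `omix_embedding` from [build_embedding()].
#' @param X_blocks list of samples x features matrices, one per omics block,
#'   values in \[0,1\].
#' @return list with matrices `mu` and `logvar` (samples x latent_dim).
#' @export
encode_omics <- function(emb, X_blocks) {
  fw <- embed_encode_forward(emb, X_blocks)
  list(mu = fw$MU, logvar = fw$LV)
}

#' Reparameterisation trick
#'
#' Draws z = mu + sigma * eps with sigma = exp(logvar/2), making sampling from
#' q(z|x) differentiable in (mu, logvar). With `eps = NULL` standard-normal
#' noise is drawn from the current RNG stream; pass `eps = 0` for the
#' deterministic mode z = mu.
#'
#' @param code list with `mu` and `logvar` (vectors or matrices of equal shape).
#' @param eps standard-normal draw(s) of the same shape, a scalar to recycle,
#'   or `NULL` to sample.
#' @return z of the same shape as `mu`.
#' @export
reparameterise <- function(code, eps = NULL) {
  mu <- code$mu
  lv <- code$logvar
  if (is.null(eps)) {
    eps <- stats::rnorm(length(mu))
    if (is.matrix(mu)) eps <- matrix(eps, nrow(mu), ncol(mu))
  }
  mu + exp(lv / 2) * eps
}

# Decoder forward; Z is samples x latent_dim. Returns intermediates including
# pre-sigmoid logits per block.
embed_decode_forward <- function(emb, Z) {
  p <- emb$params
  D1 <- sweep(Z %*% p$dec0_W, 2, p$dec0_b, "+")
  Hd1 <- lrelu(D1)
  M <- emb$n_blocks
  D2 <- vector("list", M); Hd2 <- vector("list", M); LG <- vector("list", M)
  for (b in seq_len(M)) {
    D2[[b]] <- sweep(Hd1 %*% p[[paste0("dec", b, "h_W")]], 2,
                     p[[paste0("dec", b, "h_b")]], "+")
    Hd2[[b]] <- lrelu(D2[[b]])
    LG[[b]] <- sweep(Hd2[[b]] %*% p[[paste0("dec", b, "o_W")]], 2,
                     p[[paste0("dec", b, "o_b")]], "+")
  }
  list(Z = Z, D1 = D1, Hd1 = Hd1, D2 = D2, Hd2 = Hd2, LG = LG)
}

#' Decode a latent code into reconstructed omics blocks
#'
#' @param emb an `omix_embedding`.
#' @param z latent matrix (samples x latent_dim) or a single vector.
#' @return list of reconstructed blocks, each entry in (0,1).
#' @export
decode_latent <- function(emb, z) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1)
  stopifnot(ncol(z) == emb$latent_dim)
  fw <- embed_decode_forward(emb, z)
  lapply(fw$LG, sigmoid)
}

#' KL divergence of the variational posterior from the standard normal prior
#'
#' Closed form for diagonal Gaussians, summed over latent dimensions and
#' averaged over the batch:
#' 0.5 * sum_j (mu_j^2 + sigma_j^2 - 1 - log sigma_j^2).
#'
#' @param code list with `mu` and `logvar` (vectors or matrices, samples in
#'   rows).
#' @return non-negative scalar.
#' @export
kl_divergence <- function(code) {
  mu <- code$mu
  lv <- code$logvar
  if (!is.matrix(mu)) { mu <- matrix(mu, 1); lv <- matrix(lv, 1) }
  per_sample <- 0.5 * rowSums(mu^2 + exp(lv) - 1 - lv)
  mean(per_sample)
}

#' Reconstruction loss (binary cross-entropy)
#'
#' Per-block BCE summed over features, averaged over the batch, then averaged
#' over the M omics blocks. Inputs must lie in \[0,1\] and reconstructions in
#' (0,1). The feature-sum reduction keeps the reconstruction term on a scale
#' comparable to the KL term when d >> p; `reduction = "mean"` divides by the
#' feature count instead.
#'
#' @param X_blocks list of input matrices in \[0,1\] (samples x features).
#' @param Xhat_blocks list of reconstructions in (0,1), same shapes.
#' @param reduction `"sum"` (default) or `"mean"` over features.
#' @return non-negative scalar.
#' @export
reconstruction_loss <- function(X_blocks, Xhat_blocks, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (is.matrix(X_blocks)) X_blocks <- list(X_blocks)
  if (is.matrix(Xhat_blocks)) Xhat_blocks <- list(Xhat_blocks)
  stopifnot(length(X_blocks) == length(Xhat_blocks))
  M <- length(X_blocks)
  total <- 0
  for (b in seq_len(M)) {
    x <- X_blocks[[b]]; xh <- Xhat_blocks[[b]]
    if (!is.matrix(x)) x <- matrix(x, 1)
    if (!is.matrix(xh)) xh <- matrix(xh, 1)
    if (any(x < 0 | x > 1)) stop("input values must lie in [0,1]")
    xh <- pmin(pmax(xh, 1e-12), 1 - 1e-12)
    bce <- -(x * log(xh) + (1 - x) * log(1 - xh))
    per_sample <- rowSums(bce)
    if (reduction == "mean") per_sample <- per_sample / ncol(x)
    total <- total + mean(per_sample)
  }
  total / M
}

#' Deep-embedding loss
#'
#' Sum of the reconstruction loss and the KL divergence: the negative
#' variational lower bound (up to constants) optimised in the unsupervised
#' phase.
#'
#' @inheritParams reconstruction_loss
#' @param code latent code list with `mu`, `logvar`.
#' @return scalar loss.
#' @export
embedding_loss <- function(X_blocks, Xhat_blocks, code,
                           reduction = c("sum", "mean")) {
  reconstruction_loss(X_blocks, Xhat_blocks, reduction = match.arg(reduction)) +
    kl_divergence(code)
}

#' Export the deterministic latent representation
#'
#' Encodes samples with z = mu (no sampling) and writes/returns a table of
#' latent coordinates suitable for any external visualiser.
#'
#' @param emb an `omix_embedding`.
#' @param X_blocks list of omics matrices (samples x features) with rownames
#'   as sample IDs.
#' @param path optional TSV path; when given the table is written there.
#' @return data.frame: sample_id plus latent_1..latent_p.
#' @export
latent_table <- function(emb, X_blocks, path = NULL) {
  code <- encode_omics(emb, X_blocks)
  ids <- rownames(X_blocks[[1]])
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(code$mu)))
  df <- data.frame(sample_id = ids, code$mu)
  names(df)[-1] <- paste0("latent_", seq_len(ncol(code$mu)))
  if (!is.null(path)) {
    data.table::fwrite(df, path, sep = "\t")
  }
  df
}
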