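# Full multi-task model: the variational embedding plus one downstream head
# per task, all parameters held in one flat named list so the optimiser can
# freeze/unfreeze groups by name (the three training phases).

#' Build the full multi-task model
#'
#' Combines a variational embedding ([build_embedding()]) with one downstream
#' head per task. Each head is a small fully connected network on the latent
#' code z: one LeakyReLU hidden layer and a linear output layer whose width is
#' the number of classes (classification, softmax applied downstream), one
#' neuron (regression), or the number of time intervals m (survival logits).
#'
#' @param omics_dims integer vector of per-block feature counts.
#' @param tasks named list of task descriptors; each a list with `type`
#'   (`"classification"`, `"regression"` or `"survival"`), `label` (phenotype
#'   column; ignored for survival which uses the reserved survival columns),
#'   and the output size: `n_classes` for classification, `m` for survival.
#' @param latent_dim latent dimension p.
#' @param hidden_per_block,hidden_fusion encoder widths, see
#'   [build_embedding()].
#' @param head_hidden hidden width of every downstream head.
#' @param chromosome_blocks optional per-block chromosome annotation, see
#'   [build_embedding()].
#' @return an `omix_model`: flat parameter list, first-layer sparsity masks,
#'   parameter-group names (`embedding`, `downstream`), task metadata.
#' @export
build_model <- function(omics_dims, tasks, latent_dim = 16,
                        hidden_per_block = 64, hidden_fusion = 64,
                        head_hidden = 32, chromosome_blocks = NULL) {
  stopifnot(length(tasks) >= 1)
  emb <- build_embedding(omics_dims, latent_dim,
                         hidden_per_block = hidden_per_block,
                         hidden_fusion = hidden_fusion,
                         chromosome_blocks = chromosome_blocks)
  params <- emb$params
  embed_names <- names(params)
  task_meta <- list()
  for (k in seq_along(tasks)) {
    tk <- tasks[[k]]
    n_out <- switch(tk$type,
      classification = tk$n_classes,
      regression = 1L,
      survival = tk$m,
      stop("unknown task type: ", tk$type))
    if (is.null(n_out) || n_out < 1) stop("task ", k, " has no valid output size")
    l1 <- new_linear(latent_dim, head_hidden)
    l2 <- new_linear(head_hidden, n_out)
    params[[paste0("task", k, "_W1")]] <- l1$W
    params[[paste0("task", k, "_b1")]] <- l1$b
    params[[paste0("task", k, "_W2")]] <- l2$W
    params[[paste0("task", k, "_b2")]] <- l2$b
    tk$n_out <- as.integer(n_out)
    tk$id <- k
    task_meta[[k]] <- tk
  }
  names(task_meta) <- names(tasks)
  obj <- list(
    params = params,
    masks = emb$masks,
    omics_dims = emb$omics_dims,
    enc_widths = emb$enc_widths,
    hidden_fusion = emb$hidden_fusion,
    latent_dim = emb$latent_dim,
    n_blocks = emb$n_blocks,
    head_hidden = head_hidden,
    tasks = task_meta,
    groups = list(
      embedding = embed_names,
      downstream = setdiff(names(params), embed_names)
    )
  )
  class(obj) <- "omix_model"
  obj
}

#' @export
print.omix_model <- function(x, ...) {
  cat("Multi-task omics model:", length(x$tasks), "task(s),",
      sum(vapply(x$params, length, 1L)), "parameters\n")
  cat("  blocks:", paste(x$omics_dims, collapse = " + "),
      "-> latent", x$latent_dim, "\n")
  for (nm in names(x$tasks)) {
    tk <- x$tasks[[nm]]
    cat(sprintf("  task %-12s %-14s out=%d\n", nm, tk$type, tk$n_out))
  }
  invisible(x)
}

# View of the embedding half as an omix_embedding (shares no state; copies
# the current parameter values).
embedding_view <- function(model) {
  obj <- list(
    params = model$params[model$groups$embedding],
    masks = model$masks,
    omics_dims = model$omics_dims,
    enc_widths = model$enc_widths,
    hidden_fusion = model$hidden_fusion,
    latent_dim = model$latent_dim,
    n_blocks = model$n_blocks,
    n_parameters = sum(vapply(model$params[model$groups$embedding], length, 1L))
  )
  class(obj) <- "omix_embedding"
  obj
}

# Forward pass of head k on latent Z; returns intermediates for backprop.
# Inverted dropout on the head's hidden layer when a mask is supplied.
head_forward <- function(model, k, Z, drop_mask = NULL, keep = 1) {
  p <- model$params
  K1 <- sweep(Z %*% p[[paste0("task", k, "_W1")]], 2,
              p[[paste0("task", k, "_b1")]], "+")
  HK <- lrelu(K1)
  HKd <- if (is.null(drop_mask)) HK else HK * drop_mask / keep
  OUT <- sweep(HKd %*% p[[paste0("task", k, "_W2")]], 2,
               p[[paste0("task", k, "_b2")]], "+")
  list(K1 = K1, HK = HK, HKd = HKd, OUT = OUT, drop_mask = drop_mask, keep = keep)
}

# Full forward pass: encoder, reparameterisation, decoder, every head.
# eps = NULL draws noise; eps = 0 gives deterministic z = mu.
# drop_rate > 0 applies dropout to the downstream heads' hidden layers.
mt_forward <- function(model, X_blocks, eps = NULL, drop_rate = 0) {
  emb <- embedding_view(model)
  enc <- embed_encode_forward(emb, X_blocks)
  B <- nrow(enc$MU); p <- ncol(enc$MU)
  if (is.null(eps)) {
    EPS <- matrix(stats::rnorm(B * p), B, p)
  } else {
    EPS <- if (is.matrix(eps)) eps else matrix(eps, B, p)
  }
  SD <- exp(enc$LV / 2)
  Z <- enc$MU + SD * EPS
  dec <- embed_decode_forward(emb, Z)
  keep <- 1 - drop_rate
  heads <- lapply(seq_along(model$tasks), function(k) {
    mask <- NULL
    if (drop_rate > 0) {
      mask <- matrix(stats::rbinom(B * model$head_hidden, 1, keep),
                     B, model$head_hidden)
    }
    head_forward(model, k, Z, drop_mask = mask, keep = keep)
  })
  c(enc, list(EPS = EPS, SD = SD, Z = Z, dec = dec, heads = heads))
}
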