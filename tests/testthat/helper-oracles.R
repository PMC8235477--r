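# Independent oracles used across tests. These re-derive quantities by brute
# force or closed form and must stay independent of the implementation paths
# they check.

# All m+1 monotone outcome sequences scored directly: outcome j (0-based)
# has score exp(sum of logits after position j); normalise.
pmf_enum <- function(logits) {
  m <- length(logits)
  scores <- vapply(0:m, function(j) {
    if (j == m) 1 else exp(sum(logits[(j + 1):m]))
  }, 0)
  scores / sum(scores)
}

# Harrell's C by explicit double loop over ordered pairs.
cindex_brute <- function(risk, T, E) {
  num <- 0; den <- 0
  n <- length(T)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (T[i] < T[j] && E[i] == 1) {
        den <- den + 1
        if (risk[i] > risk[j]) num <- num + 1
        else if (risk[i] == risk[j]) num <- num + 0.5
      }
    }
  }
  num / den
}

# Numeric central-difference gradient of the MTLR loss w.r.t. the logits.
survloss_fd_grad <- function(logits, label, h = 1e-6) {
  vapply(seq_along(logits), function(i) {
    lp <- logits; lp[i] <- lp[i] + h
    lm <- logits; lm[i] <- lm[i] - h
    (as.numeric(survival_loss(matrix(lp, 1), list(label))) -
       as.numeric(survival_loss(matrix(lm, 1), list(label)))) / (2 * h)
  }, 0)
}

# Small end-to-end study shared by trainer and CLI tests.
make_tiny_study <- function(n = 150, seed = 11, missing_rate = 0) {
  res <- synth_generate(synth_config(
    n_samples = n, omics_dims = c(30, 40), n_classes = 3,
    class_separation = 5, censoring_rate = 0.3, missing_rate = missing_rate,
    seed = seed))
  sp <- stratified_split(res$dataset$phenotype, "class",
                         c(0.6, 0.2, 0.2), seed = seed)
  pr <- omixtask:::prepare_for_training(res$dataset$blocks, sp$train)
  list(res = res, split = sp, X = pr$X, phenotype = res$dataset$phenotype)
}

tiny_config <- function(...) {
  base <- list(latent_dim = 6, hidden_per_block = 12, hidden_fusion = 10,
               head_hidden = 8, m = 16, epochs = c(3, 5, 5),
               batch_size = 32, seed = 5)
  do.call(train_config, utils::modifyList(base, list(...)))
}

all_tasks <- function() {
  list(class = list(type = "classification", label = "class"),
       age = list(type = "regression", label = "age"),
       surv = list(type = "survival"))
}
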