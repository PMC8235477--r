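# Low-level dense-network primitives shared by the embedding module and the
# downstream heads. Everything operates on plain numeric matrices with samples
# in rows; gradients are computed analytically (no autodiff dependency).

LRELU_SLOPE <- 0.01

lrelu <- function(x) {
  ifelse(x > 0, x, LRELU_SLOPE * x)
}

lrelu_grad <- function(x) {
  ifelse(x > 0, 1, LRELU_SLOPE)
}

sigmoid <- function(x) {
  1 / (1 + exp(-x))
}

# Row-wise log-sum-exp, numerically stable for |x| up to ~1e300.
logsumexp_rows <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# He-style initialisation for LeakyReLU layers.
init_weight <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

new_linear <- function(n_in, n_out) {
  list(W = init_weight(n_in, n_out), b = rep(0, n_out))
}

# Adam state for a named list of parameter arrays.
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

# One Adam update restricted to `active` parameter names. Classic Adam with an
# L2 weight-decay term added to the gradient (decay skips bias vectors).
adam_step <- function(params, grads, state, lr, active = names(params),
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in active) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0 && !endsWith(nm, "_b")) {
      g <- g + weight_decay * params[[nm]]
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Split a column-concatenated matrix back into per-block matrices.
split_cols <- function(x, widths) {
  stops <- cumsum(widths)
  starts <- c(1, head(stops, -1) + 1)
  lapply(seq_along(widths), function(i) {
    x[, starts[i]:stops[i], drop = FALSE]
  })
}
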