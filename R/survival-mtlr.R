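# Discrete-time survival prediction (multi-task logistic regression, MTLR).
# The time axis is divided into m intervals l_i = [t_{i-1}, t_i) with t_0 = 0
# and t_m >= max(T). A network emits m logits y'; the label is an m-vector of
# survival statuses y with y_i = 1 iff death occurred by t_i. Each of the m+1
# monotone outcome sequences (death in interval 1..m, or survival beyond t_m)
# is scored by exp(sum of the logits after the death index) and normalised.
# Censored subjects contribute the marginal likelihood over all outcome
# sequences consistent with being alive at the last time point before
# censoring.

#' Build a time-interval grid for discrete-time survival
#'
#' @param times observed times T (> 0), events and censorings together.
#' @param events event indicators E in \{0,1\}.
#' @param m number of intervals.
#' @param scheme `"quantile"` places interior boundaries at empirical
#'   quantiles of the event times (balanced events per interval);
#'   `"uniform"` uses equal-width intervals on \[0, max(T)\].
#' @return numeric vector of m+1 boundaries t_0 = 0 < t_1 < ... < t_m,
#'   with t_m >= max(times).
#' @examples
#' make_time_grid(c(2, 10, 7), c(1, 1, 0), m = 5, scheme = "uniform")
#' @export
make_time_grid <- function(times, events, m, scheme = c("quantile", "uniform")) {
  scheme <- match.arg(scheme)
  stopifnot(m >= 1, all(times > 0), all(events %in% c(0, 1)))
  tmax <- max(times)
  if (scheme == "uniform") {
    grid <- seq(0, tmax, length.out = m + 1)
  } else {
    ev_times <- times[events == 1]
    if (length(ev_times) == 0) stop("quantile scheme requires at least one event")
    if (m > length(unique(ev_times))) {
      stop("m exceeds the number of distinct event times under the quantile scheme")
    }
    # order statistics at ranks ceil(n*k/m): exact integer arithmetic (the
    # generic quantile() fuzz duplicates boundaries when m == n)
    srt <- sort(ev_times)
    n_ev <- length(srt)
    ranks <- ceiling(n_ev * seq_len(m - 1) / m)
    inner <- srt[pmin(pmax(ranks, 1L), n_ev)]
    grid <- c(0, inner, tmax)
    if (any(diff(grid) <= 0)) {
      stop("quantile grid boundaries are not strictly increasing; reduce m")
    }
  }
  grid
}

#' Encode a survival label on a time grid
#'
#' For an observed event (E = 1) the label is the monotone step sequence
#' y_i = 1 iff T <= t_i; a death at exactly a boundary t_i is attributed to
#' interval i. For a censored subject (E = 0) the sequence is only known up to
#' the last grid point at or before T; all later outcomes remain admissible.
#' Outcome index j in 0..m means death in interval j+1 (j < m) or survival
#' beyond t_m (j = m); the admissible outcomes always form a contiguous range
#' \[lo, hi\].
#'
#' @param T observed time (>= 0).
#' @param E event indicator, 1 = death observed, 0 = censored.
#' @param grid boundaries from [make_time_grid()].
#' @return list: `y` (m-vector; for censored subjects the undetermined tail is
#'   `NA`), `lo`/`hi` (admissible outcome range, 0-based), `censor_index`
#'   (last time point known alive, 0-based; `NA` for events), `event` (E).
#' @export
encode_survival_label <- function(T, E, grid) {
  stopifnot(T >= 0, E %in% c(0, 1))
  m <- length(grid) - 1L
  tm <- grid[m + 1L]
  if (T > tm + 1e-9 * max(1, abs(tm))) stop("time exceeds the last grid boundary t_m")
  ts <- grid[-1L]                      # t_1 .. t_m
  if (E == 1) {
    y <- as.numeric(T <= ts)
    j <- sum(ts < T)                   # outcome index, 0-based
    list(y = y, lo = j, hi = j, censor_index = NA_integer_, event = 1)
  } else {
    c_idx <- sum(ts <= T)              # last time point known alive
    y <- rep(NA_real_, m)
    if (c_idx >= 1) y[seq_len(c_idx)] <- 0
    list(y = y, lo = c_idx, hi = m, censor_index = c_idx, event = 0)
  }
}

# Outcome scores s_j = sum_{i=j+1}^m y'_i for j = 0..m, rows = samples.
mtlr_scores <- function(logits) {
  if (!is.matrix(logits)) logits <- matrix(logits, nrow = 1)
  m <- ncol(logits)
  cs <- t(apply(cbind(logits, 0), 1, function(r) rev(cumsum(rev(r)))))
  if (m == 0) stop("need at least one interval")
  matrix(cs, nrow = nrow(logits))      # samples x (m+1)
}

#' Outcome probability mass function of the MTLR head
#'
#' Maps m logits to the m+1 outcome probabilities
#' p_j proportional to exp(sum_{i=j+1}^m y'_i), computed with log-sum-exp
#' stabilisation.
#'
#' @param logits numeric vector of length m, or samples x m matrix.
#' @return probability vector of length m+1 (or samples x (m+1) matrix);
#'   rows sum to 1.
#' @examples
#' survival_pmf(c(0, 0))     # uniform over 3 outcomes
#' @export
survival_pmf <- function(logits) {
  vec <- !is.matrix(logits)
  s <- mtlr_scores(logits)
  p <- softmax_rows(s)
  if (vec) drop(p) else p
}

#' MTLR survival loss
#'
#' Negative log-likelihood of the encoded survival labels under the MTLR
#' outcome distribution, averaged over the batch. An uncensored subject
#' contributes -log p\[outcome\]; a censored subject contributes the negative
#' log of the total mass over all admissible outcomes (marginal likelihood).
#'
#' @param logits samples x m matrix (or length-m vector for one subject).
#' @param labels a single encoding from [encode_survival_label()] or a list of
#'   them, one per row of `logits`.
#' @return scalar mean loss; gradient w.r.t. the logits in attribute
#'   `"gradient"`.
#' @export
survival_loss <- function(logits, labels) {
  if (!is.matrix(logits)) logits <- matrix(logits, nrow = 1)
  if (!is.null(labels$lo)) labels <- list(labels)
  stopifnot(length(labels) == nrow(logits))
  m <- ncol(logits)
  s <- mtlr_scores(logits)             # B x (m+1)
  logZ <- logsumexp_rows(s)
  P <- exp(s - logZ)                   # full pmf
  B <- nrow(logits)
  loss <- numeric(B)
  grad <- matrix(0, B, m)
  cumP <- t(apply(P, 1, cumsum))       # cumP[, i] = sum_{j <= i-1} p_j at col i
  for (i in seq_len(B)) {
    lo <- labels[[i]]$lo; hi <- labels[[i]]$hi
    idx <- (lo:hi) + 1L
    sa <- s[i, idx, drop = TRUE]
    mx <- max(sa)
    log_adm <- mx + log(sum(exp(sa - mx)))
    loss[i] <- logZ[i] - log_adm
    q <- exp(sa - log_adm)             # pmf renormalised over admissible set
    cumQ <- numeric(m + 1)
    cumQ[idx] <- q
    cumQ <- cumsum(cumQ)
    # d loss / d y'_k = sum_{j<k} p_j - sum_{j<k, admissible} q_j
    grad[i, ] <- cumP[i, seq_len(m)] - cumQ[seq_len(m)]
  }
  out <- mean(loss)
  attr(out, "gradient") <- grad / B
  out
}

#' Survival function from the outcome pmf
#'
#' S(t_k) = P(T > t_k) = sum of outcome probabilities j >= k; S(t_0) = 1 and
#' S is non-increasing.
#'
#' @param pmf outcome probabilities (length m+1 vector or samples x (m+1)
#'   matrix).
#' @param grid optional grid boundaries (used only for naming).
#' @return survival probabilities at t_1..t_m (vector or samples x m matrix).
#' @export
survival_function <- function(pmf, grid = NULL) {
  vec <- !is.matrix(pmf)
  if (vec) pmf <- matrix(pmf, nrow = 1)
  m <- ncol(pmf) - 1L
  S <- t(apply(pmf, 1, function(p) rev(cumsum(rev(p)))))
  S <- matrix(S, nrow = nrow(pmf))[, -1L, drop = FALSE]   # S(t_1)..S(t_m)
  if (!is.null(grid)) colnames(S) <- paste0("t", seq_len(m))
  if (vec) drop(S) else S
}

#' Risk score from the outcome pmf
#'
#' Sum over intervals of the discrete hazard
#' h_i = P(death in interval i | alive at t_{i-1}) = p_{i-1} / S(t_{i-1}),
#' with S(t_0) = 1. Intervals whose conditioning probability is zero
#' contribute the defined limit 1. Higher risk means earlier expected death.
#'
#' @param pmf outcome probabilities (vector or samples x (m+1) matrix).
#' @return scalar risk per sample.
#' @examples
#' risk_score(c(1/3, 1/3, 1/3))   # 1/3 + 1/2 = 5/6
#' @export
risk_score <- function(pmf) {
  vec <- !is.matrix(pmf)
  if (vec) pmf <- matrix(pmf, nrow = 1)
  m <- ncol(pmf) - 1L
  apply(pmf, 1, function(p) {
    Sprev <- rev(cumsum(rev(p)))       # S(t_0)=1, S(t_1), ..., S(t_m)
    h <- numeric(m)
    for (i in seq_len(m)) {
      h[i] <- if (Sprev[i] > 0) p[i] / Sprev[i] else 1
    }
    sum(h)
  }) -> r
  if (vec) r[1] else r
}

#' Classification loss (cross-entropy)
#'
#' Mean negative log-probability of the true class.
#'
#' @param probabilities samples x K matrix of class probabilities (rows sum
#'   to 1).
#' @param labels integer class indices in 1..K (or a factor).
#' @return scalar loss.
#' @export
classification_loss <- function(probabilities, labels) {
  if (!is.matrix(probabilities)) probabilities <- matrix(probabilities, nrow = 1)
  if (is.factor(labels)) labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(probabilities))
  if (any(labels < 1 | labels > ncol(probabilities))) {
    stop("label outside 1..K")
  }
  p <- probabilities[cbind(seq_along(labels), labels)]
  mean(-log(pmax(p, 1e-300)))
}

#' Regression loss (mean squared error)
#'
#' @param predictions numeric vector.
#' @param targets numeric vector of the same length.
#' @return scalar mean squared error.
#' @export
regression_loss <- function(predictions, targets) {
  stopifnot(length(predictions) == length(targets))
  mean((predictions - targets)^2)
}
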