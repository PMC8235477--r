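# Evaluation metrics: macro-averaged multi-class classification metrics,
# regression error metrics, Harrell's concordance index, and the
# inverse-probability-of-censoring-weighted Brier score / integrated Brier
# score (Graf decomposition).

#' Macro-averaged classification metrics
#'
#' Per-class precision (PPV), recall (TPR) and F1 from one-vs-rest counts,
#' averaged over classes with equal weight (the macro convention, insensitive
#' to class frequency); overall accuracy; and one-vs-rest ROC AUC per class
#' averaged over classes. Classes absent from the truth are excluded from the
#' macro averages; a class whose truth is single-valued is skipped for AUC
#' with a warning.
#'
#' @param true true class labels (factor or character).
#' @param predicted predicted class labels.
#' @param probabilities samples x K matrix of class probabilities, columns
#'   named by class; required for AUC (may be `NULL` to skip AUC).
#' @return list: `macro_f1`, `macro_tpr`, `macro_ppv`, `accuracy`,
#'   `macro_rocauc`, and `per_class` breakdown data.frame.
#' @export
macro_classification_metrics <- function(true, predicted, probabilities = NULL) {
  true <- as.character(true)
  predicted <- as.character(predicted)
  stopifnot(length(true) == length(predicted))
  classes <- sort(unique(true))
  per <- lapply(classes, function(cl) {
    tp <- sum(true == cl & predicted == cl)
    fp <- sum(true != cl & predicted == cl)
    fn <- sum(true == cl & predicted != cl)
    ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
    tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (ppv + tpr > 0) 2 * ppv * tpr / (ppv + tpr) else 0
    auc <- NA_real_
    if (!is.null(probabilities)) {
      pos <- true == cl
      if (all(pos) || !any(pos)) {
        warning("class '", cl, "' has single-valued truth; AUC skipped")
      } else {
        score <- probabilities[, cl]
        auc <- as.numeric(pROC::auc(pROC::roc(
          response = pos, predictor = score,
          direction = "<", levels = c(FALSE, TRUE), quiet = TRUE)))
      }
    }
    data.frame(class = cl, ppv = ppv, tpr = tpr, f1 = f1, auc = auc)
  })
  per <- do.call(rbind, per)
  list(
    macro_f1 = mean(per$f1),
    macro_tpr = mean(per$tpr),
    macro_ppv = mean(per$ppv),
    accuracy = mean(true == predicted),
    macro_rocauc = if (all(is.na(per$auc))) NA_real_ else
      mean(per$auc, na.rm = TRUE),
    per_class = per
  )
}

#' Regression metrics
#'
#' Median absolute error, mean absolute error, root mean square error and the
#' coefficient of determination R^2 = 1 - SS_res / SS_tot.
#'
#' @param true numeric truth.
#' @param predicted numeric predictions of equal length.
#' @return list: `median_ae`, `mean_ae`, `rmse`, `r2`.
#' @export
regression_metrics <- function(true, predicted) {
  stopifnot(length(true) == length(predicted), length(true) >= 2)
  if (stats::var(true) == 0) stop("truth has zero variance; R^2 undefined")
  err <- predicted - true
  list(
    median_ae = stats::median(abs(err)),
    mean_ae = mean(abs(err)),
    rmse = sqrt(mean(err^2)),
    r2 = 1 - sum(err^2) / sum((true - mean(true))^2)
  )
}

#' Harrell's concordance index
#'
#' A pair (i, j) is comparable when T_i < T_j and subject i died (E_i = 1);
#' it is concordant when the earlier death carries the higher risk score.
#' Ties in risk count one half; ties in time are skipped. C = 1 is perfect
#' ranking, C = 0.5 is random.
#'
#' @param risk numeric risk scores (higher = earlier expected death).
#' @param T observed times.
#' @param E event indicators in \{0,1\}.
#' @return concordance in \[0,1\].
#' @export
concordance_index <- function(risk, T, E) {
  stopifnot(length(risk) == length(T), length(T) == length(E),
            all(E %in% c(0, 1)))
  comparable <- outer(T, T, "<") & (E == 1)
  n_comp <- sum(comparable)
  if (n_comp == 0) stop("no comparable pairs")
  concordant <- sum(comparable & outer(risk, risk, ">"))
  tied <- sum(comparable & outer(risk, risk, "=="))
  (concordant + 0.5 * tied) / n_comp
}

# Kaplan-Meier estimate of the censoring distribution G(t) = P(C > t);
# returns an evaluator with a left-limit mode for G(t-).
censoring_km <- function(T, E) {
  fit <- survival::survfit(survival::Surv(T, 1 - E) ~ 1)
  times <- fit$time
  surv <- fit$surv
  function(t, minus = FALSE) {
    vapply(t, function(tt) {
      keep <- if (minus) times < tt else times <= tt
      if (!any(keep)) 1 else surv[max(which(keep))]
    }, 0)
  }
}

#' Brier score curve and integrated Brier score (IPCW)
#'
#' At each grid time t the Brier score is the
#' inverse-probability-of-censoring-weighted squared error between the
#' observed status 1\{T > t\} and the predicted survival probability S(t)
#' (Graf decomposition): subjects dead by t are weighted by 1/G(T-),
#' subjects still at risk by 1/G(t), censored subjects contribute nothing,
#' with G the Kaplan-Meier estimate of the censoring distribution. The IBS is
#' the average Brier score over the grid points up to the last observed event
#' time. If G reaches 0 before that, later times are dropped with a warning.
#' `ipcw = FALSE` uses unit weights.
#'
#' @param surv_curves samples x m matrix of predicted S(t_k) at the grid
#'   points (or a length-m vector for a single shared curve).
#' @param grid m+1 boundaries (t_0 = 0 first) or the m evaluation times.
#' @param T observed times.
#' @param E event indicators.
#' @param ipcw logical, apply censoring weights (default) or not.
#' @return list: `times`, per-time `brier`, scalar `ibs`.
#' @export
brier_and_ibs <- function(surv_curves, grid, T, E, ipcw = TRUE) {
  if (!is.matrix(surv_curves)) {
    surv_curves <- matrix(surv_curves, nrow = length(T),
                          ncol = length(surv_curves), byrow = TRUE)
  }
  times <- if (length(grid) == ncol(surv_curves) + 1L) grid[-1L] else grid
  stopifnot(ncol(surv_curves) == length(times),
            nrow(surv_curves) == length(T))
  G <- censoring_km(T, E)
  n <- length(T)
  brier <- vapply(seq_along(times), function(k) {
    t <- times[k]
    S <- surv_curves[, k]
    dead <- T <= t & E == 1
    alive <- T > t
    w_dead <- if (ipcw) 1 / G(T[dead], minus = TRUE) else rep(1, sum(dead))
    gt <- if (ipcw) G(t) else 1
    if (gt == 0) return(NA_real_)
    contrib <- sum(S[dead]^2 * w_dead) + sum((1 - S[alive])^2) / gt
    contrib / n
  }, 0)
  t_last_event <- if (any(E == 1)) max(T[E == 1]) else max(T)
  use <- times <= t_last_event
  if (any(is.na(brier[use]))) {
    warning("censoring distribution reached 0 before the last grid time; ",
            "later times dropped from the IBS")
    use <- use & !is.na(brier)
  }
  if (!any(use)) stop("no usable grid times for the IBS")
  list(times = times, brier = brier, ibs = mean(brier[use]))
}
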