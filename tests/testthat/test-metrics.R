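# Classification, regression and survival evaluation metrics against hand
# counts, brute force and permutation expectations.

test_that("perfect 3-class predictions score 1.0 on every macro metric", {
  truth <- rep(c("a", "b", "c"), each = 4)
  P <- matrix(0, 12, 3, dimnames = list(NULL, c("a", "b", "c")))
  P[cbind(1:12, rep(1:3, each = 4))] <- 1
  m <- macro_classification_metrics(truth, truth, P)
  expect_equal(m$macro_f1, 1)
  expect_equal(m$macro_tpr, 1)
  expect_equal(m$macro_ppv, 1)
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro_rocauc, 1)
})

test_that("macro metrics match a hand-counted 2x2 confusion matrix", {
  # confusion [[8,2],[3,7]]: 10 of A (8 right), 10 of B (7 right)
  truth <- rep(c("A", "B"), each = 10)
  pred <- c(rep("A", 8), rep("B", 2), rep("A", 3), rep("B", 7))
  m <- macro_classification_metrics(truth, pred)
  expect_equal(m$macro_tpr, (0.8 + 0.7) / 2)
  expect_equal(m$macro_ppv, (8 / 11 + 7 / 9) / 2)
  expect_equal(m$accuracy, 15 / 20)
  f1a <- 2 * (8 / 11) * 0.8 / (8 / 11 + 0.8)
  f1b <- 2 * (7 / 9) * 0.7 / (7 / 9 + 0.7)
  expect_equal(m$macro_f1, (f1a + f1b) / 2)
})

test_that("uniform random probabilities give chance-level macro AUC", {
  set.seed(1)
  n <- 2000
  truth <- sample(c("x", "y", "z"), n, replace = TRUE)
  P <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, c("x", "y", "z")))
  P <- P / rowSums(P)
  m <- macro_classification_metrics(truth, colnames(P)[max.col(P)], P)
  expect_lt(abs(m$macro_rocauc - 0.5), 0.03)
})

test_that("macro metrics are invariant to class-label permutation", {
  set.seed(2)
  truth <- sample(c("a", "b", "c"), 60, replace = TRUE)
  pred <- sample(c("a", "b", "c"), 60, replace = TRUE)
  m1 <- macro_classification_metrics(truth, pred)
  swap <- c(a = "c", b = "a", c = "b")
  m2 <- macro_classification_metrics(swap[truth], swap[pred])
  expect_equal(m1$macro_f1, m2$macro_f1)
  expect_equal(m1$macro_tpr, m2$macro_tpr)
  expect_equal(m1$accuracy, m2$accuracy)
})

test_that("a class with single-valued truth is skipped for AUC with a warning", {
  truth <- rep("a", 6)
  P <- matrix(c(0.6, 0.4), 6, 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  expect_warning(m <- macro_classification_metrics(truth, truth, P),
                 "single-valued")
  expect_true(is.na(m$macro_rocauc))
})

test_that("regression metrics match their definitions", {
  y <- c(1, 2, 3, 6)
  m <- regression_metrics(y, y)
  expect_equal(unlist(m[c("median_ae", "mean_ae", "rmse", "r2")]),
               c(median_ae = 0, mean_ae = 0, rmse = 0, r2 = 1))
  # predicting the mean gives R^2 = 0
  m2 <- regression_metrics(y, rep(mean(y), 4))
  expect_equal(m2$r2, 0)
  # toy 4-point set against hand arithmetic
  pred <- c(2, 2, 2, 7)
  m3 <- regression_metrics(y, pred)
  expect_equal(m3$median_ae, median(c(1, 0, 1, 1)))
  expect_equal(m3$mean_ae, 3 / 4)
  expect_equal(m3$rmse, sqrt(3 / 4))
  expect_equal(m3$r2, 1 - 3 / sum((y - 3)^2))
  expect_error(regression_metrics(c(2, 2), c(1, 3)), "zero variance")
})

test_that("concordance index matches limits and O(n^2) brute force", {
  Tv <- 1:6; Ev <- rep(1, 6)
  expect_equal(concordance_index(6:1, Tv, Ev), 1)     # anti-ordered risks
  expect_equal(concordance_index(rep(2, 6), Tv, Ev), 0.5)  # all ties
  set.seed(3)
  for (i in 1:50) {
    n <- 20
    Tv <- rexp(n); Ev <- rbinom(n, 1, 0.7)
    if (sum(Ev) == 0) Ev[1] <- 1
    risk <- rnorm(n)
    expect_equal(concordance_index(risk, Tv, Ev), cindex_brute(risk, Tv, Ev))
  }
  expect_error(concordance_index(1, 5, 0), "comparable")
})

test_that("flipping risk signs mirrors the concordance when no ties exist", {
  set.seed(4)
  Tv <- runif(30); Ev <- rbinom(30, 1, 0.6); Ev[1] <- 1
  risk <- rnorm(30)
  expect_equal(concordance_index(risk, Tv, Ev),
               1 - concordance_index(-risk, Tv, Ev))
})

test_that("Brier score is exact for oracle and constant predictors", {
  Tv <- c(1, 2, 3, 4, 5); Ev <- rep(1, 5)
  times <- c(0.5, 2.5, 4.5)
  oracle <- t(vapply(Tv, function(ti) as.numeric(ti > times), numeric(3)))
  b <- brier_and_ibs(oracle, times, Tv, Ev)
  expect_equal(b$brier, rep(0, 3))
  expect_equal(b$ibs, 0)
  # constant 1/2 with no censoring: (1/2)^2 at every time
  bh <- brier_and_ibs(matrix(0.5, 5, 3), times, Tv, Ev)
  expect_equal(bh$brier, rep(0.25, 3))
  expect_equal(bh$ibs, 0.25)
})

test_that("IPCW Brier matches the hand-worked 5-subject example", {
  # subjects T = 1..5, subject 2 censored; censoring KM drops to 3/4 at t=2
  Tv <- c(1, 2, 3, 4, 5); Ev <- c(1, 0, 1, 1, 1)
  S25 <- c(0.9, 0.5, 0.8, 0.3, 0.6)
  b <- brier_and_ibs(matrix(S25, 5, 1), 2.5, Tv, Ev)
  # dead: subject 1, weight 1/G(1-) = 1, error 0.9^2
  # alive: subjects 3,4,5, weight 1/G(2.5) = 4/3, errors (1-S)^2
  hand <- (0.9^2 * 1 + (0.2^2 + 0.7^2 + 0.4^2) * 4 / 3) / 5
  expect_equal(b$brier, hand, tolerance = 1e-12)
  expect_equal(b$ibs, hand, tolerance = 1e-12)
})

test_that("on data with signal the Kaplan-Meier curve beats the 1/2 predictor on IBS", {
  res <- synth_generate(synth_config(n_samples = 300, omics_dims = 5,
                                     hazard_effect = 1, censoring_rate = 0.3,
                                     seed = 9))
  ph <- res$dataset$phenotype
  grid <- make_time_grid(ph$survival_T, ph$survival_E, 10, "quantile")
  km <- survival::survfit(survival::Surv(ph$survival_T, ph$survival_E) ~ 1)
  km_s <- vapply(grid[-1], function(t) {
    s <- summary(km, times = min(t, max(km$time)))$surv
    if (length(s)) s else min(km$surv)
  }, 0)
  n <- nrow(ph)
  ibs_km <- brier_and_ibs(matrix(km_s, n, 10, byrow = TRUE), grid,
                          ph$survival_T, ph$survival_E)$ibs
  ibs_half <- brier_and_ibs(matrix(0.5, n, 10), grid,
                            ph$survival_T, ph$survival_E)$ibs
  expect_lte(ibs_km, ibs_half)
})
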