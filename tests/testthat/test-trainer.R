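# Joint loss assembly, GradNorm weighting and the three-phase schedule.

test_that("downstream loss is the weighted task mean", {
  expect_equal(downstream_loss(c(2, 4), c(1, 1)), 3)
  expect_equal(downstream_loss(5, 1.5), 7.5)
  expect_equal(downstream_loss(c(3, 99), c(2, 0)), 3)
})

test_that("total loss is linear in lambda", {
  expect_equal(total_loss(10, 2, 0), 2)
  expect_equal(total_loss(10, 2, 1), 12)
  for (lam in c(0.25, 0.5, 2)) {
    expect_equal(total_loss(10, 2, lam), lam * 10 + 2)
  }
  expect_error(total_loss(1, 1, -1))
})

test_that("relative inverse training rates follow the loss-ratio definition", {
  expect_equal(gradnorm_rates(c(0.5, 2), c(1, 2)), c(2/3, 4/3))
  expect_equal(gradnorm_rates(c(3, 3), c(3, 3)), c(1, 1))
  expect_error(gradnorm_rates(c(1, 1), c(0, 1)), "zero")
})

test_that("gradnorm_step is a fixed point under task symmetry and keeps sum(w) = K", {
  gs <- gradnorm_step(c(1, 1), c(0.7, 0.7), c(0.4, 0.4), c(1, 1))
  expect_equal(gs$weights, c(1, 1))
  expect_equal(gs$L_grad, 0)
  set.seed(1)
  w <- c(1, 1, 1)
  for (i in 1:50) {
    gs <- gradnorm_step(w, runif(3, 0.1, 2), runif(3, 0.1, 2),
                        c(1, 1.5, 0.7), alpha = 1)
    w <- gs$weights
    expect_lt(abs(sum(w) - 3), 1e-9)
    expect_true(all(w > 0))
  }
})

test_that("at alpha = 0 the weight update shrinks the gradient-norm spread", {
  norms <- c(2, 0.5)          # task 1 too strong, task 2 too weak
  losses <- c(1, 1); L0 <- c(1, 1)
  w <- c(1, 1)
  spread_before <- sum(abs(w * norms - mean(w * norms)))
  gs <- gradnorm_step(w, norms, losses, L0, alpha = 0, lr = 0.05)
  spread_after <- sum(abs(gs$weights * norms - mean(gs$weights * norms)))
  expect_lt(spread_after, spread_before)
  expect_lt(gs$weights[1], 1)   # strong task down-weighted
  expect_gt(gs$weights[2], 1)
})

test_that("single-task training is unchanged by the GradNorm toggle", {
  st <- make_tiny_study()
  tasks <- list(class = list(type = "classification", label = "class"))
  f1 <- train_multitask(st$X, st$phenotype, tasks, tiny_config(gradnorm = TRUE),
                        train_idx = st$split$train)
  f2 <- train_multitask(st$X, st$phenotype, tasks, tiny_config(gradnorm = FALSE),
                        train_idx = st$split$train)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("training is reproducible under a fixed seed", {
  st <- make_tiny_study()
  f1 <- train_multitask(st$X, st$phenotype, all_tasks(), tiny_config(),
                        train_idx = st$split$train, val_idx = st$split$val)
  f2 <- train_multitask(st$X, st$phenotype, all_tasks(), tiny_config(),
                        train_idx = st$split$train, val_idx = st$split$val)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)
})

test_that("task weights stay at 1 before Phase 3 and sum to K during it", {
  st <- make_tiny_study()
  fit <- train_multitask(st$X, st$phenotype, all_tasks(), tiny_config(),
                         train_idx = st$split$train)
  h <- fit$history
  wcols <- grep("^w_", names(h))
  expect_true(all(h[h$phase < 3, wcols] == 1))
  expect_true(all(abs(rowSums(h[, wcols]) - 3) < 1e-9))
  expect_length(fit$initial_losses, 3)
})

test_that("the survival head only starts learning once Phase 2 begins", {
  st <- make_tiny_study(n = 200)
  fit <- train_multitask(st$X, st$phenotype, all_tasks(),
                         tiny_config(epochs = c(4, 15, 0), batch_size = 16),
                         train_idx = st$split$train)
  h <- fit$history
  expect_lt(mean(h$loss_surv[h$phase == 2]),
            mean(h$loss_surv[h$phase == 1]))
})

test_that("validation losses are tracked and finite", {
  st <- make_tiny_study()
  fit <- train_multitask(st$X, st$phenotype, all_tasks(), tiny_config(),
                         train_idx = st$split$train, val_idx = st$split$val)
  expect_true(all(is.finite(fit$history$val_total)))
  expect_true(all(c("val_loss_class", "val_loss_age", "val_loss_surv") %in%
                    names(fit$history)))
})

test_that("prediction outputs are complete, deterministic and well-formed", {
  st <- make_tiny_study()
  fit <- train_multitask(st$X, st$phenotype, all_tasks(), tiny_config(),
                         train_idx = st$split$train)
  p1 <- predict_multitask(fit, st$X, st$split$test)
  p2 <- predict_multitask(fit, st$X, st$split$test)
  expect_identical(p1, p2)
  n <- length(st$split$test)
  expect_equal(dim(p1$latent), c(n, 6))
  expect_equal(unname(rowSums(p1$class$probabilities)), rep(1, n),
               tolerance = 1e-12)
  expect_true(all(p1$surv$survival >= 0 & p1$surv$survival <= 1))
  expect_true(all(apply(p1$surv$survival, 1, function(s) all(diff(s) <= 1e-12))))
  expect_true(all(is.finite(p1$age$predicted)))
})

test_that("training rejects tasks whose labels are absent", {
  st <- make_tiny_study()
  expect_error(train_multitask(st$X, st$phenotype,
                               list(x = list(type = "classification",
                                             label = "nope")),
                               tiny_config(), train_idx = st$split$train),
               "no column")
  ph2 <- st$phenotype; ph2$survival_T <- NULL
  expect_error(train_multitask(st$X, ph2, list(s = list(type = "survival")),
                               tiny_config(), train_idx = st$split$train),
               "survival_T")
})
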