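# Multi-task training: joint loss assembly, the three-phase schedule
# (unsupervised embedding -> heads on frozen embedding -> joint fine-tuning),
# and gradient-norm task weighting in the joint phase.

#' Weighted downstream loss
#'
#' L_down = (1/K) * sum_k w_k * L_k over the K downstream tasks.
#'
#' @param task_losses numeric vector of per-task losses.
#' @param weights positive task weights of the same length.
#' @return scalar.
#' @export
downstream_loss <- function(task_losses, weights) {
  stopifnot(length(task_losses) == length(weights), length(task_losses) >= 1)
  mean(weights * task_losses)
}

#' Total joint loss
#'
#' L_total = lambda * L_embed + L_down; lambda balances the unsupervised
#' embedding term against the supervised downstream term.
#'
#' @param embed_loss scalar embedding loss.
#' @param down_loss scalar downstream loss.
#' @param lambda non-negative balance.
#' @return scalar.
#' @export
total_loss <- function(embed_loss, down_loss, lambda) {
  stopifnot(lambda >= 0)
  lambda * embed_loss + down_loss
}

#' Relative inverse training rates for GradNorm
#'
#' r_k = Ltilde_k / mean(Ltilde) with Ltilde_k = L_k / L0_k, the ratio of the
#' current to the initial loss of task k. Tasks that have decayed less than
#' average (r_k > 1) get a larger gradient-norm target.
#'
#' @param losses current per-task losses.
#' @param initial_losses per-task losses at the first joint-phase iteration.
#' @return numeric vector r with mean 1.
#' @export
gradnorm_rates <- function(losses, initial_losses) {
  stopifnot(length(losses) == length(initial_losses))
  if (any(initial_losses == 0)) stop("initial task loss of zero")
  lt <- losses / initial_losses
  lt / mean(lt)
}

#' One GradNorm update of the task weights
#'
#' Computes per-task gradient norms G_k = ||grad_theta(w_k * L_k)||_2 at the
#' last encoding layer, their mean, the relative inverse training rates r_k,
#' and the GradNorm loss L_grad = sum_k |G_k - Gbar * r_k^alpha| with the
#' targets treated as constants. The weights are updated by one gradient step
#' on L_grad (analytic: dL_grad/dw_k = sign(G_k - target_k) * ||grad L_k||)
#' and renormalised so they sum to K.
#'
#' @param weights current positive task weights w_k.
#' @param grad_norms unweighted gradient norms ||grad_theta L_k||_2.
#' @param losses current per-task losses L_k.
#' @param initial_losses L0_k recorded at the first joint-phase iteration.
#' @param alpha asymmetry strength pulling tasks to a common rate.
#' @param lr step size for the weight update.
#' @return list: updated `weights`, `L_grad`, per-task `G`, `targets`, `r`.
#' @export
gradnorm_step <- function(weights, grad_norms, losses, initial_losses,
                          alpha = 1, lr = 0.025) {
  K <- length(weights)
  stopifnot(length(grad_norms) == K, length(losses) == K)
  r <- gradnorm_rates(losses, initial_losses)
  G <- weights * grad_norms
  Gbar <- mean(G)
  targets <- Gbar * r^alpha
  L_grad <- sum(abs(G - targets))
  gw <- sign(G - targets) * grad_norms
  w <- weights - lr * gw
  w <- pmax(w, 1e-4)
  w <- w * K / sum(w)
  list(weights = w, L_grad = L_grad, G = G, targets = targets, r = r)
}

# ---------------------------------------------------------------------------
# Loss + analytic gradient assembly for one batch.
#
# phase 1: loss = L_embed, gradients for embedding parameters only.
# phase 2: loss = L_down,  gradients for head parameters only.
# phase 3: loss = lambda*L_embed + L_down, gradients for everything; when
#          want_gnorm, also per-task ||grad_{mu-layer W} L_k||_F for GradNorm.
#
# targets: list per task -- classification: integer labels 1..K;
# regression: numeric (standardised); survival: list of label encodings.
mt_losses_grads <- function(model, cache, targets, weights, phase, lambda,
                            want_grads = TRUE, want_gnorm = FALSE) {
  p <- model$params
  M <- model$n_blocks
  B <- nrow(cache$MU)
  X <- cache$X
  LG <- cache$dec$LG

  # reconstruction (stable BCE from logits) and KL
  recon <- 0
  for (b in seq_len(M)) {
    lg <- LG[[b]]
    bce <- pmax(lg, 0) - lg * X[[b]] + log1p(exp(-abs(lg)))
    recon <- recon + mean(rowSums(bce))
  }
  recon <- recon / M
  kl <- mean(0.5 * rowSums(cache$MU^2 + exp(cache$LV) - 1 - cache$LV))
  embed <- recon + kl

  # per-task losses and raw output gradients dL_k/dOUT
  Ktasks <- length(model$tasks)
  task_losses <- numeric(Ktasks)
  dOUT_raw <- vector("list", Ktasks)
  probs_cache <- vector("list", Ktasks)
  for (k in seq_len(Ktasks)) {
    type <- model$tasks[[k]]$type
    OUT <- cache$heads[[k]]$OUT
    if (type == "classification") {
      P <- softmax_rows(OUT)
      lab <- targets[[k]]
      task_losses[k] <- mean(-log(pmax(P[cbind(seq_len(B), lab)], 1e-300)))
      Y <- matrix(0, B, ncol(OUT)); Y[cbind(seq_len(B), lab)] <- 1
      dOUT_raw[[k]] <- (P - Y) / B
      probs_cache[[k]] <- P
    } else if (type == "regression") {
      pred <- OUT[, 1]
      y <- targets[[k]]
      task_losses[k] <- mean((pred - y)^2)
      dOUT_raw[[k]] <- matrix(2 * (pred - y) / B, ncol = 1)
    } else {
      sl <- survival_loss(OUT, targets[[k]])
      task_losses[k] <- as.numeric(sl)
      dOUT_raw[[k]] <- attr(sl, "gradient")
    }
  }
  down <- downstream_loss(task_losses, weights)
  total <- switch(phase, embed, down, total_loss(embed, down, lambda))

  losses <- list(recon = recon, kl = kl, embed = embed,
                 task = task_losses, down = down, total = total)
  if (!want_grads) {
    return(list(losses = losses, probs = probs_cache))
  }

  grads <- list()
  embed_scale <- if (phase == 1) 1 else if (phase == 3) lambda else 0
  down_on <- phase >= 2

  # heads backward; accumulate dL/dZ
  dZ <- matrix(0, B, model$latent_dim)
  dZ_raw <- if (want_gnorm) vector("list", Ktasks) else NULL
  if (down_on || want_gnorm) {
    for (k in seq_len(Ktasks)) {
      hc <- cache$heads[[k]]
      W2 <- p[[paste0("task", k, "_W2")]]
      W1 <- p[[paste0("task", k, "_W1")]]
      back_head <- function(dout) {
        dHKd <- dout %*% t(W2)
        dHK <- if (is.null(hc$drop_mask)) dHKd else dHKd * hc$drop_mask / hc$keep
        dK1 <- dHK * lrelu_grad(hc$K1)
        list(dK1 = dK1, dZ = dK1 %*% t(W1))
      }
      if (want_gnorm) {
        bh_raw <- back_head(dOUT_raw[[k]])
        dZ_raw[[k]] <- bh_raw$dZ
      }
      if (down_on) {
        scale_k <- weights[k] / Ktasks
        dout <- dOUT_raw[[k]] * scale_k
        bh <- back_head(dout)
        grads[[paste0("task", k, "_W2")]] <- t(hc$HKd) %*% dout
        grads[[paste0("task", k, "_b2")]] <- colSums(dout)
        grads[[paste0("task", k, "_W1")]] <- t(cache$Z) %*% bh$dK1
        grads[[paste0("task", k, "_b1")]] <- colSums(bh$dK1)
        dZ <- dZ + bh$dZ
      }
    }
  }

  gnorm <- NULL
  if (want_gnorm) {
    # || d L_k / d W_mu ||_F with theta = the mu bottleneck weights; the
    # latent-to-mu path has unit Jacobian, so dL_k/dMU = dL_k/dZ.
    gnorm <- vapply(seq_len(Ktasks), function(k) {
      sqrt(sum((t(cache$Hf) %*% dZ_raw[[k]])^2))
    }, 0)
  }

  # decoder backward (embedding loss path)
  if (embed_scale > 0) {
    dHd1 <- matrix(0, B, model$hidden_fusion)
    Hd1 <- cache$dec$Hd1
    for (b in seq_len(M)) {
      dLG <- embed_scale * (sigmoid(LG[[b]]) - X[[b]]) / (M * B)
      Hd2 <- cache$dec$Hd2[[b]]
      Wd3 <- p[[paste0("dec", b, "o_W")]]
      grads[[paste0("dec", b, "o_W")]] <- t(Hd2) %*% dLG
      grads[[paste0("dec", b, "o_b")]] <- colSums(dLG)
      dHd2 <- dLG %*% t(Wd3)
      dD2 <- dHd2 * lrelu_grad(cache$dec$D2[[b]])
      Wd2 <- p[[paste0("dec", b, "h_W")]]
      grads[[paste0("dec", b, "h_W")]] <- t(Hd1) %*% dD2
      grads[[paste0("dec", b, "h_b")]] <- colSums(dD2)
      dHd1 <- dHd1 + dD2 %*% t(Wd2)
    }
    dD1 <- dHd1 * lrelu_grad(cache$dec$D1)
    grads$dec0_W <- t(cache$Z) %*% dD1
    grads$dec0_b <- colSums(dD1)
    dZ <- dZ + dD1 %*% t(p$dec0_W)
  }

  # encoder backward (needed in phases 1 and 3)
  if (phase != 2) {
    dMU <- dZ + embed_scale * cache$MU / B
    dLV <- dZ * cache$EPS * cache$SD / 2 +
      embed_scale * (exp(cache$LV) - 1) / (2 * B)
    grads$mu_W <- t(cache$Hf) %*% dMU
    grads$mu_b <- colSums(dMU)
    grads$lv_W <- t(cache$Hf) %*% dLV
    grads$lv_b <- colSums(dLV)
    dHf <- dMU %*% t(p$mu_W) + dLV %*% t(p$lv_W)
    dA2 <- dHf * lrelu_grad(cache$A2)
    grads$fus_W <- t(cache$Hc) %*% dA2
    grads$fus_b <- colSums(dA2)
    dHc <- dA2 %*% t(p$fus_W)
    dH1 <- split_cols(dHc, model$enc_widths)
    for (b in seq_len(M)) {
      dA1 <- dH1[[b]] * lrelu_grad(cache$A1[[b]])
      gW <- t(X[[b]]) %*% dA1
      mask <- model$masks[[paste0("enc", b, "_W")]]
      if (!is.null(mask)) gW <- gW * mask
      grads[[paste0("enc", b, "_W")]] <- gW
      grads[[paste0("enc", b, "_b")]] <- colSums(dA1)
    }
  }

  list(losses = losses, grads = grads, gnorm = gnorm, probs = probs_cache)
}

#' Training configuration
#'
#' Collects every tunable of the multi-task trainer with defaults sized for
#' datasets of a few hundred samples and a few hundred features per block.
#'
#' @param latent_dim latent dimension p.
#' @param hidden_per_block,hidden_fusion,head_hidden layer widths.
#' @param lambda embedding-loss weight in the joint phase; `NULL` uses the
#'   heuristic 0.01 * p / mean(omics_dims).
#' @param alpha GradNorm asymmetry strength.
#' @param m number of survival time intervals (capped at the number of
#'   observed events in the training split).
#' @param grid_scheme `"quantile"` or `"uniform"` time grid.
#' @param epochs integer vector of length 3: epochs of Phase 1 (unsupervised
#'   embedding), Phase 2 (heads on the frozen embedding) and Phase 3 (joint
#'   fine-tuning).
#' @param batch_size minibatch size.
#' @param lr Adam learning rate; decays by `lr_gamma` every `lr_step` epochs
#'   within each phase.
#' @param lr_gamma,lr_step step learning-rate schedule.
#' @param weight_decay L2 penalty added to weight gradients (biases exempt).
#' @param dropout dropout rate on the heads' hidden layers during training.
#' @param gradnorm enable GradNorm task weighting in Phase 3 (needs >= 2
#'   tasks).
#' @param gradnorm_lr step size of the task-weight update.
#' @param recon_reduction `"sum"` or `"mean"` over features in the BCE.
#' @param seed RNG seed controlling initialisation, batching and sampling.
#' @return list of class `omix_train_config`.
#' @export
train_config <- function(latent_dim = 16, hidden_per_block = 64,
                         hidden_fusion = 64, head_hidden = 32,
                         lambda = NULL, alpha = 1, m = 256,
                         grid_scheme = "quantile",
                         epochs = c(10, 30, 30), batch_size = 32,
                         lr = 1e-3, lr_gamma = 0.5, lr_step = 20,
                         weight_decay = 1e-4, dropout = 0,
                         gradnorm = TRUE, gradnorm_lr = 0.025,
                         recon_reduction = "sum", seed = 1) {
  stopifnot(length(epochs) == 3, all(epochs >= 0), sum(epochs) > 0)
  cfg <- as.list(environment())
  class(cfg) <- "omix_train_config"
  cfg
}

# Resolve task descriptors against the data: attach class levels, regression
# standardisation, the survival grid and encoded labels.
resolve_tasks <- function(tasks, phenotype, train_idx, other_idx, config,
                          fixed_m = NULL) {
  out <- list()
  for (nm in names(tasks)) {
    tk <- tasks[[nm]]
    tk$name <- nm
    if (tk$type == "classification") {
      col <- phenotype[[tk$label]]
      if (is.null(col)) stop("phenotype has no column '", tk$label, "'")
      f <- factor(col)
      tk$levels <- levels(f)
      tk$n_classes <- nlevels(f)
      tk$target <- as.integer(f)
    } else if (tk$type == "regression") {
      y <- phenotype[[tk$label]]
      if (is.null(y)) stop("phenotype has no column '", tk$label, "'")
      mu <- mean(y[train_idx]); sdv <- stats::sd(y[train_idx])
      if (sdv == 0) stop("regression target is constant on the training split")
      tk$centre <- mu; tk$scale <- sdv
      tk$target <- (y - mu) / sdv
      tk$raw <- y
    } else if (tk$type == "survival") {
      Tv <- phenotype$survival_T; Ev <- phenotype$survival_E
      if (is.null(Tv) || is.null(Ev)) {
        stop("phenotype lacks survival_T / survival_E columns")
      }
      n_events <- sum(Ev[train_idx] == 1)
      if (n_events == 0) stop("no observed events in the training split")
      m_eff <- if (!is.null(fixed_m)) fixed_m else min(config$m, n_events)
      grid <- make_time_grid(Tv[train_idx], Ev[train_idx], m_eff,
                             scheme = config$grid_scheme)
      # the grid must cover every subject the model will score during training
      tmax_all <- max(Tv[c(train_idx, other_idx)])
      grid[length(grid)] <- max(grid[length(grid)], tmax_all)
      tk$grid <- grid
      tk$m <- m_eff
      tk$target <- lapply(seq_along(Tv), function(i) {
        if (i %in% c(train_idx, other_idx)) {
          encode_survival_label(Tv[i], Ev[i], grid)
        } else NULL
      })
      tk$T <- Tv; tk$E <- Ev
    } else {
      stop("unknown task type: ", tk$type)
    }
    out[[nm]] <- tk
  }
  out
}

batch_targets <- function(tasks_resolved, idx) {
  lapply(tasks_resolved, function(tk) {
    if (tk$type == "survival") tk$target[idx] else tk$target[idx]
  })
}

#' Train the multi-task model in three phases
#'
#' Phase 1 optimises the embedding loss alone (heads untouched); Phase 2
#' optimises the weighted downstream loss with the embedding frozen; Phase 3
#' fine-tunes everything on lambda * L_embed + L_down, updating the task
#' weights by GradNorm at each iteration when two or more tasks are present
#' (initial losses L0 are recorded at the first Phase-3 iteration). Each
#' phase uses a fresh Adam optimiser with a step learning-rate schedule.
#' Fully reproducible under `config$seed`.
#'
#' @param X_blocks list of omics matrices (samples x features, values in
#'   \[0,1\]), aligned rows across blocks.
#' @param phenotype data.frame with one row per sample: label columns plus
#'   reserved `survival_T`, `survival_E` when a survival task is configured.
#' @param tasks named list of task descriptors: `list(type =
#'   "classification", label = <column>)`, `list(type = "regression", label =
#'   <column>)`, `list(type = "survival")`.
#' @param config an [train_config()] object.
#' @param train_idx integer indices of training samples.
#' @param val_idx optional validation indices (per-epoch validation losses
#'   recorded).
#' @param model optional prebuilt [build_model()]; built from the config
#'   otherwise (a prebuilt survival head fixes the number of intervals m).
#' @param chromosome_blocks optional per-block chromosome annotation passed
#'   to [build_model()] when the model is built here.
#' @return an `omix_fit`: trained model, resolved task metadata, task
#'   weights, training history (one row per epoch) and the config.
#' @export
train_multitask <- function(X_blocks, phenotype, tasks, config = train_config(),
                            train_idx, val_idx = NULL, model = NULL,
                            chromosome_blocks = NULL) {
  set.seed(config$seed)
  if (is.matrix(X_blocks)) X_blocks <- list(X_blocks)
  n <- nrow(X_blocks[[1]])
  stopifnot(all(vapply(X_blocks, nrow, 1L) == n), nrow(phenotype) == n)

  fixed_m <- NULL
  if (!is.null(model)) {
    sk <- which(vapply(model$tasks, function(t) t$type == "survival", TRUE))
    if (length(sk)) fixed_m <- model$tasks[[sk[1]]]$n_out
  }
  tres <- resolve_tasks(tasks, phenotype, train_idx, val_idx, config, fixed_m)
  K <- length(tres)

  if (is.null(model)) {
    desc <- lapply(tres, function(tk) {
      list(type = tk$type, label = tk$label,
           n_classes = tk$n_classes, m = tk$m)
    })
    model <- build_model(vapply(X_blocks, ncol, 1L), desc,
                         latent_dim = config$latent_dim,
                         hidden_per_block = config$hidden_per_block,
                         hidden_fusion = config$hidden_fusion,
                         head_hidden = config$head_hidden,
                         chromosome_blocks = chromosome_blocks)
  }
  lambda <- config$lambda
  if (is.null(lambda)) {
    lambda <- 0.01 * model$latent_dim / mean(model$omics_dims)
  }

  Xtr <- lapply(X_blocks, function(x) x[train_idx, , drop = FALSE])
  n_tr <- length(train_idx)
  weights <- rep(1, K)
  L0 <- NULL
  history <- list()
  global_epoch <- 0L

  active_sets <- list(model$groups$embedding, model$groups$downstream,
                      names(model$params))
  for (phase in 1:3) {
    n_ep <- config$epochs[phase]
    if (n_ep == 0) next
    opt <- adam_init(model$params)
    active <- active_sets[[phase]]
    for (ep in seq_len(n_ep)) {
      global_epoch <- global_epoch + 1L
      lr_e <- config$lr * config$lr_gamma^floor((ep - 1) / config$lr_step)
      perm <- sample.int(n_tr)
      starts <- seq(1, n_tr, by = config$batch_size)
      acc <- NULL; n_b <- 0L
      for (s in starts) {
        bidx <- perm[s:min(s + config$batch_size - 1L, n_tr)]
        Xb <- lapply(Xtr, function(x) x[bidx, , drop = FALSE])
        tb <- batch_targets(tres, train_idx[bidx])
        cache <- mt_forward(model, Xb, drop_rate = config$dropout)
        use_gn <- phase == 3 && K >= 2 && isTRUE(config$gradnorm)
        lg <- mt_losses_grads(model, cache, tb, weights, phase, lambda,
                              want_gnorm = use_gn)
        upd <- adam_step(model$params, lg$grads, opt, lr_e, active = active,
                         weight_decay = config$weight_decay)
        model$params <- upd$params
        opt <- upd$state
        if (use_gn) {
          if (is.null(L0)) L0 <- lg$losses$task
          gs <- gradnorm_step(weights, lg$gnorm, lg$losses$task, L0,
                              alpha = config$alpha, lr = config$gradnorm_lr)
          weights <- gs$weights
        }
        vals <- c(recon = lg$losses$recon, kl = lg$losses$kl,
                  down = lg$losses$down, total = lg$losses$total,
                  stats::setNames(lg$losses$task,
                                  paste0("loss_", names(tres))))
        acc <- if (is.null(acc)) vals else acc + vals
        n_b <- n_b + 1L
      }
      row <- as.list(acc / n_b)
      row$epoch <- global_epoch; row$phase <- phase; row$lr <- lr_e
      for (k in seq_len(K)) row[[paste0("w_", names(tres)[k])]] <- weights[k]
      if (!is.null(val_idx)) {
        Xv <- lapply(X_blocks, function(x) x[val_idx, , drop = FALSE])
        cv <- mt_forward(model, Xv, eps = 0)
        lv <- mt_losses_grads(model, cv, batch_targets(tres, val_idx),
                              weights, phase, lambda, want_grads = FALSE)
        row$val_total <- lv$losses$total
        row$val_down <- lv$losses$down
        for (k in seq_len(K)) {
          row[[paste0("val_loss_", names(tres)[k])]] <- lv$losses$task[k]
        }
      }
      history[[length(history) + 1L]] <- row
    }
  }
  hist_df <- do.call(rbind, lapply(history, function(r) {
    as.data.frame(r, check.names = FALSE)
  }))
  fit <- list(model = model, tasks = tres, weights = weights,
              initial_losses = L0, lambda = lambda, config = config,
              history = hist_df, train_idx = train_idx, val_idx = val_idx)
  class(fit) <- "omix_fit"
  fit
}

#' @export
print.omix_fit <- function(x, ...) {
  cat("Trained multi-task omics model (", nrow(x$history), "epochs )\n")
  cat("  tasks:", paste(names(x$tasks), collapse = ", "), "\n")
  cat("  final task weights:", paste(sprintf("%.3f", x$weights),
                                     collapse = ", "), "\n")
  cat("  final training loss:", sprintf("%.4f", utils::tail(x$history$total, 1)),
      "\n")
  invisible(x)
}

#' Predict with a trained multi-task model
#'
#' Runs the deterministic forward pass (z = mu) and returns, per task:
#' class probabilities and the predicted class, the back-transformed
#' regression prediction, or the survival outcome pmf, survival function at
#' the grid points and the hazard-sum risk score. The latent coordinates are
#' always included.
#'
#' @param fit an `omix_fit`.
#' @param X_blocks list of omics matrices aligned with the training blocks.
#' @param idx optional row indices to score (default: all rows).
#' @return list with `latent` and one entry per task.
#' @export
predict_multitask <- function(fit, X_blocks, idx = NULL) {
  if (is.matrix(X_blocks)) X_blocks <- list(X_blocks)
  if (!is.null(idx)) {
    X_blocks <- lapply(X_blocks, function(x) x[idx, , drop = FALSE])
  }
  cache <- mt_forward(fit$model, X_blocks, eps = 0)
  out <- list(latent = cache$MU)
  for (k in seq_along(fit$tasks)) {
    tk <- fit$tasks[[k]]
    OUT <- cache$heads[[k]]$OUT
    if (tk$type == "classification") {
      P <- softmax_rows(OUT)
      colnames(P) <- tk$levels
      out[[tk$name]] <- list(
        probabilities = P,
        predicted = tk$levels[max.col(P, ties.method = "first")]
      )
    } else if (tk$type == "regression") {
      out[[tk$name]] <- list(predicted = OUT[, 1] * tk$scale + tk$centre)
    } else {
      pmf <- survival_pmf(OUT)
      S <- survival_function(pmf, tk$grid)
      out[[tk$name]] <- list(pmf = pmf, survival = S,
                             risk = risk_score(pmf), grid = tk$grid)
    }
  }
  out
}

#' Evaluate a trained model on held-out samples
#'
#' Applies the metric battery appropriate to each task: macro-averaged
#' classification metrics, regression error metrics, and concordance index
#' plus IPCW Brier/integrated Brier score for survival.
#'
#' @param fit an `omix_fit`.
#' @param X_blocks aligned omics matrices (all samples).
#' @param phenotype phenotype table (all samples).
#' @param idx indices of the evaluation samples.
#' @return named list of per-task metric reports.
#' @export
evaluate_fit <- function(fit, X_blocks, phenotype, idx) {
  pred <- predict_multitask(fit, X_blocks, idx)
  out <- list()
  for (nm in names(fit$tasks)) {
    tk <- fit$tasks[[nm]]
    if (tk$type == "classification") {
      truth <- factor(phenotype[[tk$label]][idx], levels = tk$levels)
      out[[nm]] <- macro_classification_metrics(
        truth, pred[[nm]]$predicted, pred[[nm]]$probabilities)
    } else if (tk$type == "regression") {
      out[[nm]] <- regression_metrics(phenotype[[tk$label]][idx],
                                      pred[[nm]]$predicted)
    } else {
      Tv <- phenotype$survival_T[idx]; Ev <- phenotype$survival_E[idx]
      bi <- brier_and_ibs(pred[[nm]]$survival, tk$grid, Tv, Ev)
      out[[nm]] <- list(
        c_index = concordance_index(pred[[nm]]$risk, Tv, Ev),
        brier = bi$brier, ibs = bi$ibs
      )
    }
  }
  out
}
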