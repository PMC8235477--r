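# Synthetic multi-omics generator: a single low-dimensional latent factor
# drives every omics block and every phenotype (class, age, gender, hazard),
# giving each downstream head a known ground truth. Class centroids sit on
# scaled coordinate axes of the true latent space; omics blocks are
# elementwise sigmoids of noisy random linear maps of the latent, so all
# values lie in [0,1] by construction; survival times are exponential with a
# log-linear hazard in latent axis 1 and independent exponential censoring
# calibrated to the requested censored fraction.

#' Synthetic multi-omics configuration
#'
#' @param n_samples number of samples.
#' @param omics_dims per-block feature counts; blocks 1..3 are typed
#'   expression / methylation / miRNA, further blocks "other".
#' @param latent_dim_true dimension of the generating latent space; must be
#'   at least `n_classes` (one centroid axis per class).
#' @param n_classes number of phenotype classes, sampled uniformly.
#' @param class_separation pairwise Euclidean distance between class
#'   centroids in the true latent space.
#' @param age_noise_sd sd (years) of the noise on the age label; age is an
#'   affine map of latent axis 2.
#' @param baseline_hazard exponential death rate per unit time at latent
#'   axis 1 = 0.
#' @param hazard_effect log-hazard coefficient on latent axis 1.
#' @param censoring_rate target fraction of censored subjects in \[0,1).
#' @param missing_rate fraction of omics entries replaced by missing markers.
#' @param seed RNG seed; identical configs generate bit-identical data.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 600, omics_dims = c(200, 300, 100),
                         latent_dim_true = NULL, n_classes = 4,
                         class_separation = 5, age_noise_sd = 5,
                         baseline_hazard = 0.1, hazard_effect = 1,
                         censoring_rate = 0.3, missing_rate = 0,
                         seed = 1) {
  if (is.null(latent_dim_true)) latent_dim_true <- max(4, n_classes)
  stopifnot(n_samples >= 1, all(omics_dims >= 1), latent_dim_true >= 1,
            n_classes >= 1, class_separation >= 0, age_noise_sd >= 0,
            baseline_hazard > 0, missing_rate >= 0, missing_rate <= 1)
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop("censoring_rate must lie in [0, 1)")
  }
  if (n_classes > latent_dim_true) {
    stop("latent_dim_true must be >= n_classes (one centroid axis per class)")
  }
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

block_type_names <- function(M) {
  base <- c("expression", "methylation", "mirna")
  if (M <= 3) base[seq_len(M)] else c(base, rep("other", M - 3))
}

#' Generate a synthetic multi-omics dataset with ground truth
#'
#' Classes are sampled uniformly; the true latent of a sample is its class
#' centroid (at distance `class_separation` from every other centroid, on
#' scaled coordinate axes) plus unit Gaussian noise. Each omics block is the
#' elementwise sigmoid of a fixed random linear map of the latent plus
#' Gaussian noise. Age is affine in latent axis 2, gender thresholds latent
#' axis 3, and the death time is exponential with rate
#' `baseline_hazard * exp(hazard_effect * latent_1)`. Censoring times are
#' exponential with a rate solved numerically so the expected censored
#' fraction matches `censoring_rate`, independent of covariates;
#' T = min(death, censor), E = 1\{death <= censor\}. Finally a `missing_rate`
#' fraction of omics entries is set missing.
#'
#' @param config a [synth_config()].
#' @return list with `dataset` (an `omics_dataset`: blocks + phenotype) and
#'   `truth` (true latent, class, age, risk linear predictor, death/censor
#'   times).
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_samples
  q <- config$latent_dim_true
  K <- config$n_classes

  centroids <- matrix(0, K, q)
  for (k in seq_len(K)) {
    centroids[k, k] <- config$class_separation / sqrt(2)
  }
  cls <- sample.int(K, n, replace = TRUE)
  Zt <- centroids[cls, , drop = FALSE] + matrix(stats::rnorm(n * q), n, q)

  sample_ids <- sprintf("S%04d", seq_len(n))
  types <- block_type_names(length(config$omics_dims))
  prefixes <- c(expression = "gene", methylation = "cg", mirna = "mir",
                other = "feat")
  blocks <- vector("list", length(config$omics_dims))
  for (b in seq_along(config$omics_dims)) {
    d <- config$omics_dims[b]
    W <- matrix(stats::rnorm(q * d, sd = 1 / sqrt(q)), q, d)
    intercept <- stats::rnorm(d, sd = 0.5)
    U <- Zt %*% W + matrix(intercept, n, d, byrow = TRUE) +
      matrix(stats::rnorm(n * d, sd = 0.3), n, d)
    V <- sigmoid(U)
    fid <- sprintf("%s_%05d", prefixes[[types[b]]], seq_len(d))
    dimnames(V) <- list(sample_ids, fid)
    ann <- NULL
    if (types[b] == "methylation") {
      ann <- data.frame(feature_id = fid,
                        chromosome = paste0("chr", ((seq_len(d) - 1) %% 22) + 1))
    }
    blocks[[b]] <- new_omics_block(V, name = paste0(types[b], b),
                                   type = types[b], annotation = ann)
  }

  age <- 50 + 10 * Zt[, min(2, q)] + stats::rnorm(n, sd = config$age_noise_sd)
  gender <- ifelse(Zt[, min(3, q)] > 0, "female", "male")
  lp <- config$hazard_effect * Zt[, 1]
  rate <- config$baseline_hazard * exp(lp)
  death <- stats::rexp(n, rate = rate)
  if (config$censoring_rate == 0) {
    censor <- rep(Inf, n)
  } else {
    # P(C < D | rate_i) = rc / (rc + rate_i) for independent exponentials;
    # solve rc so the mean over subjects hits the target censored fraction.
    f <- function(log_rc) {
      rc <- exp(log_rc)
      mean(rc / (rc + rate)) - config$censoring_rate
    }
    log_rc <- stats::uniroot(f, lower = log(1e-10), upper = log(1e10))$root
    censor <- stats::rexp(n, rate = exp(log_rc))
  }
  Tobs <- pmin(death, censor)
  E <- as.numeric(death <= censor)

  if (config$missing_rate > 0) {
    for (b in seq_along(blocks)) {
      v <- blocks[[b]]$values
      n_miss <- round(config$missing_rate * length(v))
      if (n_miss > 0) {
        v[sample.int(length(v), n_miss)] <- NA
        blocks[[b]]$values <- v
      }
    }
  }

  phenotype <- data.frame(
    sample_id = sample_ids,
    class = paste0("C", cls),
    gender = gender,
    age = age,
    survival_T = Tobs,
    survival_E = E
  )
  dataset <- new_omics_dataset(blocks, phenotype)
  truth <- list(
    true_latent = Zt,
    true_class = cls,
    true_age = age,
    true_risk = lp,
    death_time = death,
    censor_time = censor,
    event_time = Tobs,
    event_indicator = E,
    centroids = centroids
  )
  list(dataset = dataset, truth = truth)
}

#' Write a dataset (and optional ground truth) as TSV fixtures
#'
#' One features x samples TSV per omics block (Xena orientation), a
#' phenotype TSV, one annotation TSV per annotated block, a block manifest,
#' and optionally the ground-truth table. Missing values are serialised as
#' "NA". [read_fixture()] restores the dataset; values round-trip to full
#' double precision.
#'
#' @param dataset an `omics_dataset`.
#' @param dir output directory (created if needed).
#' @param truth optional ground-truth list from [synth_generate()].
#' @return invisibly, the manifest data.frame.
#' @export
write_fixture <- function(dataset, dir, truth = NULL) {
  stopifnot(inherits(dataset, "omics_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (b in seq_along(dataset$blocks)) {
    blk <- dataset$blocks[[b]]
    file <- paste0(blk$name, ".tsv")
    mat <- t(blk$values)                       # features x samples on disk
    dt <- data.table::data.table(feature_id = rownames(mat))
    for (j in seq_len(ncol(mat))) dt[[colnames(mat)[j]]] <- mat[, j]
    data.table::fwrite(dt, file.path(dir, file), sep = "\t", na = "NA")
    ann_file <- NA_character_
    if (!is.null(blk$annotation)) {
      ann_file <- paste0(blk$name, "_annotation.tsv")
      data.table::fwrite(blk$annotation, file.path(dir, ann_file), sep = "\t")
    }
    manifest[[b]] <- data.frame(name = blk$name, type = blk$type,
                                file = file, annotation_file = ann_file)
  }
  manifest <- do.call(rbind, manifest)
  data.table::fwrite(manifest, file.path(dir, "blocks.tsv"), sep = "\t",
                     na = "NA")
  data.table::fwrite(dataset$phenotype, file.path(dir, "phenotype.tsv"),
                     sep = "\t", na = "NA")
  if (!is.null(truth)) {
    gt <- data.frame(sample_id = dataset$phenotype$sample_id,
                     true_class = truth$true_class,
                     true_age = truth$true_age,
                     true_risk = truth$true_risk,
                     death_time = truth$death_time,
                     event_time = truth$event_time,
                     event_indicator = truth$event_indicator)
    gt <- cbind(gt, stats::setNames(as.data.frame(truth$true_latent),
                                    paste0("latent_", seq_len(ncol(truth$true_latent)))))
    data.table::fwrite(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
                       na = "NA")
  }
  invisible(manifest)
}

#' Read a fixture directory back into an `omics_dataset`
#'
#' @param dir directory written by [write_fixture()].
#' @return an `omics_dataset`.
#' @export
read_fixture <- function(dir) {
  manifest <- data.table::fread(file.path(dir, "blocks.tsv"),
                                sep = "\t", data.table = FALSE)
  blocks <- lapply(seq_len(nrow(manifest)), function(b) {
    blk <- read_omics_matrix(file.path(dir, manifest$file[b]),
                             omics_type = manifest$type[b],
                             name = manifest$name[b])
    af <- manifest$annotation_file[b]
    if (!is.na(af) && nzchar(af)) {
      blk$annotation <- data.table::fread(file.path(dir, af), sep = "\t",
                                          data.table = FALSE)
    }
    blk
  })
  phenotype <- data.table::fread(file.path(dir, "phenotype.tsv"), sep = "\t",
                                 data.table = FALSE)
  new_omics_dataset(blocks, phenotype)
}
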