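# Reading, filtering, imputing, normalising and splitting multi-omics
# matrices and phenotype tables. On disk matrices are features x samples
# (Xena convention, feature IDs in the first column, sample IDs in the
# header); in memory they are samples x features.

#' Construct an omics block
#'
#' @param values samples x features numeric matrix with sample IDs as
#'   rownames and feature IDs as colnames.
#' @param name block name (used as the fixture file stem).
#' @param type omics-type tag: expression, methylation, mirna or other.
#' @param annotation optional data.frame `feature_id`, `chromosome`.
#' @return object of class `omics_block`.
#' @export
new_omics_block <- function(values, name, type = "other", annotation = NULL) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  if (anyDuplicated(colnames(values))) stop("duplicate feature IDs")
  obj <- list(values = values, name = name, type = type,
              annotation = annotation)
  class(obj) <- "omics_block"
  obj
}

#' @export
print.omics_block <- function(x, ...) {
  cat(sprintf("omics block '%s' (%s): %d samples x %d features\n",
              x$name, x$type, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Construct an aligned multi-omics dataset
#'
#' Verifies that every block carries the same samples in the same order and
#' that the phenotype table matches.
#'
#' @param blocks list of `omics_block`s.
#' @param phenotype data.frame with a `sample_id` column aligned to the
#'   blocks' rows.
#' @return object of class `omics_dataset`.
#' @export
new_omics_dataset <- function(blocks, phenotype) {
  stopifnot(length(blocks) >= 1, "sample_id" %in% names(phenotype))
  ids <- rownames(blocks[[1]]$values)
  for (b in blocks) {
    if (!identical(rownames(b$values), ids)) {
      stop("sample order differs between omics blocks")
    }
  }
  if (!identical(as.character(phenotype$sample_id), ids)) {
    stop("phenotype sample_id does not match block columns")
  }
  obj <- list(blocks = blocks, phenotype = phenotype)
  class(obj) <- "omics_dataset"
  obj
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat("omics dataset:", nrow(x$phenotype), "samples,",
      length(x$blocks), "block(s)\n")
  for (b in x$blocks) print(b)
  invisible(x)
}

#' Read a features x samples omics TSV
#'
#' Expects feature IDs in the first column and sample IDs in the header.
#' The missing markers "NA", "NaN" and the empty string are preserved as
#' missing; any other non-numeric cell is an error, as are duplicate feature
#' IDs and ragged rows.
#'
#' @param path TSV file.
#' @param omics_type type tag for the block.
#' @param name block name; defaults to the file stem.
#' @return an `omics_block` (samples x features in memory).
#' @export
read_omics_matrix <- function(path, omics_type = "other", name = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", "NaN", ""),
                          colClasses = list(character = 1),
                          data.table = FALSE, fill = FALSE)
  if (ncol(dt) < 2) stop("matrix file needs a feature column and >= 1 sample")
  fid <- dt[[1]]
  if (anyDuplicated(fid)) {
    stop("duplicate feature IDs: ", paste(unique(fid[duplicated(fid)]),
                                          collapse = ", "))
  }
  num <- dt[, -1, drop = FALSE]
  for (j in seq_len(ncol(num))) {
    col <- num[[j]]
    if (!is.numeric(col)) {
      bad <- col[!is.na(col) & is.na(suppressWarnings(as.numeric(col)))]
      if (length(bad)) {
        stop("non-numeric cell(s) in column '", names(num)[j], "': ",
             paste(utils::head(unique(bad), 3), collapse = ", "))
      }
      num[[j]] <- as.numeric(col)
    }
  }
  mat <- t(as.matrix(num))               # samples x features
  colnames(mat) <- fid
  rownames(mat) <- names(num)
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(path))
  new_omics_block(mat, name = name, type = omics_type)
}

#' Probe exclusion criteria for methylation arrays
#'
#' Bundles the per-criterion feature-ID lists (each may be empty; lists may
#' overlap, removal is by union) and the missingness threshold. The reference
#' lists come from external annotations and are supplied by the user, not
#' bundled.
#'
#' @param y_chromosome,snp_overlap,non_unique,not_in_epic,snp_assay,non_cpg
#'   character vectors of feature IDs to exclude per criterion.
#' @param max_missing_fraction features missing in more than this fraction of
#'   samples are removed (default 0.1).
#' @return list of class `probe_filter_spec`.
#' @export
probe_filter_spec <- function(y_chromosome = character(),
                              snp_overlap = character(),
                              non_unique = character(),
                              not_in_epic = character(),
                              snp_assay = character(),
                              non_cpg = character(),
                              max_missing_fraction = 0.1) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  spec <- list(criteria = list(
    y_chromosome = y_chromosome, snp_overlap = snp_overlap,
    non_unique = non_unique, not_in_epic = not_in_epic,
    snp_assay = snp_assay, non_cpg = non_cpg
  ), max_missing_fraction = max_missing_fraction)
  class(spec) <- "probe_filter_spec"
  spec
}

#' Filter features by exclusion lists and missingness
#'
#' Removes the union of the criterion lists plus every feature missing in
#' more than `max_missing_fraction` of samples; IDs absent from the block are
#' ignored; retained feature order is preserved. Per-criterion removal counts
#' (counting overlaps once each, in criterion order) are attached as
#' attribute `"removal_counts"`.
#'
#' @param block an `omics_block`.
#' @param spec a [probe_filter_spec()].
#' @return the filtered `omics_block`; error if nothing survives.
#' @export
filter_features <- function(block, spec) {
  stopifnot(inherits(spec, "probe_filter_spec"))
  fid <- colnames(block$values)
  drop <- rep(FALSE, length(fid))
  counts <- integer(0)
  for (nm in names(spec$criteria)) {
    hit <- fid %in% spec$criteria[[nm]] & !drop
    counts[nm] <- sum(hit)
    drop <- drop | (fid %in% spec$criteria[[nm]])
  }
  miss_frac <- colMeans(is.na(block$values))
  hit <- miss_frac > spec$max_missing_fraction & !drop
  counts["missingness"] <- sum(hit)
  drop <- drop | miss_frac > spec$max_missing_fraction
  if (all(drop)) stop("all features removed by the filter")
  counts["total"] <- sum(drop)
  block$values <- block$values[, !drop, drop = FALSE]
  if (!is.null(block$annotation)) {
    block$annotation <- block$annotation[
      block$annotation$feature_id %in% colnames(block$values), , drop = FALSE]
  }
  attr(block, "removal_counts") <- counts
  block
}

#' Drop Y-chromosome genes and all-zero genes from an expression block
#'
#' @param block expression `omics_block`.
#' @param y_gene_ids optional character vector of Y-chromosome gene IDs; when
#'   `NULL` only the zero-expression filter applies.
#' @return filtered block; error if nothing survives.
#' @export
filter_zero_and_y_genes <- function(block, y_gene_ids = NULL) {
  fid <- colnames(block$values)
  all_zero <- apply(block$values, 2, function(v) all(!is.na(v) & v == 0))
  drop <- all_zero
  if (!is.null(y_gene_ids)) drop <- drop | fid %in% y_gene_ids
  if (all(drop)) stop("all genes removed")
  block$values <- block$values[, !drop, drop = FALSE]
  attr(block, "removal_counts") <- c(
    y_chromosome = if (is.null(y_gene_ids)) 0L else
      sum(fid %in% y_gene_ids),
    all_zero = sum(all_zero))
  block
}

#' Impute missing entries by the feature mean
#'
#' @param block an `omics_block`.
#' @return block with every missing entry replaced by the mean of that
#'   feature's observed values; error if a feature is entirely missing.
#' @export
impute_mean <- function(block) {
  v <- block$values
  nmiss <- colSums(is.na(v))
  if (any(nmiss == nrow(v))) {
    stop("feature(s) entirely missing: ",
         paste(utils::head(colnames(v)[nmiss == nrow(v)], 3), collapse = ", "))
  }
  if (any(nmiss > 0)) {
    mu <- colMeans(v, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- mu[idx[, 2]]
    block$values <- v
  }
  block
}

#' Min-max normalise a block to \[0,1\]
#'
#' Per-feature (x - min) / (max - min), with min/max computed on
#' `fit_samples` only (training split); the transform is applied to every
#' sample with clamping to \[0,1\], so held-out values outside the training
#' range do not leak. Constant features map to 0.
#'
#' @param block an `omics_block` (no missing values).
#' @param fit_samples row indices (or rownames) used to fit the ranges;
#'   default all samples (global normalisation).
#' @return list: `block` (normalised) and `ranges` (feature, min, max).
#' @export
minmax_normalise <- function(block, fit_samples = NULL) {
  v <- block$values
  if (is.null(fit_samples)) fit_samples <- seq_len(nrow(v))
  stopifnot(length(fit_samples) >= 1)
  fit <- v[fit_samples, , drop = FALSE]
  mn <- apply(fit, 2, min)
  mx <- apply(fit, 2, max)
  rng <- mx - mn
  scaled <- sweep(v, 2, mn, "-")
  scaled <- sweep(scaled, 2, ifelse(rng > 0, rng, 1), "/")
  scaled[, rng == 0] <- 0
  scaled <- pmin(pmax(scaled, 0), 1)
  block$values <- scaled
  list(block = block,
       ranges = data.frame(feature = colnames(v), min = mn, max = mx))
}

# Largest-remainder allocation of n items to fractions; deviates from exact
# proportionality by less than one item per cell.
allocate_counts <- function(n, fractions) {
  quota <- n * fractions
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    order_rem <- order(quota - base, decreasing = TRUE)
    base[order_rem[seq_len(left)]] <- base[order_rem[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Splits sample indices so that each class's share of every split deviates
#' from exact proportionality by less than one sample (largest-remainder
#' allocation within class). Classes with fewer than 3 members cannot be
#' stratified over three splits and are routed entirely to training.
#'
#' @param phenotype phenotype data.frame.
#' @param label name of the class column to stratify on.
#' @param fractions length-3 fractions (train, val, test) summing to 1.
#' @param seed RNG seed; identical seeds give identical partitions.
#' @return list of integer index vectors `train`, `val`, `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(phenotype, label, fractions = c(0.6, 0.2, 0.2),
                             seed = 1) {
  if (!label %in% names(phenotype)) stop("unknown label: ", label)
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  cls <- as.character(phenotype[[label]])
  set.seed(seed)
  out <- list(train = integer(), val = integer(), test = integer())
  for (cl in sort(unique(cls))) {
    idx <- which(cls == cl)
    if (length(idx) < 3) {
      out$train <- c(out$train, idx)
      next
    }
    idx <- idx[sample.int(length(idx))]
    counts <- allocate_counts(length(idx), fractions)
    ends <- cumsum(counts)
    out$train <- c(out$train, idx[seq_len(counts[1])])
    if (counts[2] > 0) out$val <- c(out$val, idx[(ends[1] + 1):ends[2]])
    if (counts[3] > 0) out$test <- c(out$test, idx[(ends[2] + 1):ends[3]])
  }
  lapply(out, sort)
}

#' Stratified k-fold partition
#'
#' Class members are shuffled and dealt round-robin over folds, so per-class
#' fold counts differ by at most one; folds are disjoint and exhaustive.
#'
#' @param phenotype phenotype data.frame.
#' @param label class column to stratify on.
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @return list of k elements, each `list(train = ..., test = ...)`.
#' @export
stratified_kfold <- function(phenotype, label, k = 5, seed = 1) {
  if (!label %in% names(phenotype)) stop("unknown label: ", label)
  n <- nrow(phenotype)
  stopifnot(k >= 2)
  if (k > n) stop("k exceeds the number of samples")
  cls <- as.character(phenotype[[label]])
  set.seed(seed)
  fold_of <- integer(n)
  for (cl in sort(unique(cls))) {
    idx <- which(cls == cl)
    idx <- idx[sample.int(length(idx))]
    fold_of[idx] <- ((seq_along(idx) - 1L) %% k) + 1L
  }
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}

#' Impute then normalise a block for model input
#'
#' Convenience wrapper: [impute_mean()] followed by [minmax_normalise()] fit
#' on the training samples (or globally when `fit_samples` is `NULL`).
#'
#' @param block an `omics_block`.
#' @param fit_samples training row indices for the min-max fit; `NULL` fits
#'   on all samples.
#' @return normalised `omics_block`.
#' @export
prepare_block <- function(block, fit_samples = NULL) {
  minmax_normalise(impute_mean(block), fit_samples)$block
}
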