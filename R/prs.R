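#' Score individuals from a variant-weight table
#'
#' Computes the weighted allele-dosage sum
#' `score_i = sum over variants with gwas_p <= p_threshold of
#' weight * dosage`, after harmonizing alleles: when a weight row's effect
#' allele equals the genotype's other allele the dosage is flipped
#' (`2 - dosage`); when it matches neither allele the variant is dropped with
#' a warning. Missing dosages are imputed by the variant's mean dosage.
#'
#' @param genotypes A `genotype_matrix`.
#' @param weights Variant-weight data.frame (`variant_id`, `effect_allele`,
#'   `weight`, `gwas_p`).
#' @param p_threshold Include only variants with source-GWAS p-value at or
#'   below this cutoff.
#' @return Named numeric vector of raw scores (one per individual).
#' @export
score_individuals <- function(genotypes, weights, p_threshold = 1) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  w <- weights[weights$gwas_p <= p_threshold, , drop = FALSE]
  if (nrow(w) == 0L) stop("no variants pass the p-value threshold")
  pos <- match(w$variant_id, genotypes$variant_ids)
  if (anyNA(pos)) {
    w <- w[!is.na(pos), , drop = FALSE]
    pos <- pos[!is.na(pos)]
  }
  if (nrow(w) == 0L) stop("no weight variants found in the genotype matrix")
  eff <- genotypes$effect_alleles[pos]
  oth <- genotypes$other_alleles[pos]
  same <- w$effect_allele == eff
  flip <- !same & w$effect_allele == oth
  drop <- !same & !flip
  if (any(drop)) {
    warning(sum(drop), " variant(s) dropped: effect allele matches neither ",
            "genotype allele")
    w <- w[!drop, , drop = FALSE]
    pos <- pos[!drop]; same <- same[!drop]; flip <- flip[!drop]
  }
  dos <- genotypes$dosages[, pos, drop = FALSE]
  if (anyNA(dos)) {
    mu <- colMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- mu[idx[, 2]]
  }
  if (any(flip)) dos[, flip] <- 2 - dos[, flip]
  drop(dos %*% w$weight)
}

#' Standardize a raw polygenic score to mean 0, SD 1
#'
#' Uses the sample standard deviation (n - 1 denominator). Apply within each
#' study.
#' @param raw Numeric vector with at least two distinct values.
#' @return z-scores.
#' @export
standardize_prs <- function(raw) {
  s <- stats::sd(raw, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("degenerate input: constant scores")
  (raw - mean(raw, na.rm = TRUE)) / s
}

#' Assign score tertiles
#'
#' Cuts at the empirical 33.3/66.7 percentiles; values exactly at a boundary
#' are assigned to the lower tertile (deterministic, order-independent).
#' @param z Numeric scores, `n >= 3`.
#' @return Integer tertile labels in \{1, 2, 3\} (`NA` preserved).
#' @export
assign_tertiles <- function(z) {
  if (sum(!is.na(z)) < 3L) stop("need at least 3 scores to form tertiles")
  q <- stats::quantile(z, c(1 / 3, 2 / 3), na.rm = TRUE, names = FALSE)
  1L + (z > q[1]) + (z > q[2])
}

#' Stratified 70/30 train/validation split
#'
#' Within each study, `floor(fraction * n)` individuals are sampled into the
#' training set; the remainder validate. Deterministic for a fixed seed.
#' @param study Character/factor vector of study labels, one per individual.
#' @param fraction Training fraction (default 0.70).
#' @param seed Optional integer seed.
#' @return Logical vector, `TRUE` for training rows.
#' @export
split_train_valid <- function(study, fraction = 0.70, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  train <- logical(length(study))
  for (s in unique(study)) {
    idx <- which(study == s)
    if (length(idx) < 2L) stop("study ", s, " has < 2 individuals")
    n_tr <- floor(fraction * length(idx))
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

#' Mann-Whitney AUC of a score against binary labels
#'
#' Rank-based probability that a randomly chosen case outscores a randomly
#' chosen control, ties counted one half.
#' @param scores Numeric vector.
#' @param labels 0/1 vector (1 = case).
#' @return AUC in [0, 1].
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as.integer(labels > 0)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: one class is empty")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Default p-value grid for threshold selection
#'
#' 17 cutoffs log-spaced from 5e-8 to 1.
#' @export
default_p_grid <- function() {
  exp(seq(log(5e-8), log(1), length.out = 17))
}

#' Select a p-value threshold by grid search on a stratified split
#'
#' For each cutoff in the grid, variants with source-GWAS p-value at or below
#' the cutoff are scored and the validation-set AUC against the binary labels
#' is computed; the cutoff maximizing validation AUC is chosen (ties go to
#' the most stringent cutoff). The split is 70/30 stratified by study.
#'
#' @param genotypes A `genotype_matrix`.
#' @param weights Variant-weight table.
#' @param labels Binary outcome per individual.
#' @param study Study label per individual (for stratified splitting).
#' @param threshold_grid P-value cutoffs (default [default_p_grid()]).
#' @param seed Optional integer seed for the split.
#' @return A list of class `grid_search_result`: `grid` (data.frame with
#'   `threshold`, `n_variants`, `auc`), `chosen_threshold`,
#'   `chosen_n_variants`, `chosen_auc`, `train` (the split indicator).
#' @export
grid_search_prs <- function(genotypes, weights, labels, study,
                            threshold_grid = default_p_grid(), seed = NULL) {
  labels <- as.integer(labels > 0)
  train <- split_train_valid(study, 0.70, seed)
  valid <- !train
  if (length(unique(labels[valid])) < 2L) {
    stop("validation set contains a single outcome class; AUC undefined")
  }
  grid <- data.frame(threshold = threshold_grid,
                     n_variants = NA_integer_, auc = NA_real_)
  for (j in seq_along(threshold_grid)) {
    keep <- weights$gwas_p <= threshold_grid[j]
    grid$n_variants[j] <- sum(keep)
    if (!any(keep)) next
    sc <- score_individuals(genotypes, weights, threshold_grid[j])
    grid$auc[j] <- auc_mann_whitney(sc[valid], labels[valid])
  }
  ok <- which(!is.na(grid$auc))
  best <- ok[which.max(grid$auc[ok])]
  structure(
    list(grid = grid, chosen_threshold = grid$threshold[best],
         chosen_n_variants = grid$n_variants[best],
         chosen_auc = grid$auc[best], train = train),
    class = "grid_search_result"
  )
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result> chosen p <= %.3g (%d variants), AUC %.3f\n",
              x$chosen_threshold, x$chosen_n_variants, x$chosen_auc))
  invisible(x)
}

#' Principal components of a genotype matrix
#'
#' Columns are centered by twice the allele frequency and scaled by the
#' binomial standard deviation `sqrt(2 p (1 - p))`; zero-variance variants
#' are dropped; the top `k` left singular vectors (scaled by their singular
#' values) are returned as PC coordinates.
#'
#' @param genotypes A `genotype_matrix`.
#' @param k Number of components (default 5).
#' @return List of class `pc_result`: `scores` (n x k matrix), `explained`
#'   (fraction of total variance per component).
#' @export
genotype_pca <- function(genotypes, k = 5L) {
  dos <- genotypes$dosages
  p <- colMeans(dos) / 2
  keep <- p > 0 & p < 1
  dos <- dos[, keep, drop = FALSE]
  p <- p[keep]
  if (k >= min(dim(dos))) stop("k must be < min(n individuals, n variants)")
  X <- sweep(dos, 2, 2 * p)
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(X, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- genotypes$individual_ids
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(
    list(scores = scores, explained = sv$d[seq_len(k)]^2 / sum(sv$d^2)),
    class = "pc_result"
  )
}

#' Full per-individual PRS result
#'
#' Convenience wrapper combining scoring, per-study standardization and
#' tertile assignment.
#' @inheritParams score_individuals
#' @param study Study label per individual.
#' @return data.frame with `individual_id`, `study`, `raw_score`, `z_score`,
#'   `tertile`.
#' @export
prs_result <- function(genotypes, weights, study, p_threshold = 1) {
  raw <- score_individuals(genotypes, weights, p_threshold)
  z <- numeric(length(raw))
  tert <- integer(length(raw))
  for (s in unique(study)) {
    i <- study == s
    z[i] <- standardize_prs(raw[i])
    tert[i] <- assign_tertiles(z[i])
  }
  data.frame(individual_id = genotypes$individual_ids, study = study,
             raw_score = unname(raw), z_score = z, tertile = tert,
             stringsAsFactors = FALSE)
}
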