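# Median-of-ratios normalization, regularized log10 transform, z-scored
# per-population profiles, and the sample correlation matrix.

#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over genes g of
#' `counts[g, j] / geomean_k(counts[g, k])`, computed only over genes with
#' strictly positive counts in every sample (the pseudo-reference is the
#' per-gene geometric mean across samples).
#'
#' @param counts integer gene x sample matrix.
#' @return Named positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  if (ncol(counts) < 1L) stopf("counts has no samples")
  eligible <- rowSums(counts > 0) == ncol(counts)
  if (!any(eligible)) {
    stopf(paste("no gene has strictly positive counts in all samples;",
                "consider adding a pseudocount upstream"))
  }
  lc <- log(counts[eligible, , drop = FALSE])
  ref <- rowMeans(lc)                    # log geometric mean per gene
  s <- apply(exp(lc - ref), 2L, stats::median)
  stats::setNames(s, colnames(counts))
}

#' Regularized log10 expression
#'
#' `x[g, j] = log10(counts[g, j] / s[j] + pseudocount)`. The +1
#' pseudocount keeps zeros at zero and is configurable.
#'
#' @param counts gene x sample count matrix.
#' @param factors size factors, one per sample (recycled by name when
#'   named).
#' @param pseudocount added inside the log; default 1.
#' @return Numeric matrix, same shape as `counts`.
#' @export
regularized_log <- function(counts, factors, pseudocount = 1) {
  if (length(factors) != ncol(counts)) {
    stopf("need one size factor per sample (%d vs %d)",
          length(factors), ncol(counts))
  }
  if (!is.null(names(factors)) && !is.null(colnames(counts))) {
    factors <- factors[colnames(counts)]
  }
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    stopf("size factors must be positive and finite")
  }
  log10(sweep(counts, 2L, factors, "/") + pseudocount)
}

#' Per-gene z-scored profiles across stromal types
#'
#' Within one condition, averages the (regularized) expression of each
#' gene over the replicates of every stromal type, then z-scores the
#' resulting per-type means across types using the n-1 standard
#' deviation. Genes whose per-type means are constant (sd below
#' `flat_sd`) are flagged flat and carry NA profiles; they are excluded
#' from clustering.
#'
#' @param expr numeric gene x sample matrix (typically
#'   [regularized_log()] output).
#' @param meta sample metadata with sample_id, stromal_type, condition.
#' @param condition which condition's samples to profile (default "ctrl",
#'   the homeostatic reference).
#' @param flat_sd standard-deviation threshold below which a gene is
#'   considered flat.
#' @return List with `z` (gene x type matrix), `means` (per-type means)
#'   and `flat` (logical vector).
#' @export
z_profiles <- function(expr, meta, condition = "ctrl", flat_sd = 1e-12) {
  sel <- meta$condition == condition
  if (!any(sel)) stopf("no samples with condition '%s'", condition)
  meta <- meta[sel, , drop = FALSE]
  missing_cols <- setdiff(meta$sample_id, colnames(expr))
  if (length(missing_cols)) stopf("expression lacks sample(s): %s",
                                  paste(missing_cols, collapse = ", "))
  types <- unique(meta$stromal_type)
  if (length(types) < 2L) stopf("need >=2 stromal types in condition '%s'",
                                condition)
  counts_per_type <- table(meta$stromal_type)
  if (any(counts_per_type == 0)) stopf("stromal type with zero samples")
  means <- sapply(types, function(ty) {
    cols <- meta$sample_id[meta$stromal_type == ty]
    rowMeans(expr[, cols, drop = FALSE])
  })
  colnames(means) <- types
  sds <- apply(means, 1L, stats::sd)
  mu <- rowMeans(means)
  flat <- sds < flat_sd
  z <- (means - mu) / sds
  z[flat, ] <- NA_real_
  list(z = z, means = means, flat = flat)
}

#' Pearson correlation between samples
#'
#' Correlation matrix of the columns of a (regularized-log) expression
#' matrix, as used to compare stromal populations. Zero-variance samples
#' yield NA entries and a warning; the diagonal is always 1.
#'
#' @param expr numeric gene x sample matrix.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(expr) {
  if (ncol(expr) < 2L) stopf("need >=2 samples")
  sds <- apply(expr, 2L, stats::sd)
  if (any(sds == 0)) {
    warnf("zero-variance sample(s): %s; correlations set to NA",
          paste(colnames(expr)[sds == 0], collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(expr))
  diag(r) <- 1
  r
}
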