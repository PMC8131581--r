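# Two-group negative-binomial Wald differential expression, BH
# adjustment, gene selection for clustering, and set-overlap statistics.
#
# This is a deliberately compact reimplementation: per-gene
# method-of-moments dispersion with a floor and empirical-Bayes
# shrinkage toward the ensemble mean (no trend fitting, no Cook's or
# independent filtering), then a two-group NB GLM with log link and
# log(size-factor) offsets fitted by IRLS. Type-I error is checked by
# calibration tests rather than inherited from a reference package.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sorted ascending p(i) maps to
#' `min_{j >= i} m * p(j) / j`, capped at 1. NA p-values are ignored for
#' m and propagated as NA.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stopf("p-values must lie in [0, 1]")
  m <- length(pv)
  o <- order(pv, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * pv[o]))
  out[ok[o]] <- adj
  out
}

# Method-of-moments NB dispersion from size-factor-normalized counts,
# pooling within-group variances: max(floor, (v - mu) / mu^2) per gene,
# then empirical-Bayes shrinkage on the log scale toward the ensemble
# mean with weight d / (d + prior_df). The raw per-gene estimator is far
# too noisy at typical replicate counts (its left tail produces wildly
# anticonservative Wald statistics); prior_df = Inf collapses to a
# single common dispersion, the correct model when all genes share one
# dispersion.
mom_dispersion <- function(norm_a, norm_b, floor = 1e-8, prior_df = 10) {
  va <- apply(norm_a, 1L, stats::var)
  vb <- apply(norm_b, 1L, stats::var)
  na <- ncol(norm_a); nb <- ncol(norm_b)
  v <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  mu <- (rowSums(norm_a) + rowSums(norm_b)) / (na + nb)
  alpha <- (v - mu) / mu^2
  alpha[!is.finite(alpha)] <- floor
  alpha <- pmax(alpha, floor)
  if (length(alpha) > 1L && prior_df > 0) {
    d <- na + nb - 2
    z0 <- log(mean(alpha))
    if (is.infinite(prior_df)) {
      alpha <- rep(exp(z0), length(alpha))
    } else {
      w <- d / (d + prior_df)
      alpha <- exp(w * log(alpha) + (1 - w) * z0)
    }
  }
  pmax(alpha, floor)
}

# IRLS fit of a single-gene two-group NB GLM with log link and offsets.
# x is the 0/1 indicator of group A; beta[2] is log(mean_A / mean_B).
nb_irls <- function(y, offset, x, alpha, max_iter = 50L, tol = 1e-8) {
  X <- cbind(1, x)
  mb <- mean(pmax(y[x == 0] / exp(offset[x == 0]), 0)) + 0.5
  ma <- mean(pmax(y[x == 1] / exp(offset[x == 1]), 0)) + 0.5
  b <- c(log(mb), log(ma) - log(mb))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b) + offset
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * w)
    A <- XtW %*% X
    if (!all(is.finite(A)) || abs(det(A)) < 1e-300) break
    bnew <- drop(solve(A, XtW %*% z))
    if (!all(is.finite(bnew))) break
    delta <- max(abs(bnew - b))
    b <- bnew
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% b) + offset
  mu <- pmin(exp(eta), 1e12)
  w <- mu / (1 + alpha * mu)
  info <- t(X * w) %*% X
  se <- tryCatch(sqrt(solve(info)[2, 2]), error = function(e) NA_real_)
  list(beta = b[2], se = se, converged = converged)
}

#' Negative-binomial Wald test between two groups
#'
#' Per gene: method-of-moments dispersion (with floor) from
#' size-factor-normalized counts pooled within groups, then a two-group
#' NB regression with log link and log size-factor offsets fitted by
#' IRLS. The Wald statistic is beta / SE(beta) with a two-sided normal
#' p-value; the effect is reported as log2FC = beta / ln 2 for group A
#' over group B. Genes with an all-zero group are fitted with a +0.5
#' pseudocount and flagged; non-converged fits are flagged with p = NA.
#'
#' @param counts integer gene x sample matrix.
#' @param meta sample metadata (sample_id plus the grouping column).
#' @param contrast length-2 character vector `c(A, B)`; positive log2FC
#'   means higher in A.
#' @param group_col metadata column holding the group labels
#'   (default "condition"; use "stromal_type" for population contrasts).
#' @param factors size factors; computed by [size_factors()] on the
#'   selected samples when NULL.
#' @param q FDR threshold for the up/down/ns call (default 0.1).
#' @param alpha_floor dispersion floor.
#' @param prior_df strength (in degrees of freedom) of the
#'   empirical-Bayes shrinkage of log-dispersions toward the ensemble
#'   mean; `Inf` fits one common dispersion, 0 disables shrinkage.
#' @param max_iter,tol IRLS controls.
#' @return data.frame with feature, group_a, group_b, log2FC, SE,
#'   wald_stat, p, padj, call, flag.
#' @export
nb_wald_test <- function(counts, meta, contrast, group_col = "condition",
                         factors = NULL, q = 0.1, alpha_floor = 1e-8,
                         prior_df = 10, max_iter = 50L, tol = 1e-8) {
  if (length(contrast) != 2L) stopf("contrast must be c(A, B)")
  grp <- meta[[group_col]]
  sel_a <- meta$sample_id[grp == contrast[1]]
  sel_b <- meta$sample_id[grp == contrast[2]]
  if (length(sel_a) < 2L || length(sel_b) < 2L) {
    stopf("need >=2 replicates per group (got %d vs %d for %s vs %s)",
          length(sel_a), length(sel_b), contrast[1], contrast[2])
  }
  cols <- c(sel_a, sel_b)
  cts <- counts[, cols, drop = FALSE]
  if (is.null(factors)) factors <- size_factors(cts)
  factors <- factors[cols]
  x <- as.numeric(cols %in% sel_a)
  offset <- log(factors)
  norm <- sweep(cts, 2L, factors, "/")
  alpha <- mom_dispersion(norm[, x == 1, drop = FALSE],
                          norm[, x == 0, drop = FALSE], floor = alpha_floor,
                          prior_df = prior_df)

  n_genes <- nrow(cts)
  beta <- se <- rep(NA_real_, n_genes)
  flag <- character(n_genes)
  for (g in seq_len(n_genes)) {
    y <- cts[g, ]
    zero_a <- all(y[x == 1] == 0)
    zero_b <- all(y[x == 0] == 0)
    if (zero_a && zero_b) {
      beta[g] <- 0; se[g] <- NA_real_
      flag[g] <- "all_zero"
      next
    }
    yy <- y
    if (zero_a || zero_b) {
      yy <- y + 0.5            # shrinkage pseudo-mean for the empty group
      flag[g] <- "zero_group"
    }
    fit <- nb_irls(yy, offset, x, alpha[g], max_iter = max_iter, tol = tol)
    beta[g] <- fit$beta
    se[g] <- fit$se
    if (!fit$converged) flag[g] <- paste0(flag[g], "+nonconv")
  }
  wald <- beta / se
  p <- 2 * stats::pnorm(-abs(wald))
  p[flag == "all_zero"] <- 1
  p[grepl("nonconv", flag)] <- NA_real_
  padj <- bh_adjust(p)
  log2fc <- beta / log(2)
  call <- rep("ns", n_genes)
  call[!is.na(padj) & padj < q & log2fc > 0] <- "up"
  call[!is.na(padj) & padj < q & log2fc < 0] <- "down"
  data.frame(feature = rownames(cts), group_a = contrast[1],
             group_b = contrast[2], log2FC = log2fc, SE = se,
             wald_stat = wald, p = p, padj = padj, call = call,
             flag = flag, stringsAsFactors = FALSE)
}

#' AML-versus-control tests within every stromal type
#'
#' Runs [nb_wald_test()] on the samples of each stromal type separately,
#' contrasting two conditions.
#'
#' @param counts gene x sample count matrix.
#' @param meta sample metadata.
#' @param contrast conditions `c(A, B)` (default AML vs ctrl).
#' @param factors optional size factors computed on all samples jointly;
#'   when NULL, factors are computed per stromal type.
#' @param q FDR threshold for calls (default 0.1 per the condition rule).
#' @param prior_df dispersion-shrinkage strength (see [nb_wald_test()]).
#' @return Named list of DE tables, one per stromal type.
#' @export
de_condition_per_type <- function(counts, meta, contrast = c("AML", "ctrl"),
                                  factors = NULL, q = 0.1, prior_df = 10) {
  types <- unique(meta$stromal_type)
  out <- lapply(types, function(ty) {
    m <- meta[meta$stromal_type == ty, , drop = FALSE]
    f <- if (is.null(factors)) NULL else factors[m$sample_id]
    nb_wald_test(counts[, m$sample_id, drop = FALSE], m, contrast,
                 group_col = "condition", factors = f, q = q,
                 prior_df = prior_df)
  })
  names(out) <- types
  out
}

#' All pairwise stromal contrasts within one condition
#'
#' @param counts gene x sample count matrix.
#' @param meta sample metadata.
#' @param condition condition to test within (default "ctrl").
#' @param factors optional precomputed size factors.
#' @param q FDR threshold for calls (default 0.05, the pairwise
#'   selection rule).
#' @param prior_df dispersion-shrinkage strength (see [nb_wald_test()]).
#' @return Named list of DE tables, names "A_vs_B" over all C(S,2) pairs.
#' @export
de_pairwise_types <- function(counts, meta, condition = "ctrl",
                              factors = NULL, q = 0.05, prior_df = 10) {
  m <- meta[meta$condition == condition, , drop = FALSE]
  types <- unique(m$stromal_type)
  if (length(types) < 2L) stopf("need >=2 stromal types in '%s'", condition)
  pairs <- utils::combn(types, 2L, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    mm <- m[m$stromal_type %in% pr, , drop = FALSE]
    f <- if (is.null(factors)) NULL else factors[mm$sample_id]
    nb_wald_test(counts[, mm$sample_id, drop = FALSE], mm, pr,
                 group_col = "stromal_type", factors = f, q = q,
                 prior_df = prior_df)
  })
  names(out) <- vapply(pairs, function(pr) paste(pr, collapse = "_vs_"), "")
  out
}

#' Select genes for clustering from pairwise stromal contrasts
#'
#' Union of genes with at least one adjusted p below `threshold` across
#' all C(S,2) pairwise stromal comparisons.
#'
#' @param pairwise named list of DE tables from [de_pairwise_types()].
#' @param threshold adjusted-p cutoff (default 0.05).
#' @param types optional stromal-type vector; when given, the presence of
#'   every pairwise contrast is checked and missing pairs are an error.
#' @return Character vector of selected gene ids.
#' @export
select_cluster_genes <- function(pairwise, threshold = 0.05, types = NULL) {
  if (!is.null(types)) {
    want <- utils::combn(types, 2L, simplify = FALSE)
    have <- names(pairwise)
    ok <- vapply(want, function(pr) {
      paste(pr, collapse = "_vs_") %in% have ||
        paste(rev(pr), collapse = "_vs_") %in% have
    }, TRUE)
    if (!all(ok)) {
      miss <- vapply(want[!ok], function(pr) paste(pr, collapse = " vs "), "")
      stopf("missing pairwise contrast(s): %s", paste(miss, collapse = "; "))
    }
  }
  hits <- lapply(pairwise, function(de) {
    de$feature[!is.na(de$padj) & de$padj < threshold]
  })
  sort(unique(unlist(hits)))
}

#' Overlap of late-stage deregulated genes with early-stage sets
#'
#' Proportion of a late-deregulation gene set recovered in each early
#' set: `|late . early| / |late|`.
#'
#' @param set_late character vector of late-deregulated symbols
#'   (non-empty).
#' @param early_sets named list of early-deregulation symbol sets.
#' @return Named numeric vector of proportions.
#' @export
deregulation_overlap <- function(set_late, early_sets) {
  set_late <- unique(norm_symbol(set_late))
  if (!length(set_late)) stopf("late set is empty; overlap undefined")
  vapply(early_sets, function(e) {
    length(intersect(set_late, unique(norm_symbol(e)))) / length(set_late)
  }, numeric(1))
}
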