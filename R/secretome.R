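# Secretome processing: quantile normalization, log2 transform and
# empirical-Bayes moderated t-statistics (Smyth-style variance
# moderation, reimplemented with closed-form moment matching on
# log-variances and a Newton inverse-trigamma solve).

#' Quantile normalization
#'
#' Replaces each sample's sorted values by the across-sample mean of
#' order statistics; tied values receive the mean of the reference
#' distribution over their rank span, so all columns share an identical
#' value multiset afterwards. A single-column matrix is returned
#' unchanged.
#'
#' @param X numeric feature x sample matrix without missing values.
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(X) {
  if (anyNA(X)) {
    stopf("missing intensities; impute or filter before quantile normalization")
  }
  if (ncol(X) == 1L) return(X)
  sorted <- apply(X, 2L, sort)
  ref <- rowMeans(sorted)
  cum <- c(0, cumsum(ref))
  out <- X
  for (j in seq_len(ncol(X))) {
    rmin <- rank(X[, j], ties.method = "min")
    rmax <- rank(X[, j], ties.method = "max")
    out[, j] <- (cum[rmax + 1L] - cum[rmin]) / (rmax - rmin + 1L)
  }
  out
}

# Newton solve of trigamma(x) = y (limma-style starting value).
trigamma_inverse <- function(y, tol = 1e-8, max_iter = 50L) {
  if (y <= 0) stopf("trigamma_inverse needs y > 0")
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (it in seq_len(max_iter)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif) / x < tol) break
  }
  x
}

# Moment-matching estimate of the variance prior (d0, s0^2) from
# gene-wise variances s2 on d df: solve trigamma(d0/2) = var of
# log-variance residuals, then back out s0^2.
fit_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) return(list(d0 = Inf, s0_sq = mean(s2, na.rm = TRUE)))
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  if (sum(ok) < 2L) return(list(d0 = Inf, s0_sq = exp(emean)))
  evar <- sum((e - emean)^2) / (sum(ok) - 1)
  rhs <- evar - trigamma(d / 2)
  if (rhs <= 0) {
    list(d0 = Inf, s0_sq = exp(emean))
  } else {
    d0 <- 2 * trigamma_inverse(rhs)
    list(d0 = d0, s0_sq = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  }
}

#' Empirical-Bayes moderated t-test between two groups
#'
#' Per feature: the ordinary two-group difference beta and residual
#' variance s^2 on d df; the prior (d0, s0^2) is estimated from the
#' ensemble of log-variances by moment matching (digamma/trigamma
#' equations, Newton inverse-trigamma); the posterior variance
#' `(d0 s0^2 + d s^2) / (d0 + d)` yields a moderated t on d0 + d df,
#' followed by BH adjustment. `d0_override = 0` recovers the ordinary
#' two-sample (pooled-variance) t-test; `d0 = Inf` (estimated when the
#' variance ensemble is underdispersed, or forced) fully pools variances.
#'
#' @param X numeric feature x sample matrix on the log2 scale.
#' @param meta sample metadata with sample_id and the grouping column.
#' @param contrast groups `c(A, B)`; positive log2FC means higher in A.
#' @param group_col metadata grouping column (default "condition").
#' @param q FDR threshold for calls (default 0.1).
#' @param d0_override fix the prior df instead of estimating them.
#' @return data.frame with feature, group_a, group_b, log2FC, SE,
#'   t_stat (moderated), df, p, padj, call, plus the prior as
#'   attributes `d0` and `s0_sq`.
#' @export
moderated_t <- function(X, meta, contrast, group_col = "condition",
                        q = 0.1, d0_override = NULL) {
  grp <- meta[[group_col]]
  a <- meta$sample_id[grp == contrast[1]]
  b <- meta$sample_id[grp == contrast[2]]
  if (length(a) < 2L || length(b) < 2L) stopf("need >=2 samples per group")
  Xa <- X[, a, drop = FALSE]; Xb <- X[, b, drop = FALSE]
  na <- length(a); nb <- length(b)
  beta <- rowMeans(Xa) - rowMeans(Xb)
  ssa <- rowSums((Xa - rowMeans(Xa))^2)
  ssb <- rowSums((Xb - rowMeans(Xb))^2)
  d <- na + nb - 2
  s2 <- (ssa + ssb) / d
  v <- 1 / na + 1 / nb

  if (!is.null(d0_override)) {
    d0 <- d0_override
    s0_sq <- if (is.finite(d0) && d0 > 0) fit_variance_prior(s2, d)$s0_sq
             else mean(s2)
    if (is.infinite(d0)) s0_sq <- fit_variance_prior(s2, d)$s0_sq
  } else if (all(s2 == 0)) {
    d0 <- Inf
    s0_sq <- mean(s2) + 1e-12
  } else {
    pr <- fit_variance_prior(s2, d)
    d0 <- pr$d0; s0_sq <- pr$s0_sq
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
             else if (d0 == 0) s2
             else (d0 * s0_sq + d * s2) / (d0 + d)
  tstat <- beta / sqrt(s2_post * v)
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  padj <- bh_adjust(p)
  call <- rep("ns", length(p))
  call[!is.na(padj) & padj < q & beta > 0] <- "up"
  call[!is.na(padj) & padj < q & beta < 0] <- "down"
  out <- data.frame(feature = rownames(X), group_a = contrast[1],
                    group_b = contrast[2], log2FC = beta,
                    SE = sqrt(s2_post * v), t_stat = tstat, df = df_total,
                    p = p, padj = padj, call = call,
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

#' Proportion of one symbol set recovered in another
#'
#' `|A . B| / |A|` after symbol normalization; errors on an empty A.
#'
#' @param setA,setB character vectors of symbols.
#' @return Single numeric proportion.
#' @export
dataset_overlap <- function(setA, setB) {
  a <- unique(norm_symbol(setA))
  if (!length(a)) stopf("reference set A is empty; overlap undefined")
  length(intersect(a, unique(norm_symbol(setB)))) / length(a)
}
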