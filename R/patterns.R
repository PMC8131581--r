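# Ternary deregulation patterns across stromal types and the EM-fitted
# finite mixture grouping genes by shared pattern.
#
# The generative model: each gene carries a latent component m with
# ternary prototype pi_m over stromal types; the observed entry equals
# the prototype with probability 1 - eps and flips to either other
# symbol with probability eps/2 each (symmetric flip noise). Mixture
# weights get Dirichlet(alpha) smoothing. Inference is EM with seeded
# random restarts, which is deterministic and fast; components falling
# below weight 1/(10 * M_max) are pruned after convergence.

#' Ternary deregulation calls per gene and stromal type
#'
#' +1 when padj < q with positive log2FC, -1 when negative, else 0 —
#' the FDR < 0.1 deregulation rule applied per stromal type.
#'
#' @param de_by_type named list of condition DE tables (one per stromal
#'   type).
#' @param q FDR threshold (default 0.1).
#' @return Integer matrix genes x stromal types with entries in
#'   \{-1, 0, 1\}.
#' @export
ternarize <- function(de_by_type, q = 0.1) {
  types <- names(de_by_type)
  if (is.null(types)) stopf("de_by_type must be a named list")
  genes <- sort(unique(unlist(lapply(de_by_type, `[[`, "feature"))))
  Y <- matrix(0L, length(genes), length(types),
              dimnames = list(genes, types))
  missing_any <- FALSE
  for (ty in types) {
    de <- de_by_type[[ty]]
    idx <- match(genes, de$feature)
    if (anyNA(idx)) missing_any <- TRUE
    ok <- !is.na(idx)
    sig <- !is.na(de$padj[idx[ok]]) & de$padj[idx[ok]] < q
    v <- integer(sum(ok))
    v[sig & de$log2FC[idx[ok]] > 0] <- 1L
    v[sig & de$log2FC[idx[ok]] < 0] <- -1L
    Y[ok, ty] <- v
  }
  if (missing_any) warnf("genes missing from some DE tables were set to 0")
  Y
}

# Weighted per-column mode over the ternary alphabet; ties prefer 0,
# then +1, then -1 (fixed, deterministic order).
ternary_mode <- function(Y, w) {
  alphabet <- c(0L, 1L, -1L)
  scores <- sapply(alphabet, function(v) colSums(w * (Y == v)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  alphabet[apply(scores, 1L, which.max)]
}

# Per-gene per-component log emission: m matches * log(1-eps) +
# mismatches * log(eps/2).
pattern_loglik <- function(Y, patterns, eps) {
  S <- ncol(Y)
  eps <- min(max(eps, 1e-8), 2 / 3 - 1e-8)
  sapply(seq_len(nrow(patterns)), function(m) {
    match_ct <- rowSums(Y == matrix(patterns[m, ], nrow(Y), S, byrow = TRUE))
    match_ct * log1p(-eps) + (S - match_ct) * log(eps / 2)
  })
}

#' Fit the ternary deregulation-pattern mixture by EM
#'
#' @param Y integer matrix genes x stromal types with entries in
#'   \{-1, 0, 1\}.
#' @param M_max maximum number of mixture components.
#' @param eps_init initial flip-noise probability.
#' @param dirichlet_alpha Dirichlet smoothing on the weights (>= 1; 1
#'   gives maximum likelihood).
#' @param n_restarts seeded random restarts; the best evidence is kept.
#' @param max_iter,tol EM controls.
#' @param seed integer seed; the fit is deterministic given it.
#' @return List of class `bm_patterns`: M, patterns (M x S matrix),
#'   weights, eps, posterior (genes x M), assignment (component index per
#'   gene), log_evidence, objective trace of the winning run.
#' @export
fit_pattern_model <- function(Y, M_max = 10L, eps_init = 0.05,
                              dirichlet_alpha = 1, n_restarts = 20L,
                              max_iter = 200L, tol = 1e-8, seed = 1L) {
  if (!all(Y %in% c(-1L, 0L, 1L))) stopf("Y entries must be in {-1, 0, 1}")
  M_max <- check_positive_int(M_max, "M_max")
  if (dirichlet_alpha < 1) stopf("dirichlet_alpha must be >= 1")
  n <- nrow(Y); S <- ncol(Y)
  if (is.null(rownames(Y))) rownames(Y) <- sprintf("g%d", seq_len(n))

  if (all(Y == 0L)) {
    patterns <- matrix(0L, 1L, S, dimnames = list(NULL, colnames(Y)))
    post <- matrix(1, n, 1L, dimnames = list(rownames(Y), NULL))
    return(structure(list(M = 1L, patterns = patterns, weights = 1,
                          eps = eps_init, posterior = post,
                          assignment = stats::setNames(rep(1L, n), rownames(Y)),
                          log_evidence = 0, objective_trace = numeric(0)),
                     class = "bm_patterns"))
  }

  run_em <- function(patterns, eps) {
    M <- nrow(patterns)
    w <- rep(1 / M, M)
    trace <- numeric(0)
    obj_old <- -Inf
    for (it in seq_len(max_iter)) {
      lp <- pattern_loglik(Y, patterns, eps)
      lw <- sweep(lp, 2L, log(w), "+")
      mx <- apply(lw, 1L, max)
      lse <- mx + log(rowSums(exp(lw - mx)))
      obj <- sum(lse) + (dirichlet_alpha - 1) * sum(log(w))
      trace <- c(trace, obj)
      gamma <- exp(lw - lse)
      Nm <- colSums(gamma)
      w <- (Nm + dirichlet_alpha - 1) /
        (n + M * (dirichlet_alpha - 1))
      w <- pmax(w, 1e-12); w <- w / sum(w)
      for (m in seq_len(M)) patterns[m, ] <- ternary_mode(Y, gamma[, m])
      match_frac <- sum(vapply(seq_len(M), function(m) {
        mc <- rowSums(Y == matrix(patterns[m, ], n, S, byrow = TRUE))
        sum(gamma[, m] * mc)
      }, numeric(1))) / (n * S)
      eps <- min(max(1 - match_frac, 1e-8), 2 / 3 - 1e-8)
      if (is.finite(obj_old) && abs(obj - obj_old) < tol * (1 + abs(obj))) break
      obj_old <- obj
    }
    lp <- pattern_loglik(Y, patterns, eps)
    lw <- sweep(lp, 2L, log(w), "+")
    mx <- apply(lw, 1L, max)
    lse <- mx + log(rowSums(exp(lw - mx)))
    obj <- sum(lse) + (dirichlet_alpha - 1) * sum(log(w))
    list(patterns = patterns, weights = w, eps = eps,
         log_evidence = obj, trace = c(trace, obj))
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(seed + r - 1L, {
      M0 <- min(M_max, n)
      init_rows <- unique(Y)[sample(nrow(unique(Y)),
                                    min(M0, nrow(unique(Y)))), , drop = FALSE]
      while (nrow(init_rows) < M0) {
        init_rows <- rbind(init_rows, Y[sample(n, 1L), ])
      }
      run_em(matrix(as.integer(init_rows), nrow(init_rows), S), eps_init)
    })
    if (is.null(best) || fit$log_evidence > best$log_evidence) best <- fit
  }

  keep <- best$weights >= 1 / (10 * M_max)
  patterns <- best$patterns[keep, , drop = FALSE]
  # collapse duplicate prototypes produced by different components
  key <- apply(patterns, 1L, paste, collapse = ",")
  patterns <- patterns[!duplicated(key), , drop = FALSE]
  w <- rep(1 / nrow(patterns), nrow(patterns))
  lp <- pattern_loglik(Y, patterns, best$eps)
  lw <- sweep(lp, 2L, log(w), "+")
  mx <- apply(lw, 1L, max)
  lse <- mx + log(rowSums(exp(lw - mx)))
  gamma <- exp(lw - lse)
  Nm <- colSums(gamma)
  w <- Nm / sum(Nm)
  # final responsibilities under re-estimated weights
  lw <- sweep(lp, 2L, log(pmax(w, 1e-12)), "+")
  mx <- apply(lw, 1L, max)
  lse <- mx + log(rowSums(exp(lw - mx)))
  gamma <- exp(lw - lse)
  assign_idx <- max.col(gamma, ties.method = "first")
  used <- sort(unique(assign_idx))
  patterns <- patterns[used, , drop = FALSE]
  gamma <- gamma[, used, drop = FALSE]
  gamma <- gamma / rowSums(gamma)
  w <- colSums(gamma) / n
  assign_idx <- match(assign_idx, used)
  colnames(patterns) <- colnames(Y)
  rownames(gamma) <- rownames(Y)
  structure(list(M = nrow(patterns), patterns = patterns, weights = w,
                 eps = best$eps, posterior = gamma,
                 assignment = stats::setNames(assign_idx, rownames(Y)),
                 log_evidence = best$log_evidence,
                 objective_trace = best$trace),
            class = "bm_patterns")
}

#' Classify patterns as cell-type-specific or shared
#'
#' A pattern with exactly one non-zero entry is specific to that stromal
#' type; two or more non-zero entries make it shared; the all-zero
#' pattern is the null pattern.
#'
#' @param model a fitted `bm_patterns` object (or a bare ternary matrix).
#' @return data.frame (pattern_id, class, member_types, n_genes).
#' @export
pattern_sharing <- function(model) {
  patterns <- if (inherits(model, "bm_patterns")) model$patterns else model
  n_genes <- if (inherits(model, "bm_patterns")) {
    tabulate(model$assignment, nbins = nrow(patterns))
  } else rep(NA_integer_, nrow(patterns))
  out <- lapply(seq_len(nrow(patterns)), function(m) {
    nz <- which(patterns[m, ] != 0)
    cls <- if (!length(nz)) "null" else if (length(nz) == 1L) "specific"
           else "shared"
    data.frame(pattern_id = m, class = cls,
               member_types = paste(colnames(patterns)[nz], collapse = ","),
               n_genes = n_genes[m], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
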