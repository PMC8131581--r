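# Independent brute-force oracles (explicit loops over the definitions)
# and small fixture builders. These stay deliberately naive and separate
# from the package implementations they check.

bf_size_factors <- function(counts) {
  n <- nrow(counts); m <- ncol(counts)
  eligible <- logical(n)
  for (g in seq_len(n)) eligible[g] <- all(counts[g, ] > 0)
  stopifnot(any(eligible))
  s <- numeric(m)
  for (j in seq_len(m)) {
    ratios <- c()
    for (g in which(eligible)) {
      geo <- prod(counts[g, ])^(1 / m)
      ratios <- c(ratios, counts[g, j] / geo)
    }
    s[j] <- median(ratios)
  }
  names(s) <- colnames(counts)
  s
}

bf_bh <- function(p) {
  m <- length(p)
  out <- rep(NA_real_, m)
  ok <- which(!is.na(p))
  pv <- p[ok]
  mm <- length(pv)
  ord <- order(pv)
  for (k in seq_len(mm)) {
    cand <- numeric(0)
    for (l in k:mm) cand <- c(cand, mm * pv[ord[l]] / l)
    out[ok[ord[k]]] <- min(1, min(cand))
  }
  out
}

bf_quantile_normalize <- function(X) {
  n <- nrow(X); m <- ncol(X)
  sorted <- matrix(0, n, m)
  for (j in seq_len(m)) sorted[, j] <- sort(X[, j])
  ref <- numeric(n)
  for (i in seq_len(n)) ref[i] <- mean(sorted[i, ])
  out <- X
  for (j in seq_len(m)) {
    rmin <- rank(X[, j], ties.method = "min")
    rmax <- rank(X[, j], ties.method = "max")
    for (i in seq_len(n)) out[i, j] <- mean(ref[rmin[i]:rmax[i]])
  }
  out
}

# rho/delta/nearest under the package's stable tie-break: j is "higher"
# than i iff rho_j > rho_i, or rho_j == rho_i and j precedes i.
bf_density <- function(z, d_c) {
  n <- nrow(z)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sqrt(sum((z[i, ] - z[j, ])^2))
  }
  rho <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) if (j != i) rho[i] <- rho[i] + exp(-(d[i, j] / d_c)^2)
  }
  delta <- numeric(n); nearest <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    best <- Inf; bj <- NA_integer_
    for (j in seq_len(n)) {
      if (j == i) next
      higher <- rho[j] > rho[i] || (rho[j] == rho[i] && j < i)
      if (higher && d[i, j] < best) { best <- d[i, j]; bj <- j }
    }
    if (is.na(bj)) delta[i] <- max(d[i, ]) else { delta[i] <- best; nearest[i] <- bj }
  }
  list(rho = rho, delta = delta, nearest = nearest)
}

# nested-loop join: significant ligand x significant receptor per type
bf_build_edges <- function(secretome_de, stromal_de, pairs) {
  rows <- list()
  for (ty in names(stromal_de)) {
    de <- stromal_de[[ty]]
    for (r in seq_len(nrow(pairs))) {
      lg <- toupper(pairs$ligand[r]); rc <- toupper(pairs$receptor[r])
      i <- which(toupper(secretome_de$feature) == lg)
      j <- which(toupper(de$feature) == rc)
      if (!length(i) || !length(j)) next
      ld <- secretome_de$call[i[1]]; rd <- de$call[j[1]]
      if (ld == "ns" || rd == "ns") next
      rows[[length(rows) + 1L]] <- data.frame(
        stromal_type = ty, ligand = lg, ligand_dir = ld, receptor = rc,
        receptor_dir = rd, coherent = ld == rd, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# Random profile instance without accidental rho near-ties (the
# delta/nearest definition is only unambiguous when densities are
# strictly ordered; exact duplicates are exercised by a dedicated test).
rand_density_instance <- function(seed) {
  set.seed(seed)
  repeat {
    n <- sample(10:60, 1)
    z <- matrix(rnorm(n * sample(2:7, 1)), n)
    rownames(z) <- sprintf("g%02d", seq_len(n))
    dc <- runif(1, 0.3, 2)
    d <- as.matrix(dist(z))
    rho <- colSums(exp(-(d / dc)^2)) - 1
    if (min(diff(sort(rho))) > 1e-8) return(list(z = z, dc = dc))
  }
}

# ---- fixture builders ------------------------------------------------

rand_counts <- function(n_genes, n_samples, mu = 50, size = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, mu = mu, size = size) + 1L,
              n_genes, n_samples)
  storage.mode(m) <- "integer" 
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%02d", seq_len(n_samples)))
  m
}

two_group_meta <- function(n_per_group, groups = c("AML", "ctrl"),
                           stromal_type = "x") {
  data.frame(sample_id = sprintf("s%02d", seq_len(2 * n_per_group)),
             stromal_type = stromal_type,
             condition = rep(groups, each = n_per_group),
             replicate = seq_len(2 * n_per_group),
             stringsAsFactors = FALSE)
}

# ternary observations from known patterns with symmetric flip noise
gen_ternary <- function(patterns, weights, eps, n, seed) {
  set.seed(seed)
  S <- ncol(patterns)
  comp <- sample(nrow(patterns), n, replace = TRUE, prob = weights)
  Y <- patterns[comp, , drop = FALSE]
  flip <- which(matrix(runif(n * S) < eps, n, S))
  if (length(flip)) {
    Y[flip] <- vapply(Y[flip], function(x) {
      sample(setdiff(c(-1L, 0L, 1L), x), 1L)
    }, integer(1))
  }
  storage.mode(Y) <- "integer"
  rownames(Y) <- sprintf("g%d", seq_len(n))
  list(Y = Y, comp = comp)
}

pattern_key <- function(m) apply(m, 1L, paste, collapse = ",")

# perfect DE call tables straight from simulation ground truth
perfect_calls <- function(truth) {
  sec_de <- data.frame(
    feature = names(truth$protein_shift),
    call = ifelse(truth$protein_shift > 0, "up",
                  ifelse(truth$protein_shift < 0, "down", "ns")),
    stringsAsFactors = FALSE)
  stromal_de <- lapply(colnames(truth$pattern_of_gene), function(ty) {
    p <- truth$pattern_of_gene[, ty]
    data.frame(feature = rownames(truth$pattern_of_gene),
               call = ifelse(p > 0, "up", ifelse(p < 0, "down", "ns")),
               stringsAsFactors = FALSE)
  })
  names(stromal_de) <- colnames(truth$pattern_of_gene)
  list(secretome = sec_de, stromal = stromal_de)
}
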