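#' Simulation configuration for the synthetic niche dataset
#'
#' Bundles every knob of the synthetic-data generator. The defaults state
#' the simulated world once: 7 stromal populations (mirroring the
#' CD31 / Nes-high / Nes-low / Ng2 / Osx / Col-low / Col-high reporter
#' panel), two conditions (ctrl and AML xenograft), negative-binomial
#' counts with 8 embedded archetype clusters, ternary per-population
#' deregulation effects applied as log2 fold-changes, and a log-normal
#' secretome with a deregulated ligand subset wired to receptor genes
#' through a generated ligand-receptor table.
#'
#' @param n_genes number of genes.
#' @param n_proteins number of secretome proteins.
#' @param stromal_types ordered character vector of population labels.
#' @param replicates_per_group biological replicates per
#'   (population, condition) group; must be >= 2.
#' @param n_clusters number of archetype expression clusters (K).
#' @param n_patterns number of distinct ternary deregulation patterns (M).
#' @param effect_size_lfc deregulation effect, in log2 units, applied
#'   multiplicatively to AML-condition means.
#' @param dispersion negative-binomial dispersion alpha (variance
#'   mu + alpha * mu^2); 0 gives Poisson counts.
#' @param noise_eps ternary flip-noise probability used when simulating
#'   pattern observations.
#' @param noise_gene_frac fraction of genes with flat (clusterless) profiles.
#' @param profile_noise_sd sd, in log2 units, of per-gene per-population
#'   scatter around the archetype profile.
#' @param profile_amplitude scale, in log2 units, of the archetype signal.
#' @param dereg_gene_frac fraction of genes carrying a non-null
#'   deregulation pattern.
#' @param base_log2_range range of baseline log2 mean expression.
#' @param secretome_sd residual sd of log2 protein intensities.
#' @param n_coherent_pairs number of planted coherent ligand-receptor pairs.
#' @param n_lr_pairs total rows of the generated ligand-receptor table.
#' @param conditions conditions to simulate (subset of ctrl, CB, AML).
#' @param seed integer seed fixing all randomness end to end.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_proteins = 300L,
                       stromal_types = c("CD31", "NesHigh", "NesLow", "Ng2",
                                         "Osx", "ColLow", "ColHigh"),
                       replicates_per_group = 4L,
                       n_clusters = 8L,
                       n_patterns = 3L,
                       effect_size_lfc = 2,
                       dispersion = 0.05,
                       noise_eps = 0.05,
                       noise_gene_frac = 0.1,
                       profile_noise_sd = 0.25,
                       profile_amplitude = 2,
                       dereg_gene_frac = 0.3,
                       base_log2_range = c(5, 9),
                       secretome_sd = 0.5,
                       n_coherent_pairs = 25L,
                       n_lr_pairs = 120L,
                       conditions = c("ctrl", "AML"),
                       seed = 1L) {
  n_genes <- check_positive_int(n_genes, "n_genes")
  n_proteins <- check_positive_int(n_proteins, "n_proteins")
  replicates_per_group <- check_positive_int(replicates_per_group,
                                             "replicates_per_group")
  n_clusters <- check_positive_int(n_clusters, "n_clusters")
  n_patterns <- check_positive_int(n_patterns, "n_patterns")
  if (replicates_per_group < 2L) stopf("replicates_per_group must be >= 2")
  if (n_clusters > n_genes) stopf("n_clusters (K) must be <= n_genes")
  if (!is.finite(effect_size_lfc)) stopf("effect_size_lfc must be finite")
  if (dispersion < 0) stopf("dispersion must be non-negative")
  if (noise_eps < 0 || noise_eps > 1) stopf("noise_eps must be in [0,1]")
  if (length(stromal_types) < 2L) stopf("need at least 2 stromal types")
  if (anyDuplicated(stromal_types)) stopf("stromal_types must be unique")
  if (!all(conditions %in% c("ctrl", "CB", "AML"))) {
    stopf("conditions must be drawn from {ctrl, CB, AML}")
  }
  structure(list(
    n_genes = n_genes, n_proteins = n_proteins,
    stromal_types = as.character(stromal_types),
    replicates_per_group = replicates_per_group,
    n_clusters = n_clusters, n_patterns = n_patterns,
    effect_size_lfc = effect_size_lfc, dispersion = dispersion,
    noise_eps = noise_eps, noise_gene_frac = noise_gene_frac,
    profile_noise_sd = profile_noise_sd,
    profile_amplitude = profile_amplitude,
    dereg_gene_frac = dereg_gene_frac,
    base_log2_range = base_log2_range,
    secretome_sd = secretome_sd,
    n_coherent_pairs = as.integer(n_coherent_pairs),
    n_lr_pairs = as.integer(n_lr_pairs),
    conditions = conditions, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Separable archetype profiles over stromal types
#'
#' Generates K unit-variance (z-scored) profiles over S populations with
#' pairwise Pearson correlation below 0.5 by construction. Up to S-1
#' profiles are exactly orthogonal after centering (Gram-Schmidt in the
#' centered subspace); any surplus profiles are drawn by seeded rejection
#' sampling against the |r| < 0.5 bound, which is the best achievable once
#' K exceeds the centered dimension.
#'
#' @param K number of archetypes.
#' @param S number of stromal types.
#' @param max_cor rejection bound on pairwise |correlation|.
#' @return K x S numeric matrix, rows z-scored.
#' @export
archetype_profiles <- function(K, S, max_cor = 0.5) {
  if (S < 3L) stopf("need at least 3 stromal types for archetypes")
  zscore <- function(v) (v - mean(v)) / stats::sd(v)
  n_orth <- min(K, S - 1L)
  basis <- matrix(0, n_orth, S)
  k <- 1L
  tries <- 0L
  while (k <= n_orth) {
    v <- stats::rnorm(S)
    v <- v - mean(v)
    if (k > 1L) {
      for (j in seq_len(k - 1L)) {
        b <- basis[j, ]
        v <- v - sum(v * b) / sum(b * b) * b
      }
    }
    if (sqrt(sum(v^2)) > 1e-6) {
      basis[k, ] <- v
      k <- k + 1L
    }
    tries <- tries + 1L
    if (tries > 1000L) stopf("archetype orthogonalization failed")
  }
  A <- t(apply(basis, 1L, zscore))
  while (nrow(A) < K) {
    ok <- FALSE
    for (try in seq_len(5000L)) {
      v <- zscore(stats::rnorm(S))
      if (max(abs(A %*% v) / (S - 1L)) < max_cor) {
        A <- rbind(A, v)
        ok <- TRUE
        break
      }
    }
    if (!ok) stopf("could not place %d archetypes with |r| < %.2f over %d types",
                   K, max_cor, S)
  }
  dimnames(A) <- NULL
  A
}

# All (stromal_type, ligand, receptor, direction) records where the ligand
# shift and the receptor's ternary pattern entry share a sign.
enumerate_coherent_truth <- function(lr, shift, pat) {
  out <- list()
  for (i in seq_len(nrow(lr))) {
    s <- shift[lr$ligand[i]]
    if (is.na(s) || s == 0) next
    g <- lr$receptor[i]
    if (!g %in% rownames(pat)) next
    for (ty in colnames(pat)) {
      p <- pat[g, ty]
      if (p != 0 && sign(p) == sign(s)) {
        out[[length(out) + 1L]] <- data.frame(
          ligand = lr$ligand[i], receptor = g, stromal_type = ty,
          direction = if (s > 0) "up" else "down",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(ligand = character(), receptor = character(),
                      stromal_type = character(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Distinct random ternary patterns, each with 1..3 non-zero entries.
random_ternary_patterns <- function(M, S) {
  seen <- character(0)
  P <- matrix(0L, 0L, S)
  guard <- 0L
  while (nrow(P) < M) {
    guard <- guard + 1L
    if (guard > 10000L) stopf("could not draw %d distinct patterns", M)
    p <- integer(S)
    nz <- sample(1:3, 1L)
    pos <- sample(S, nz)
    p[pos] <- sample(c(-1L, 1L), nz, replace = TRUE)
    key <- paste(p, collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      P <- rbind(P, p)
    }
  }
  dimnames(P) <- NULL
  P
}

#' Simulate stromal transcriptome counts with known ground truth
#'
#' Draws a gene-by-sample integer count matrix from a negative-binomial
#' model. Gene g in archetype cluster k has per-population log2 mean
#' `base_g + profile_amplitude * A[k, s] + N(0, profile_noise_sd)`;
#' AML-condition samples multiply the mean by
#' `2^(pattern[g, s] * effect_size_lfc)`; every sample carries a true size
#' factor drawn log-uniformly from [0.5, 2]. The returned ground truth
#' records cluster memberships ("noise" for flat genes), the ternary
#' deregulation pattern of every gene, the archetype matrix and the true
#' size factors.
#'
#' @param cfg a [sim_config()].
#' @return list with `counts` (integer matrix, genes x samples), `meta`
#'   (sample metadata data.frame) and `truth` (ground-truth list).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    S <- length(cfg$stromal_types)
    genes <- sprintf("G%05d", seq_len(cfg$n_genes))
    A <- archetype_profiles(cfg$n_clusters, S)

    cluster_of_gene <- sample(
      c(as.character(seq_len(cfg$n_clusters)), "noise"),
      cfg$n_genes, replace = TRUE,
      prob = c(rep((1 - cfg$noise_gene_frac) / cfg$n_clusters,
                   cfg$n_clusters), cfg$noise_gene_frac))
    names(cluster_of_gene) <- genes

    base_log2 <- stats::runif(cfg$n_genes, cfg$base_log2_range[1],
                              cfg$base_log2_range[2])
    # clustered genes scatter around their archetype with reproducible
    # per-type offsets; "noise" genes have literally flat mean profiles
    # (no type effect), so pairwise stromal DE has nothing to detect
    prof <- matrix(stats::rnorm(cfg$n_genes * S, 0, cfg$profile_noise_sd),
                   cfg$n_genes, S)
    is_clustered <- cluster_of_gene != "noise"
    prof[!is_clustered, ] <- 0
    prof[is_clustered, ] <- prof[is_clustered, ] +
      cfg$profile_amplitude * A[as.integer(cluster_of_gene[is_clustered]), ]
    log2_mu0 <- base_log2 + prof   # genes x types, ctrl condition

    pat_lib <- random_ternary_patterns(cfg$n_patterns, S)
    pattern_of_gene <- matrix(0L, cfg$n_genes, S,
                              dimnames = list(genes, cfg$stromal_types))
    dereg <- stats::runif(cfg$n_genes) < cfg$dereg_gene_frac
    pattern_id <- rep(0L, cfg$n_genes)
    pattern_id[dereg] <- sample(cfg$n_patterns, sum(dereg), replace = TRUE)
    pattern_of_gene[dereg, ] <- pat_lib[pattern_id[dereg], , drop = FALSE]

    meta <- expand.grid(replicate = seq_len(cfg$replicates_per_group),
                        condition = cfg$conditions,
                        stromal_type = cfg$stromal_types,
                        stringsAsFactors = FALSE)
    meta <- meta[, c("stromal_type", "condition", "replicate")]
    meta$sample_id <- sprintf("%s_%s_r%d", meta$stromal_type,
                              meta$condition, meta$replicate)
    meta <- meta[, c("sample_id", "stromal_type", "condition", "replicate")]
    sf_true <- 2^stats::runif(nrow(meta), -1, 1)   # log-uniform in [0.5, 2]
    names(sf_true) <- meta$sample_id

    type_idx <- match(meta$stromal_type, cfg$stromal_types)
    MU <- matrix(0, cfg$n_genes, nrow(meta),
                 dimnames = list(genes, meta$sample_id))
    for (j in seq_len(nrow(meta))) {
      l2 <- log2_mu0[, type_idx[j]]
      if (meta$condition[j] == "AML") {
        l2 <- l2 + pattern_of_gene[, type_idx[j]] * cfg$effect_size_lfc
      }
      MU[, j] <- sf_true[j] * 2^l2
    }
    counts <- if (cfg$dispersion > 0) {
      matrix(stats::rnbinom(length(MU), mu = as.vector(MU),
                            size = 1 / cfg$dispersion),
             nrow(MU), ncol(MU), dimnames = dimnames(MU))
    } else {
      matrix(stats::rpois(length(MU), as.vector(MU)),
             nrow(MU), ncol(MU), dimnames = dimnames(MU))
    }
    storage.mode(counts) <- "integer"

    truth <- list(cluster_of_gene = cluster_of_gene,
                  pattern_of_gene = pattern_of_gene,
                  pattern_library = pat_lib,
                  archetypes = A,
                  size_factors = sf_true,
                  base_log2 = stats::setNames(base_log2, genes))
    list(counts = counts, meta = meta, truth = truth)
  })
}

#' Simulate z-scored expression profiles directly
#'
#' A profile-level restatement of the clustered world used by
#' [simulate_counts()]: clustered genes scatter around their archetype with
#' Gaussian noise of sd `profile_noise_sd`, flat "noise" genes carry noise
#' only, and every row is z-scored across stromal types. Used to exercise
#' the density-peak clustering stage in isolation.
#'
#' @param cfg a [sim_config()].
#' @return list with `z` (genes x types z-profile matrix) and `truth`.
#' @export
simulate_profiles <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    S <- length(cfg$stromal_types)
    genes <- sprintf("G%05d", seq_len(cfg$n_genes))
    A <- archetype_profiles(cfg$n_clusters, S)
    cluster_of_gene <- sample(
      c(as.character(seq_len(cfg$n_clusters)), "noise"),
      cfg$n_genes, replace = TRUE,
      prob = c(rep((1 - cfg$noise_gene_frac) / cfg$n_clusters,
                   cfg$n_clusters), cfg$noise_gene_frac))
    names(cluster_of_gene) <- genes
    z <- matrix(stats::rnorm(cfg$n_genes * S, 0, cfg$profile_noise_sd),
                cfg$n_genes, S, dimnames = list(genes, cfg$stromal_types))
    keep <- cluster_of_gene != "noise"
    z[keep, ] <- z[keep, ] + A[as.integer(cluster_of_gene[keep]), ]
    z <- t(apply(z, 1L, function(v) (v - mean(v)) / stats::sd(v)))
    list(z = z,
         truth = list(cluster_of_gene = cluster_of_gene, archetypes = A))
  })
}

#' Simulate secretome intensities and a ligand-receptor table
#'
#' Draws log-normal protein intensities for ctrl and AML bone-marrow-fluid
#' samples, shifts a designated ligand subset by +/- `effect_size_lfc`
#' log2 units in AML, and wires ligand proteins to receptor genes from the
#' transcriptome ground truth so that a known set of pairs is coherently
#' deregulated (ligand and receptor moving in the same direction in a
#' given stromal type). Incoherent and null pairs pad the table to
#' `n_lr_pairs` rows.
#'
#' @param cfg a [sim_config()].
#' @param truth ground truth from [simulate_counts()].
#' @return list with `intensities` (protein x sample positive matrix),
#'   `meta`, `lr_pairs` (data.frame ligand/receptor/pathway) and `truth`
#'   (adds `protein_shift` and `true_coherent_pairs`).
#' @export
simulate_secretome <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 1L, {
    proteins <- sprintf("SP%04d", seq_len(cfg$n_proteins))
    pat <- truth$pattern_of_gene
    nz <- which(pat != 0, arr.ind = TRUE)
    n_coh <- min(cfg$n_coherent_pairs, nrow(nz), cfg$n_proteins %/% 2L)
    if (n_coh < cfg$n_coherent_pairs) {
      warnf("only %d coherent pairs can be planted (requested %d)",
            n_coh, cfg$n_coherent_pairs)
    }
    if (n_coh < 1L) stopf("no deregulated (gene, type) entries to pair with")
    need_lig <- min(cfg$n_proteins, 2L * n_coh)
    lig_pool <- sample(proteins, need_lig)
    coh_lig <- lig_pool[seq_len(n_coh)]
    inc_lig <- lig_pool[-seq_len(n_coh)]

    pick <- nz[sample(nrow(nz), n_coh), , drop = FALSE]
    coh <- data.frame(
      ligand = coh_lig,
      receptor = rownames(pat)[pick[, 1]],
      stromal_type = colnames(pat)[pick[, 2]],
      direction = ifelse(pat[pick] > 0, "up", "down"),
      stringsAsFactors = FALSE)

    shift <- stats::setNames(numeric(cfg$n_proteins), proteins)
    shift[coh$ligand] <- ifelse(coh$direction == "up", 1, -1) *
      cfg$effect_size_lfc

    # incoherent pairs: ligand shifted opposite to a deregulated receptor
    inc_pick <- nz[sample(nrow(nz), length(inc_lig)), , drop = FALSE]
    inc <- data.frame(
      ligand = inc_lig,
      receptor = rownames(pat)[inc_pick[, 1]],
      stromal_type = colnames(pat)[inc_pick[, 2]],
      direction = ifelse(pat[inc_pick] > 0, "down", "up"),
      stringsAsFactors = FALSE)
    shift[inc$ligand] <- ifelse(inc$direction == "up", 1, -1) *
      cfg$effect_size_lfc

    null_genes <- names(truth$cluster_of_gene)
    free_prot <- setdiff(proteins, lig_pool)
    n_null <- if (length(free_prot)) {
      max(0L, cfg$n_lr_pairs - nrow(coh) - nrow(inc))
    } else 0L
    null_pairs <- data.frame(
      ligand = if (n_null) sample(free_prot, n_null, replace = TRUE)
               else character(0),
      receptor = if (n_null) sample(null_genes, n_null, replace = TRUE)
                 else character(0),
      stringsAsFactors = FALSE)

    lr <- rbind(coh[, c("ligand", "receptor")],
                inc[, c("ligand", "receptor")],
                null_pairs)
    lr <- lr[!duplicated(lr[, c("ligand", "receptor")]), , drop = FALSE]
    lr$pathway <- sprintf("PW%d", 1L + (seq_len(nrow(lr)) - 1L) %% 10L)
    rownames(lr) <- NULL

    conds <- intersect(c("ctrl", "AML"), cfg$conditions)
    meta <- expand.grid(replicate = seq_len(cfg$replicates_per_group),
                        condition = conds, stringsAsFactors = FALSE)
    meta$stromal_type <- "BM_fluid"
    meta$sample_id <- sprintf("SEC_%s_r%d", meta$condition, meta$replicate)
    meta <- meta[, c("sample_id", "stromal_type", "condition", "replicate")]

    base <- stats::rnorm(cfg$n_proteins, 10, 1.5)
    L2 <- matrix(stats::rnorm(cfg$n_proteins * nrow(meta), 0, cfg$secretome_sd),
                 cfg$n_proteins, nrow(meta),
                 dimnames = list(proteins, meta$sample_id))
    L2 <- L2 + base
    aml <- meta$condition == "AML"
    L2[, aml] <- L2[, aml] + shift

    # Exhaustive ground truth: a pair is coherent at a type whenever the
    # ligand is shifted and the receptor's pattern entry has the same sign
    # there (planted pairs guarantee at least n_coherent_pairs of these,
    # but cross-type matches of other deregulated pairs also count).
    truth$protein_shift <- shift
    truth$true_coherent_pairs <- enumerate_coherent_truth(lr, shift, pat)
    truth$planted_coherent_pairs <- coh
    truth$incoherent_pairs <- inc
    list(intensities = 2^L2, meta = meta, lr_pairs = lr, truth = truth)
  })
}
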