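# Density-peak clustering of z-scored gene profiles: local density rho,
# distance-to-higher-density delta, center selection by gamma = rho*delta,
# chain assignment, halo (noise) exclusion, compactness, condition-shift
# summaries and gene-set annotation.

# d_c such that the mean Gaussian neighborhood mass, mean(rho)/(n-1),
# is ~ target_mass; monotone in d_c, solved by uniroot on log d_c.
auto_dc <- function(d, target_mass = 0.02) {
  n <- nrow(d)
  off <- d[upper.tri(d)]
  pos <- off[off > 0]
  if (!length(pos)) stopf("all profiles identical; cannot choose d_c")
  mass <- function(logdc) {
    dc <- exp(logdc)
    e <- exp(-(off / dc)^2)
    2 * sum(e) / (n * (n - 1)) - target_mass
  }
  lo <- log(min(pos)) - 8
  hi <- log(max(off)) + 8
  if (mass(lo) > 0) return(min(pos) / 2)
  if (mass(hi) < 0) return(max(off))
  exp(stats::uniroot(mass, c(lo, hi), tol = 1e-10)$root)
}

#' Local density and separation statistics for density-peak clustering
#'
#' For gene profiles z (rows), with Euclidean distance d_ij:
#' `rho_i = sum_{j != i} exp(-(d_ij / d_c)^2)` (Gaussian kernel) and
#' `delta_i` = distance to the nearest gene of higher density (ties in
#' rho broken by stable row order); the globally densest gene takes
#' `delta = max_j d_ij`. `gamma = rho * delta` ranks cluster-center
#' candidates.
#'
#' @param z numeric matrix of profiles (genes x stromal types), rownames
#'   = gene ids; rows with NA are rejected.
#' @param d_c kernel bandwidth; "auto" picks d_c so the mean neighborhood
#'   mass is ~`target_mass` of the genes.
#' @param target_mass auto-bandwidth target (default 0.02).
#' @return Object of class `bm_density`: data.frame `stats` (gene, rho,
#'   delta, gamma, nearest_higher) plus the distance matrix and d_c.
#' @export
density_stats <- function(z, d_c = "auto", target_mass = 0.02) {
  if (is.null(rownames(z))) rownames(z) <- sprintf("g%d", seq_len(nrow(z)))
  if (nrow(z) < 2L) stopf("need >=2 genes")
  if (anyNA(z)) stopf("NA in profiles; drop flat genes before clustering")
  d <- as.matrix(stats::dist(z))
  if (identical(d_c, "auto")) {
    d_c <- auto_dc(d, target_mass)
  } else {
    if (!is.numeric(d_c) || d_c <= 0) stopf("d_c must be positive")
  }
  n <- nrow(d)
  rho <- unname(colSums(exp(-(d / d_c)^2))) - 1   # remove self term
  ord <- order(-rho, seq_len(n))          # density order, stable ties
  delta <- numeric(n)
  nearest <- rep(NA_integer_, n)
  delta[ord[1]] <- max(d[ord[1], ])
  for (k in seq(2L, n)) {
    i <- ord[k]
    prev <- ord[seq_len(k - 1L)]
    j <- prev[which.min(d[i, prev])]
    delta[i] <- d[i, j]
    nearest[i] <- j
  }
  genes <- rownames(z)
  stats_df <- data.frame(
    gene = genes, rho = rho, delta = delta, gamma = rho * delta,
    nearest_higher = ifelse(is.na(nearest), NA_character_, genes[nearest]),
    stringsAsFactors = FALSE)
  structure(list(stats = stats_df, dist = d, d_c = d_c,
                 order = ord, nearest_idx = nearest),
            class = "bm_density")
}

#' Assign genes to density-peak clusters
#'
#' Centers are the top-K genes by gamma (stable ties); every remaining
#' gene, visited in decreasing density, inherits the cluster of its
#' nearest higher-density neighbor, so the chain always terminates at a
#' center. `K = "auto"` picks the largest relative gap in the sorted
#' gamma sequence.
#'
#' @param dstats a `bm_density` object.
#' @param K number of clusters, or "auto".
#' @param max_auto_k largest K considered by the auto rule.
#' @return data.frame (gene, cluster, is_center); clusters are labeled
#'   "1".."K" in decreasing-gamma order of their centers.
#' @export
assign_clusters <- function(dstats, K = 8L, max_auto_k = 50L) {
  stopifnot(inherits(dstats, "bm_density"))
  st <- dstats$stats
  n <- nrow(st)
  gam_ord <- order(-st$gamma, seq_len(n))
  if (identical(K, "auto")) {
    gs <- st$gamma[gam_ord]
    kmax <- min(max_auto_k, n - 1L)
    ratios <- gs[seq_len(kmax)] / pmax(gs[seq_len(kmax) + 1L], 1e-12)
    K <- which.max(ratios)
  }
  K <- check_positive_int(K, "K")
  if (K > n) stopf("K exceeds number of genes")
  if (K > length(unique(st$gamma))) {
    stopf("K = %d exceeds the %d distinct gamma values", K,
          length(unique(st$gamma)))
  }
  centers <- gam_ord[seq_len(K)]
  cluster <- rep(NA_integer_, n)
  cluster[centers] <- seq_len(K)
  for (i in dstats$order) {
    if (!is.na(cluster[i])) next
    up <- dstats$nearest_idx[i]
    if (is.na(up) || is.na(cluster[up])) {
      # densest gene not chosen as a center: fall back to nearest center
      cluster[i] <- cluster[centers[which.min(dstats$dist[i, centers])]]
    } else {
      cluster[i] <- cluster[up]
    }
  }
  data.frame(gene = st$gene, cluster = as.character(cluster),
             is_center = seq_len(n) %in% centers, stringsAsFactors = FALSE)
}

#' Flag halo (noise) genes in low-density border regions
#'
#' For each cluster, the border density is the maximum of
#' `(rho_i + rho_j) / 2` over member/non-member pairs closer than d_c;
#' members whose density falls below it are flagged halo. Centers are
#' never flagged. Re-application is a no-op.
#'
#' @param assign assignment from [assign_clusters()].
#' @param dstats the `bm_density` object used for the assignment.
#' @return `assign` with an `is_halo` logical column.
#' @export
exclude_halo <- function(assign, dstats) {
  stopifnot(inherits(dstats, "bm_density"))
  d <- dstats$dist
  rho <- dstats$stats$rho
  cl <- assign$cluster
  halo <- rep(FALSE, nrow(assign))
  for (b in unique(cl)) {
    inb <- which(cl == b)
    outb <- which(cl != b)
    if (!length(outb)) next
    sub <- d[inb, outb, drop = FALSE] < dstats$d_c
    if (!any(sub)) next
    pairs <- which(sub, arr.ind = TRUE)
    rho_b <- max((rho[inb[pairs[, 1]]] + rho[outb[pairs[, 2]]]) / 2)
    halo[inb] <- rho[inb] < rho_b
  }
  halo[assign$is_center] <- FALSE
  assign$is_halo <- halo
  assign
}

#' Cluster mean profiles and compactness
#'
#' Compactness of a cluster is the average Pearson correlation between
#' each non-halo member's z-profile and the cluster's mean profile.
#' Singleton or degenerate (zero-variance mean) clusters report NA.
#'
#' @param assign assignment (with `is_halo` if halo exclusion was run).
#' @param z gene x type z-profile matrix.
#' @return List: `summary` data.frame (cluster, size, compactness) and
#'   `mean_profiles` (cluster x type matrix).
#' @export
compactness <- function(assign, z) {
  if (is.null(assign$is_halo)) assign$is_halo <- FALSE
  core <- assign[!assign$is_halo, , drop = FALSE]
  clusters <- sort(unique(core$cluster))
  mp <- matrix(NA_real_, length(clusters), ncol(z),
               dimnames = list(clusters, colnames(z)))
  size <- integer(length(clusters))
  comp <- rep(NA_real_, length(clusters))
  for (i in seq_along(clusters)) {
    members <- core$gene[core$cluster == clusters[i]]
    size[i] <- length(members)
    zm <- z[members, , drop = FALSE]
    mp[i, ] <- colMeans(zm)
    if (length(members) < 2L || stats::sd(mp[i, ]) < 1e-12) next
    rs <- apply(zm, 1L, function(v) {
      if (stats::sd(v) < 1e-12) return(NA_real_)
      stats::cor(v, mp[i, ])
    })
    comp[i] <- mean(rs, na.rm = TRUE)
  }
  list(summary = data.frame(cluster = clusters, size = size,
                            compactness = comp, stringsAsFactors = FALSE),
       mean_profiles = mp)
}

#' Mean deregulation of a gene cluster per stromal type
#'
#' Averages the per-type AML log2 fold-changes over a cluster's members
#' and stars the shift when at least `star_frac` of the members pass the
#' FDR gate in that type.
#'
#' @param genes cluster member gene ids.
#' @param de_by_type named list of condition DE tables, one per stromal
#'   type ([de_condition_per_type()]).
#' @param q member-level FDR gate (default 0.1).
#' @param star_frac fraction of members that must pass the gate
#'   (default 0.5).
#' @return data.frame (stromal_type, mean_log2FC, n, starred).
#' @export
cluster_condition_shift <- function(genes, de_by_type, q = 0.1,
                                    star_frac = 0.5) {
  out <- lapply(names(de_by_type), function(ty) {
    de <- de_by_type[[ty]]
    sub <- de[de$feature %in% genes, , drop = FALSE]
    if (!nrow(sub)) {
      return(data.frame(stromal_type = ty, mean_log2FC = NA_real_,
                        n = 0L, starred = NA, stringsAsFactors = FALSE))
    }
    data.frame(stromal_type = ty,
               mean_log2FC = mean(sub$log2FC, na.rm = TRUE),
               n = nrow(sub),
               starred = mean(!is.na(sub$padj) & sub$padj < q) >= star_frac,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Hypergeometric over-representation of gene sets per cluster
#'
#' For every (cluster, set) the upper-tail hypergeometric p of the
#' overlap within `universe`, BH-adjusted within each cluster. Sets
#' disjoint from the universe are skipped with a warning.
#'
#' @param assign cluster assignment (halo genes excluded when flagged).
#' @param sets named list of symbol vectors (e.g. from [read_gmt()]).
#' @param universe background gene ids (must contain all cluster genes).
#' @return data.frame (cluster, set, overlap, set_size, p, padj).
#' @export
annotate_clusters <- function(assign, sets, universe) {
  if (is.null(assign$is_halo)) assign$is_halo <- FALSE
  core <- assign[!assign$is_halo, , drop = FALSE]
  universe <- unique(norm_symbol(universe))
  if (!all(norm_symbol(core$gene) %in% universe)) {
    stopf("universe must contain all cluster genes")
  }
  N <- length(universe)
  keep <- vapply(sets, function(s) any(norm_symbol(s) %in% universe), TRUE)
  if (any(!keep)) {
    warnf("skipping %d set(s) disjoint from the universe", sum(!keep))
    sets <- sets[keep]
  }
  rows <- list()
  for (cl in sort(unique(core$cluster))) {
    members <- unique(norm_symbol(core$gene[core$cluster == cl]))
    n_draw <- length(members)
    ps <- vapply(names(sets), function(sn) {
      s <- intersect(norm_symbol(sets[[sn]]), universe)
      k <- length(intersect(members, s))
      stats::phyper(k - 1, length(s), N - length(s), n_draw,
                    lower.tail = FALSE)
    }, numeric(1))
    ks <- vapply(names(sets), function(sn) {
      length(intersect(members, norm_symbol(sets[[sn]])))
    }, integer(1))
    rows[[cl]] <- data.frame(
      cluster = cl, set = names(sets), overlap = ks,
      set_size = vapply(sets, function(s)
        length(intersect(norm_symbol(s), universe)), integer(1)),
      p = ps, padj = bh_adjust(ps), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
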