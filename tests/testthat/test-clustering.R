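two_blob_profiles <- function(seed = 20, n_per = 50, sep = 10, sd = 0.3) {
  set.seed(seed)
  z <- rbind(cbind(rnorm(n_per, 0, sd), rnorm(n_per, 0, sd)),
             cbind(rnorm(n_per, sep, sd), rnorm(n_per, 0, sd)))
  rownames(z) <- sprintf("g%03d", seq_len(2 * n_per))
  z
}

test_that("density stats match the brute-force oracle exactly", {
  for (i in 1:10) {
    inst <- rand_density_instance(500 + i)
    ds <- density_stats(inst$z, d_c = inst$dc)
    bf <- bf_density(inst$z, inst$dc)
    expect_equal(ds$stats$rho, bf$rho, tolerance = 1e-12)
    expect_equal(ds$stats$delta, bf$delta, tolerance = 1e-12)
    expect_identical(match(ds$stats$nearest_higher, rownames(inst$z)),
                     bf$nearest)
  }
})

test_that("two separated blobs give exactly two dominant gamma values", {
  z <- two_blob_profiles()
  ds <- density_stats(z, d_c = 1)
  gam <- sort(ds$stats$gamma, decreasing = TRUE)
  expect_gt(gam[2], 10 * gam[3])
  asg <- assign_clusters(ds, K = 2)
  truth <- rep(c("a", "b"), each = 50)
  expect_equal(adjusted_rand_index(truth, asg$cluster), 1)
})

test_that("degenerate duplicated profiles yield all-zero deltas", {
  z <- matrix(1, 6, 2)
  rownames(z) <- sprintf("g%d", 1:6)
  ds <- density_stats(z, d_c = 0.5)
  expect_equal(ds$stats$delta, rep(0, 6))
  expect_true(is.na(ds$stats$nearest_higher[1]))   # stable representative
  expect_false(anyNA(ds$stats$nearest_higher[-1]))
})

test_that("rho is invariant under gene reordering", {
  z <- two_blob_profiles(seed = 22)
  perm <- sample(nrow(z))
  r1 <- density_stats(z, d_c = 1)$stats
  r2 <- density_stats(z[perm, ], d_c = 1)$stats
  expect_equal(r2$rho[match(r1$gene, r2$gene)], r1$rho, tolerance = 1e-12)
})

test_that("K equal to gene count makes every gene a cluster", {
  set.seed(23)
  z <- matrix(rnorm(30), 15, 2)
  rownames(z) <- sprintf("g%02d", 1:15)
  ds <- density_stats(z, d_c = 0.8)
  asg <- assign_clusters(ds, K = 15)
  expect_equal(length(unique(asg$cluster)), 15)
  expect_error(assign_clusters(density_stats(matrix(1, 4, 2,
    dimnames = list(letters[1:4], NULL)), d_c = 1), K = 3), "distinct gamma")
})

test_that("halo exclusion flags a lone midpoint and is idempotent", {
  set.seed(24)
  blob <- function(cx, n) cbind(rnorm(n, cx, 0.05), rnorm(n, 0, 0.05))
  z <- rbind(blob(0, 50), blob(2.4, 50), c(1.2, 0))
  rownames(z) <- sprintf("g%03d", 1:101)
  ds <- density_stats(z, d_c = 1.3)
  asg <- assign_clusters(ds, K = 2)
  h1 <- exclude_halo(asg, ds)
  expect_true(h1$is_halo[101])
  expect_equal(exclude_halo(h1, ds)$is_halo, h1$is_halo)
  # fully separated tight blobs with small d_c: no halo at all
  z2 <- two_blob_profiles(seed = 25)
  ds2 <- density_stats(z2, d_c = 1)
  h2 <- exclude_halo(assign_clusters(ds2, K = 2), ds2)
  expect_equal(sum(h2$is_halo), 0)
})

test_that("compactness is 1 for identical members and NA when degenerate", {
  z <- rbind(matrix(rep(c(1, 0, -1), 4), 4, 3, byrow = TRUE),
             matrix(c(1, 0, -1, -1, 0, 1), 2, 3, byrow = TRUE))
  rownames(z) <- sprintf("g%d", 1:6)
  asg <- data.frame(gene = rownames(z),
                    cluster = rep(c("1", "2"), c(4, 2)),
                    is_center = FALSE, is_halo = FALSE)
  comp <- compactness(asg, z)
  expect_equal(comp$summary$compactness[comp$summary$cluster == "1"], 1)
  # cluster 2 members are +v and -v: mean profile is 0, degenerate
  expect_true(is.na(comp$summary$compactness[comp$summary$cluster == "2"]))
  single <- data.frame(gene = "g1", cluster = "1", is_center = TRUE,
                       is_halo = FALSE)
  expect_true(is.na(compactness(single, z)$summary$compactness))
})

test_that("archetype clusters at noise sd 0.2 are compact and recoverable", {
  cfg <- sim_config(n_genes = 400, n_clusters = 4, profile_noise_sd = 0.2,
                    noise_gene_frac = 0, seed = 26L)
  pr <- simulate_profiles(cfg)
  ds <- density_stats(pr$z)
  asg <- exclude_halo(assign_clusters(ds, K = 4), ds)
  comp <- compactness(asg, pr$z)
  expect_true(all(comp$summary$compactness > 0.9))
  core <- asg[!asg$is_halo, ]
  expect_gte(adjusted_rand_index(pr$truth$cluster_of_gene[core$gene],
                                 core$cluster), 0.9)
  # recovered mean profiles correlate with generating archetypes
  best <- apply(cor(t(comp$mean_profiles), t(pr$truth$archetypes)), 2, max)
  expect_true(all(best > 0.95))
})

test_that("cluster condition shifts are plain member means with a star gate", {
  set.seed(27)
  de <- list(
    A = data.frame(feature = sprintf("g%d", 1:6), log2FC = c(1, 1, 1, 5, 5, 5),
                   padj = c(0.01, 0.01, 0.5, 0.5, 0.5, 0.5)),
    B = data.frame(feature = sprintf("g%d", 1:6), log2FC = c(1, -1, 1, -1, 1, -1),
                   padj = rep(0.001, 6)))
  out <- cluster_condition_shift(sprintf("g%d", 1:3), de)
  expect_equal(out$mean_log2FC[out$stromal_type == "A"], 1)
  expect_true(out$starred[out$stromal_type == "A"])  # 2/3 pass the gate
  expect_equal(out$mean_log2FC[out$stromal_type == "B"],
               mean(c(1, -1, 1)))
  # brute-force mean on random tables
  genes <- sprintf("g%d", sample(1:6, 4))
  got <- cluster_condition_shift(genes, de)
  for (ty in c("A", "B")) {
    sub <- de[[ty]][de[[ty]]$feature %in% genes, ]
    expect_equal(got$mean_log2FC[got$stromal_type == ty], mean(sub$log2FC))
  }
})

test_that("cluster annotation matches the closed-form hypergeometric tail", {
  universe <- sprintf("G%02d", 1:40)
  sets <- list(S1 = universe[1:10], S2 = universe[11:30])
  asg <- data.frame(gene = universe[1:10], cluster = "1",
                    is_center = FALSE, is_halo = FALSE)
  ann <- annotate_clusters(asg, sets, universe)
  # cluster == S1 exactly: p = P[X >= 10] drawing 10 from 10/40
  expect_equal(ann$p[ann$set == "S1"],
               phyper(9, 10, 30, 10, lower.tail = FALSE))
  expect_equal(ann$overlap[ann$set == "S2"], 0)
  expect_gt(ann$p[ann$set == "S2"], 0.99)
  expect_warning(annotate_clusters(asg, c(sets, list(S3 = "ZZZ")), universe),
                 "disjoint")
})
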