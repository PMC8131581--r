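test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_genes = 150, n_proteins = 40, replicates_per_group = 2,
                    n_clusters = 4, n_coherent_pairs = 10, seed = 9L)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth$pattern_of_gene, b$truth$pattern_of_gene)
  sa <- simulate_secretome(cfg, a$truth)
  sb <- simulate_secretome(cfg, b$truth)
  expect_identical(sa$intensities, sb$intensities)
  expect_identical(sa$lr_pairs, sb$lr_pairs)
})

test_that("config validation rejects bad dimensions", {
  expect_error(sim_config(n_genes = 0), "positive integer")
  expect_error(sim_config(n_genes = 10.5), "positive integer")
  expect_error(sim_config(replicates_per_group = 1), ">= 2")
  expect_error(sim_config(n_genes = 5, n_clusters = 10), "<= n_genes")
  expect_error(sim_config(effect_size_lfc = Inf), "finite")
})

test_that("archetype profiles are z-scored and separable", {
  for (seed in 1:3) {
    set.seed(seed)
    A <- archetype_profiles(8, 7)
    expect_equal(unname(rowMeans(A)), rep(0, 8), tolerance = 1e-10)
    expect_equal(unname(apply(A, 1, sd)), rep(1, 8), tolerance = 1e-10)
    cors <- cor(t(A))
    expect_lt(max(abs(cors[upper.tri(cors)])), 0.5)
  }
})

test_that("simulated counts follow the NB mean-variance law", {
  cfg <- sim_config(n_genes = 2000, n_proteins = 10, n_clusters = 2,
                    stromal_types = c("A", "B", "C"),
                    replicates_per_group = 30,
                    conditions = "ctrl", dispersion = 0.05, seed = 4L)
  sim <- simulate_counts(cfg)
  norm <- sweep(sim$counts, 2, sim$truth$size_factors, "/")
  inv_s_bar <- mean(1 / sim$truth$size_factors)
  ratios <- c()
  for (ty in c("A", "B", "C")) {
    cols <- sim$meta$sample_id[sim$meta$stromal_type == ty]
    m <- rowMeans(norm[, cols])
    v <- apply(norm[, cols], 1, var)
    pred <- m * inv_s_bar + cfg$dispersion * m^2
    ratios <- c(ratios, v / pred)
  }
  expect_lt(abs(median(ratios) - 1), 0.1)
})

test_that("dispersion zero gives Poisson-like counts", {
  cfg <- sim_config(n_genes = 1000, n_proteins = 10, n_clusters = 2,
                    stromal_types = c("A", "B", "C"),
                    replicates_per_group = 30,
                    conditions = "ctrl", dispersion = 0, seed = 5L)
  sim <- simulate_counts(cfg)
  norm <- sweep(sim$counts, 2, sim$truth$size_factors, "/")
  cols <- sim$meta$sample_id[sim$meta$stromal_type == "A"]
  m <- rowMeans(norm[, cols])
  v <- apply(norm[, cols], 1, var)
  # Var(c/s) = mu * E[1/s] for Poisson counts
  expect_lt(abs(median(v / m) / mean(1 / sim$truth$size_factors) - 1), 0.15)
})

test_that("null simulation keeps conditions exchangeable", {
  cfg <- sim_config(n_genes = 600, n_proteins = 10, effect_size_lfc = 0,
                    seed = 6L)
  sim <- simulate_counts(cfg)
  m <- sim$meta[sim$meta$stromal_type == "CD31", ]
  de <- nb_wald_test(sim$counts[, m$sample_id], m, c("AML", "ctrl"),
                     prior_df = Inf)
  expect_lt(mean(de$p < 0.05, na.rm = TRUE), 0.1)
  expect_gt(mean(de$p < 0.05, na.rm = TRUE), 0.005)
})

test_that("forced coherence: all planted pairs survive the filter", {
  cfg <- sim_config(n_genes = 500, n_proteins = 120, n_coherent_pairs = 25,
                    seed = 7L)
  sim <- simulate_counts(cfg)
  sec <- simulate_secretome(cfg, sim$truth)
  calls <- perfect_calls(sec$truth)
  edges <- build_edges(calls$secretome, calls$stromal, sec$lr_pairs)
  coh <- coherence_filter(edges)
  truth_keys <- with(sec$truth$true_coherent_pairs,
                     paste(stromal_type, ligand, receptor))
  found_keys <- with(coh, paste(stromal_type, ligand, receptor))
  expect_true(all(truth_keys %in% found_keys))
  expect_gte(nrow(sec$truth$true_coherent_pairs), cfg$n_coherent_pairs)
})

test_that("null secretome shift gives uniform moderated-t p-values", {
  cfg <- sim_config(n_genes = 200, n_proteins = 500, effect_size_lfc = 0,
                    seed = 8L)
  sim <- simulate_counts(cfg)
  sec <- simulate_secretome(cfg, sim$truth)
  qn <- quantile_normalize(log2(sec$intensities))
  mt <- moderated_t(qn, sec$meta, c("AML", "ctrl"))
  ks <- suppressWarnings(ks.test(mt$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
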