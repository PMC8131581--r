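test_that("BH adjustment matches hand computation and the oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  p_na <- c(0.01, NA, 0.5)
  got <- bh_adjust(p_na)
  expect_true(is.na(got[2]))
  expect_equal(got[c(1, 3)], bf_bh(c(0.01, 0.5)))
  set.seed(10)
  for (i in 1:200) {
    n <- sample(1:40, 1)
    p <- round(runif(n), sample(1:3, 1))   # rounding forces ties
    expect_equal(bh_adjust(p), bf_bh(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("BH output is monotone in rank, capped, and never below p", {
  set.seed(11)
  for (i in 1:20) {
    p <- runif(30)
    adj <- bh_adjust(p)
    expect_true(all(adj <= 1))
    expect_true(all(adj >= p))
    expect_false(is.unsorted(adj[order(p)]))
    # re-adjusting can only move values up (it is not idempotent in
    # general: p = c(0.1, 0.5) adjusts to (0.2, 0.5), then (0.4, 0.5))
    expect_true(all(bh_adjust(adj) >= adj - 1e-12))
  }
})

test_that("identical groups give log2FC 0 and p 1", {
  m <- rand_counts(30, 3, seed = 12)
  cts <- cbind(m, m)
  colnames(cts) <- sprintf("s%02d", 1:6)
  meta <- two_group_meta(3)
  de <- nb_wald_test(cts, meta, c("AML", "ctrl"),
                     factors = setNames(rep(1, 6), colnames(cts)))
  expect_equal(de$log2FC, rep(0, 30), tolerance = 1e-6)
  expect_equal(de$p, rep(1, 30), tolerance = 1e-5)
})

test_that("Wald statistic sign always equals log2FC sign", {
  set.seed(13)
  cts <- rand_counts(80, 10, mu = 40, size = 4)
  meta <- two_group_meta(5)
  de <- nb_wald_test(cts, meta, c("AML", "ctrl"))
  nz <- !is.na(de$wald_stat) & de$log2FC != 0
  expect_true(all(sign(de$wald_stat[nz]) == sign(de$log2FC[nz])))
})

test_that("true log2FC of 2 is recovered within 0.2 on average", {
  set.seed(14)
  n <- 5
  cts <- cbind(matrix(rnbinom(500 * n, mu = 400, size = 20), 500),
               matrix(rnbinom(500 * n, mu = 100, size = 20), 500))
  dimnames(cts) <- list(sprintf("g%d", 1:500), sprintf("s%02d", 1:(2 * n)))
  meta <- two_group_meta(n)
  de <- nb_wald_test(cts, meta, c("AML", "ctrl"),
                     factors = setNames(rep(1, 2 * n), colnames(cts)))
  expect_lt(abs(mean(de$log2FC) - 2), 0.2)
})

test_that("a group of all zeros is flagged and still reported", {
  cts <- rand_counts(10, 8, seed = 15)
  cts[1, 1:4] <- 0L
  meta <- two_group_meta(4)
  de <- nb_wald_test(cts, meta, c("AML", "ctrl"))
  expect_match(de$flag[1], "zero_group")
  expect_true(is.finite(de$log2FC[1]))
  expect_lt(de$log2FC[1], 0)
})

test_that("Poisson data matches a quasi-Poisson GLM oracle's rejection rate", {
  set.seed(16)
  n <- 8
  cts <- matrix(rpois(400 * 2 * n, 100), 400)
  dimnames(cts) <- list(sprintf("g%d", 1:400), sprintf("s%02d", 1:(2 * n)))
  meta <- two_group_meta(n)
  de <- nb_wald_test(cts, meta, c("AML", "ctrl"), prior_df = Inf,
                     factors = setNames(rep(1, 2 * n), colnames(cts)))
  x <- rep(c(1, 0), each = n)
  p_oracle <- apply(cts, 1, function(y) {
    fit <- glm(y ~ x, family = quasipoisson())
    summary(fit)$coefficients[2, 4]
  })
  expect_lt(abs(mean(de$p < 0.05) - mean(p_oracle < 0.05)), 0.04)
})

test_that("cluster-gene selection unions pairwise hits and checks contrasts", {
  mk <- function(genes, padj) data.frame(feature = genes, padj = padj,
                                         stringsAsFactors = FALSE)
  pw <- list("A_vs_B" = mk(c("g1", "g2"), c(0.01, 0.9)),
             "A_vs_C" = mk(c("g1", "g2"), c(0.9, 0.9)),
             "B_vs_C" = mk(c("g1", "g3"), c(0.9, 0.04)))
  expect_identical(select_cluster_genes(pw, types = c("A", "B", "C")),
                   c("g1", "g3"))
  expect_identical(select_cluster_genes(rev(pw)),
                   select_cluster_genes(pw))
  expect_error(select_cluster_genes(pw[-2], types = c("A", "B", "C")),
               "A vs C")
  none <- lapply(pw, function(d) { d$padj <- 1; d })
  expect_length(select_cluster_genes(none), 0)
})

test_that("deregulation overlap proportions are plain set arithmetic", {
  late <- sprintf("g%d", 1:10)
  expect_equal(unname(deregulation_overlap(late, list(e = sprintf("g%d", 1:20)))), 1)
  expect_equal(unname(deregulation_overlap(late, list(e = "x1"))), 0)
  expect_equal(unname(deregulation_overlap(late, list(e = sprintf("g%d", 7:30)))), 0.4)
  expect_error(deregulation_overlap(character(0), list(e = "g1")), "empty")
})
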