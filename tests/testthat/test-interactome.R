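mini_de <- function(features, calls) {
  data.frame(feature = features, call = calls, stringsAsFactors = FALSE)
}

test_that("edges carry directions and the coherence flag", {
  sec <- mini_de(c("L1", "L2"), c("up", "up"))
  de <- list(T1 = mini_de(c("R1", "R2"), c("up", "down")))
  pairs <- data.frame(ligand = c("L1", "L2"), receptor = c("R1", "R2"),
                      pathway = NA)
  edges <- build_edges(sec, de, pairs)
  expect_equal(nrow(edges), 2)
  e1 <- edges[edges$receptor == "R1", ]
  expect_true(e1$coherent)
  expect_identical(c(e1$ligand_dir, e1$receptor_dir), c("up", "up"))
  expect_false(edges$coherent[edges$receptor == "R2"])
  expect_error(build_edges(sec, de, pairs[0, ]), "empty")
})

test_that("non-significant partners never produce edges", {
  sec <- mini_de(c("L1", "L2"), c("ns", "down"))
  de <- list(T1 = mini_de(c("R1", "R2"), c("up", "ns")))
  pairs <- data.frame(ligand = c("L1", "L2"), receptor = c("R1", "R2"))
  edges <- build_edges(sec, de, pairs)
  expect_equal(nrow(edges), 0)
})

test_that("build_edges matches the nested-loop oracle on random instances", {
  set.seed(50)
  for (i in 1:30) {
    nl <- sample(4:10, 1); nr <- sample(4:10, 1)
    lig <- sprintf("L%d", 1:nl); rec <- sprintf("R%d", 1:nr)
    sec <- mini_de(lig, sample(c("up", "down", "ns"), nl, replace = TRUE))
    de <- lapply(1:3, function(t) {
      mini_de(rec, sample(c("up", "down", "ns"), nr, replace = TRUE))
    })
    names(de) <- sprintf("T%d", 1:3)
    pairs <- unique(data.frame(
      ligand = sample(lig, 12, replace = TRUE),
      receptor = sample(rec, 12, replace = TRUE)))
    got <- build_edges(sec, de, pairs)
    want <- bf_build_edges(sec, de, pairs)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      key <- function(d) sort(paste(d$stromal_type, d$ligand, d$receptor,
                                    d$coherent))
      expect_identical(key(got), key(want))
    }
    # coherence filter preserves per-(type, direction) counts vs oracle
    if (!is.null(want)) {
      coh <- coherence_filter(got)
      want_coh <- want[want$coherent, ]
      expect_equal(unname(table(coh$stromal_type, coh$ligand_dir)),
                   unname(table(want_coh$stromal_type, want_coh$ligand_dir)))
    }
  }
})

test_that("coherence filter is idempotent and can empty the edge set", {
  sec <- mini_de("L1", "up")
  de <- list(T1 = mini_de("R1", "down"))
  pairs <- data.frame(ligand = "L1", receptor = "R1")
  edges <- build_edges(sec, de, pairs)
  coh <- coherence_filter(edges)
  expect_equal(nrow(coh), 0)
  d2 <- coherence_filter(coherence_filter(build_edges(
    mini_de("L1", "up"), list(T1 = mini_de("R1", "up")), pairs)))
  expect_equal(nrow(d2), 1)
})

test_that("graph collapse conserves weight and stays bipartite", {
  edges <- data.frame(
    stromal_type = c("T1", "T1", "T1", "T2"),
    ligand = c("L1", "L2", "L3", "L1"), ligand_dir = "up",
    receptor = c("R1", "R2", "R3", "R1"), receptor_dir = "up",
    coherent = TRUE, pathway = c("PW1", "PW1", "PW1", "PW2"),
    stringsAsFactors = FALSE)
  g <- build_graph(edges, group_by = "pathway")
  expect_equal(g$edges$weight[g$edges$source == "T1" &
                              g$edges$target == "PW1"], 3)
  expect_equal(sum(g$edges$weight), nrow(edges))
  types <- g$nodes$name[g$nodes$side == "stromal"]
  expect_true(all(g$edges$source %in% types))
  expect_false(any(g$edges$target %in% types))
  # node degree equals the sum of incident weights
  expect_equal(g$nodes$degree[g$nodes$name == "T1"], 3)
  gp <- build_graph(edges, group_by = "pair")
  expect_equal(sum(gp$edges$weight), nrow(edges))
  expect_equal(nrow(gp$edges), 4)
})

test_that("protein-to-gene mapping is applied before matching", {
  sec <- mini_de("PROT1", "up")
  de <- list(T1 = mini_de("GENE1", "up"))
  pairs <- data.frame(ligand = "GENE1", receptor = "GENE1")
  pmap <- c(PROT1 = "GENE1")
  edges <- build_edges(sec, de, pairs, protein_map = pmap)
  expect_equal(nrow(edges), 1)
  expect_true(edges$coherent)
})
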