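# Ligand-receptor interactome: join significant secretome proteins
# (ligands) with significant stromal genes (receptors) through a pair
# table, flag coherence, and collapse to a weighted bipartite graph.

#' Build per-stromal-type ligand-receptor edges
#'
#' For each stromal type and each pair whose ligand is a significant
#' secretome protein and whose receptor is a significant gene in that
#' type (call != "ns" in both tables), emits an edge carrying both
#' directions and the coherence flag (coherent iff the directions
#' agree). Matching is exact on normalized (uppercased) symbols after
#' the optional protein-to-gene mapping.
#'
#' @param secretome_de secretome DE table from [moderated_t()].
#' @param stromal_de named list of per-type transcriptome DE tables.
#' @param pairs ligand-receptor table (columns ligand, receptor,
#'   optional pathway).
#' @param protein_map optional named vector translating protein symbols
#'   to gene symbols before matching.
#' @return data.frame (stromal_type, ligand, ligand_dir, receptor,
#'   receptor_dir, coherent, pathway).
#' @export
build_edges <- function(secretome_de, stromal_de, pairs, protein_map = NULL) {
  if (is.null(pairs) || !nrow(pairs)) stopf("empty ligand-receptor table")
  lig <- norm_symbol(pairs$ligand)
  if (!is.null(protein_map)) {
    mapped <- unname(protein_map[lig])
    lig <- ifelse(is.na(mapped), lig, mapped)
  }
  rec <- norm_symbol(pairs$receptor)
  pw <- if (!is.null(pairs$pathway)) as.character(pairs$pathway)
        else rep(NA_character_, nrow(pairs))

  sec_sym <- norm_symbol(secretome_de$feature)
  if (!is.null(protein_map)) {
    mapped <- unname(protein_map[sec_sym])
    sec_sym <- ifelse(is.na(mapped), sec_sym, mapped)
  }
  sec_dir <- stats::setNames(secretome_de$call, sec_sym)
  sec_dir <- sec_dir[sec_dir != "ns"]
  unmatched <- sum(!lig %in% sec_sym)
  if (unmatched) {
    message(sprintf("build_edges: %d pair ligand(s) absent from the secretome",
                    unmatched))
  }
  rows <- list()
  for (ty in names(stromal_de)) {
    de <- stromal_de[[ty]]
    gene_dir <- stats::setNames(de$call, norm_symbol(de$feature))
    gene_dir <- gene_dir[gene_dir != "ns"]
    hit <- lig %in% names(sec_dir) & rec %in% names(gene_dir)
    if (!any(hit)) next
    ld <- unname(sec_dir[lig[hit]])
    rd <- unname(gene_dir[rec[hit]])
    rows[[ty]] <- data.frame(
      stromal_type = ty, ligand = lig[hit], ligand_dir = ld,
      receptor = rec[hit], receptor_dir = rd, coherent = ld == rd,
      pathway = pw[hit], stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(stromal_type = character(), ligand = character(),
                      ligand_dir = character(), receptor = character(),
                      receptor_dir = character(), coherent = logical(),
                      pathway = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Keep only coherently deregulated edges
#'
#' @param edges edge table from [build_edges()].
#' @return The coherent subset (ligand and receptor moving in the same
#'   direction); idempotent.
#' @export
coherence_filter <- function(edges) {
  out <- edges[edges$coherent, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse ligand-receptor edges into a weighted bipartite graph
#'
#' Nodes are the stromal types on one side and grouping units (pathways,
#' or ligand:receptor pairs when no pathway grouping is requested) on
#' the other; the weight of a graph edge is the number of interactome
#' edges it collapses, and each node records its total connection count
#' for size scaling.
#'
#' @param edges (typically coherence-filtered) edge table.
#' @param group_by "pathway" or "pair".
#' @return Object of class `bm_graph`: `nodes` (name, side, degree) and
#'   `edges` (source = stromal type, target = unit, weight).
#' @export
build_graph <- function(edges, group_by = c("pair", "pathway")) {
  group_by <- match.arg(group_by)
  if (!nrow(edges)) stopf("no edges to build a graph from")
  unit <- if (group_by == "pathway") {
    if (all(is.na(edges$pathway))) {
      stopf("pathway grouping requested but no pathway labels present")
    }
    ifelse(is.na(edges$pathway), "unannotated", edges$pathway)
  } else {
    paste(edges$ligand, edges$receptor, sep = ":")
  }
  agg <- stats::aggregate(list(weight = rep(1L, nrow(edges))),
                          by = list(source = edges$stromal_type,
                                    target = unit), FUN = sum)
  agg <- agg[order(agg$source, agg$target), , drop = FALSE]
  rownames(agg) <- NULL
  deg <- c(tapply(agg$weight, agg$source, sum),
           tapply(agg$weight, agg$target, sum))
  nodes <- data.frame(
    name = c(unique(agg$source), unique(agg$target)),
    side = c(rep("stromal", length(unique(agg$source))),
             rep(group_by, length(unique(agg$target)))),
    stringsAsFactors = FALSE)
  nodes$degree <- as.numeric(deg[nodes$name])
  structure(list(nodes = nodes, edges = agg, group_by = group_by),
            class = "bm_graph")
}

#' Convert a `bm_graph` to an igraph object
#'
#' @param graph a `bm_graph`.
#' @return An undirected weighted igraph graph with node attribute
#'   `side`.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "bm_graph"))
  g <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                     vertices = graph$nodes)
  g
}
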