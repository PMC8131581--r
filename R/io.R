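# Readers and writers for the pipeline's tabular formats. TSV is the
# canonical dialect; '#'-prefixed lines are comments; a ragged row is
# always an error, never padded.

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]
  if (!length(lines)) stopf("%s: no non-comment content", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    stopf("%s: row %d has %d fields, expected %d (truncated or ragged file)",
          path, bad, nf[bad], nf[1])
  }
  header <- fields[[1]]
  if (length(fields) == 1L) {
    df <- as.data.frame(matrix(character(0), 0, length(header)),
                        stringsAsFactors = FALSE)
  } else {
    body <- do.call(rbind, fields[-1])
    df <- as.data.frame(body, stringsAsFactors = FALSE)
  }
  names(df) <- header
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Read a gene-by-sample count matrix
#'
#' Expects a TSV whose first column holds gene identifiers and whose
#' remaining columns hold non-negative integer counts, one per sample.
#'
#' @param path TSV file path.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 2L) stopf("%s: need a gene-id column plus >=1 sample", path)
  genes <- df[[1]]
  if (anyDuplicated(genes)) {
    stopf("%s: duplicate gene id '%s'", path, genes[duplicated(genes)][1])
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                 dimnames = list(genes, colnames(m))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stopf("%s: non-numeric count at gene '%s', sample '%s'",
          path, genes[bad[1]], colnames(num)[bad[2]])
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1, ]
    stopf("%s: negative count at gene '%s', sample '%s'",
          path, genes[bad[1]], colnames(num)[bad[2]])
  }
  if (any(num != round(num))) {
    bad <- which(num != round(num), arr.ind = TRUE)[1, ]
    stopf("%s: non-integer count at gene '%s', sample '%s'",
          path, genes[bad[1]], colnames(num)[bad[2]])
  }
  storage.mode(num) <- "integer"
  num
}

#' Write a count (or numeric) matrix as TSV
#'
#' @param counts matrix with rownames (feature ids) and colnames (samples).
#' @param path output TSV path.
#' @param id_col header of the identifier column.
#' @export
write_counts <- function(counts, path, id_col = "gene") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
  invisible(path)
}

#' Read sample metadata
#'
#' Requires columns sample_id, stromal_type, condition (ctrl/CB/AML) and
#' replicate; sample ids must be unique. If `counts` is supplied, every
#' counts column must have a metadata row.
#'
#' @param path TSV file path.
#' @param counts optional count matrix to validate against.
#' @return data.frame of sample metadata.
#' @export
read_metadata <- function(path, counts = NULL) {
  df <- read_tsv_strict(path)
  need <- c("sample_id", "stromal_type", "condition", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing metadata column(s): %s",
                          path, paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) {
    stopf("%s: duplicate sample_id '%s'", path,
          df$sample_id[duplicated(df$sample_id)][1])
  }
  bad <- setdiff(unique(df$condition), c("ctrl", "CB", "AML"))
  if (length(bad)) stopf("%s: unknown condition value(s): %s", path,
                         paste(bad, collapse = ", "))
  df$replicate <- as.integer(df$replicate)
  if (!is.null(counts)) {
    orphan <- setdiff(colnames(counts), df$sample_id)
    if (length(orphan)) stopf("counts column(s) without metadata: %s",
                              paste(orphan, collapse = ", "))
  }
  df
}

#' Read a ligand-receptor pair table
#'
#' Columns: ligand, receptor, optional pathway. Symbols are uppercased;
#' duplicate (ligand, receptor) rows after normalization are dropped with
#' a warning.
#'
#' @param path TSV file path.
#' @return data.frame with columns ligand, receptor, pathway.
#' @export
read_lr_pairs <- function(path) {
  df <- read_tsv_strict(path)
  need <- c("ligand", "receptor")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing column(s): %s", path,
                          paste(miss, collapse = ", "))
  df$ligand <- norm_symbol(df$ligand)
  df$receptor <- norm_symbol(df$receptor)
  if (is.null(df$pathway)) df$pathway <- NA_character_
  dup <- duplicated(df[, c("ligand", "receptor")])
  if (any(dup)) {
    warnf("%s: dropping %d duplicate ligand-receptor pair(s)", path, sum(dup))
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df[, c("ligand", "receptor", "pathway")]
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member symbols, tab
#' separated. Symbols are uppercased; an empty set is an error.
#'
#' @param path GMT file path.
#' @return Named list of uppercase symbol vectors; descriptions attached
#'   as the "description" attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- list()
  descs <- character(0)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L) stopf("%s: line %d defines an empty set '%s'",
                              path, i, f[1])
    sets[[f[1]]] <- unique(norm_symbol(f[-(1:2)]))
    descs[f[1]] <- f[2]
  }
  if (anyDuplicated(names(sets))) stopf("%s: duplicate set names", path)
  attr(sets, "description") <- descs
  sets
}

#' Read an optional protein-to-gene symbol mapping
#'
#' Two-column TSV (protein, gene) used to translate secretome protein
#' names to gene symbols before ligand-receptor matching.
#'
#' @param path TSV file path.
#' @return Named character vector (names = protein symbols, values = gene
#'   symbols), both uppercased.
#' @export
read_symbol_map <- function(path) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 2L) stopf("%s: need two columns (protein, gene)", path)
  stats::setNames(norm_symbol(df[[2]]), norm_symbol(df[[1]]))
}

#' Write a bipartite interaction graph
#'
#' Writes the edge list as TSV (source, target, weight) and, optionally,
#' GraphML via igraph for downstream tools.
#'
#' @param graph a `bm_graph` from [build_graph()].
#' @param path edge-list TSV path.
#' @param graphml_path optional GraphML output path.
#' @return `path`, invisibly.
#' @export
write_graph_files <- function(graph, path, graphml_path = NULL) {
  stopifnot(inherits(graph, "bm_graph"))
  write_tsv(graph$edges, path)
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(graph), graphml_path, format = "graphml")
  }
  invisible(path)
}
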