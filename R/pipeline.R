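# End-to-end orchestration over synthetic inputs, plus a small CLI.
# Every stage logs its parameters; a single JSON configuration file can
# drive all stages through the CLI.

#' Write all simulated pipeline inputs to a directory
#'
#' Emits counts.tsv, meta.tsv, secretome.tsv, secretome_meta.tsv,
#' lr_pairs.tsv and ground-truth TSVs (cluster and pattern per gene,
#' protein shifts, true coherent pairs).
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created if absent).
#' @return Invisibly, the list of simulated objects.
#' @export
write_simulation <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_counts(cfg)
  sec <- simulate_secretome(cfg, sim$truth)
  write_counts(sim$counts, file.path(outdir, "counts.tsv"))
  write_tsv(sim$meta, file.path(outdir, "meta.tsv"))
  write_counts(sec$intensities, file.path(outdir, "secretome.tsv"),
               id_col = "protein")
  write_tsv(sec$meta, file.path(outdir, "secretome_meta.tsv"))
  write_tsv(sec$lr_pairs, file.path(outdir, "lr_pairs.tsv"))
  truth_genes <- data.frame(
    gene = names(sim$truth$cluster_of_gene),
    cluster = unname(sim$truth$cluster_of_gene),
    pattern = apply(sim$truth$pattern_of_gene, 1L, paste, collapse = ","),
    stringsAsFactors = FALSE)
  write_tsv(truth_genes, file.path(outdir, "truth_genes.tsv"))
  write_tsv(data.frame(protein = names(sec$truth$protein_shift),
                       shift_log2 = unname(sec$truth$protein_shift),
                       stringsAsFactors = FALSE),
            file.path(outdir, "truth_proteins.tsv"))
  write_tsv(sec$truth$true_coherent_pairs,
            file.path(outdir, "truth_coherent_pairs.tsv"))
  invisible(list(sim = sim, sec = sec))
}

#' Run the whole pipeline on synthetic data
#'
#' simulate -> normalize -> condition DE per stromal type -> pairwise
#' stromal DE -> gene selection -> z-profiles (ctrl) -> density-peak
#' clustering -> ternary patterns + mixture fit -> secretome
#' normalization + moderated t -> interactome + coherence filter ->
#' bipartite graph -> force layout. All outputs are TSV files under
#' `outdir`; the run is fully determined by `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory.
#' @param fdr condition-contrast FDR threshold (default 0.1).
#' @param pairwise_fdr pairwise stromal selection threshold (default
#'   0.05).
#' @param K cluster count for density-peak clustering (default
#'   `cfg$n_clusters`).
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(cfg, outdir, fdr = 0.1, pairwise_fdr = 0.05,
                         K = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  message(sprintf("run_pipeline: seed=%d fdr=%.3g outdir=%s",
                  cfg$seed, fdr, outdir))
  objs <- write_simulation(cfg, outdir)
  sim <- objs$sim; sec <- objs$sec

  sf <- size_factors(sim$counts)
  write_tsv(data.frame(sample_id = names(sf), size_factor = sf,
                       stringsAsFactors = FALSE),
            file.path(outdir, "size_factors.tsv"))
  expr <- regularized_log(sim$counts, sf)
  write_counts(round(expr, 6), file.path(outdir, "normexpr.tsv"))
  write_counts(round(sample_correlation(expr), 6),
               file.path(outdir, "sample_correlation.tsv"),
               id_col = "sample")

  de_cond <- de_condition_per_type(sim$counts, sim$meta, q = fdr)
  for (ty in names(de_cond)) {
    write_tsv(de_cond[[ty]], file.path(outdir, sprintf("de_AML_vs_ctrl_%s.tsv", ty)))
  }
  de_pw <- de_pairwise_types(sim$counts, sim$meta, q = pairwise_fdr)
  selected <- select_cluster_genes(de_pw, threshold = pairwise_fdr,
                                   types = cfg$stromal_types)
  writeLines(selected, file.path(outdir, "selected_genes.txt"))

  zp <- z_profiles(expr, sim$meta, condition = "ctrl")
  zsel <- zp$z[intersect(selected, rownames(zp$z)[!zp$flat]), , drop = FALSE]
  clu <- NULL
  if (nrow(zsel) >= 2L) {
    ds <- density_stats(zsel)
    asg <- assign_clusters(ds, K = if (is.null(K)) cfg$n_clusters else K)
    asg <- exclude_halo(asg, ds)
    comp <- compactness(asg, zsel)
    write_tsv(ds$stats, file.path(outdir, "density_stats.tsv"))
    write_tsv(asg, file.path(outdir, "clusters.tsv"))
    write_tsv(comp$summary, file.path(outdir, "cluster_summary.tsv"))
    clu <- list(stats = ds, assign = asg, compactness = comp)
  }

  Y <- ternarize(de_cond, q = fdr)
  pm <- fit_pattern_model(Y, M_max = cfg$n_patterns + 2L,
                          eps_init = cfg$noise_eps, seed = cfg$seed)
  write_tsv(data.frame(gene = rownames(Y),
                       pattern = apply(Y, 1L, paste, collapse = ","),
                       component = unname(pm$assignment[rownames(Y)]),
                       stringsAsFactors = FALSE),
            file.path(outdir, "patterns.tsv"))
  write_tsv(pattern_sharing(pm), file.path(outdir, "pattern_sharing.tsv"))

  qn <- quantile_normalize(log2(sec$intensities))
  sec_de <- moderated_t(qn, sec$meta, c("AML", "ctrl"), q = fdr)
  write_tsv(sec_de, file.path(outdir, "secretome_de.tsv"))

  edges <- build_edges(sec_de, de_cond, sec$lr_pairs)
  coh <- coherence_filter(edges)
  write_tsv(edges, file.path(outdir, "edges.tsv"))
  write_tsv(coh, file.path(outdir, "edges_coherent.tsv"))
  coords <- NULL
  if (nrow(coh)) {
    graph <- build_graph(coh, group_by = "pathway")
    write_graph_files(graph, file.path(outdir, "graph_edges.tsv"),
                      file.path(outdir, "graph.graphml"))
    coords <- layout_graph(graph, layout_params(seed = cfg$seed))
    coords$converged <- attr(coords, "converged")
    write_tsv(coords, file.path(outdir, "layout.tsv"))
  }
  invisible(list(sim = sim, sec = sec, size_factors = sf, expr = expr,
                 de_condition = de_cond, de_pairwise = de_pw,
                 selected = selected, clustering = clu, ternary = Y,
                 pattern_model = pm, secretome_de = sec_de, edges = edges,
                 coherent = coh, layout = coords))
}

parse_cli_args <- function(args) {
  opts <- list()
  pos <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        opts[[key]] <- TRUE
        i <- i + 1L
      } else {
        opts[[key]] <- args[i + 1L]
        i <- i + 2L
      }
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }
  list(command = if (length(pos)) pos[1] else NA_character_, opts = opts)
}

cli_config <- function(opts) {
  cfg_args <- list()
  if (!is.null(opts$config)) {
    cfg_args <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
  }
  if (!is.null(opts$seed)) cfg_args$seed <- as.integer(opts$seed)
  do.call(sim_config, cfg_args)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write synthetic inputs), `run-all` (full
#' pipeline). Global flags: `--config cfg.json`, `--seed N`,
#' `--outdir DIR`, `--fdr Q`. Invoke as
#' `Rscript -e 'bmniche::bmniche_cli()' run-all --outdir out --seed 1`.
#'
#' @param args character vector of CLI arguments (defaults to the
#'   command line).
#' @return Invisibly, the result of the subcommand.
#' @export
bmniche_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  parsed <- parse_cli_args(args)
  cmd <- parsed$command
  opts <- parsed$opts
  if (is.na(cmd)) {
    cat("usage: bmniche_cli <simulate|run-all> [--config cfg.json]",
        "[--seed N] [--outdir DIR] [--fdr Q]\n")
    return(invisible(NULL))
  }
  outdir <- if (is.null(opts$outdir)) "bmniche_out" else opts$outdir
  cfg <- cli_config(opts)
  res <- switch(cmd,
    "simulate" = write_simulation(cfg, outdir),
    "run-all" = run_pipeline(cfg, outdir,
                             fdr = if (is.null(opts$fdr)) 0.1
                                   else as.numeric(opts$fdr)),
    stopf("unknown subcommand '%s'", cmd))
  invisible(res)
}
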