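# bmniche

Multi-omics analysis of the bone-marrow (BM) stromal niche under
leukemic stress, packaged as a tested, reusable R pipeline.

The BM niche — endothelial (CD31), mesenchymal (Nes-high, Nes-low,
Ng2) and osteolineage (Osx, Col-low, Col-high) populations — regulates
blood stem cells and is remodeled by acute myeloid leukemia (AML).
Characterizing that remodeling takes several statistical stages that
are usually scattered across scripts. `bmniche` implements them as one
coherent toolkit, exercised end to end on synthetic data with known
ground truth:

* **Normalization** — median-of-ratios size factors
  `s_j = median_g c_gj / geomean_k(c_gk)`, regularized
  `log10(c/s + 1)` expression, z-scored per-population profiles,
  sample correlation matrices.
* **Differential expression** — per-gene two-group negative-binomial
  GLM (log link, size-factor offsets, IRLS), Wald statistic
  `beta / SE(beta)` with normal p-values and Benjamini-Hochberg FDR;
  empirical-Bayes shrinkage of log-dispersions toward the ensemble
  mean (`prior_df`, default 10; `Inf` = common dispersion).
* **Density-peak clustering** of z-profiles — Gaussian-kernel density
  `rho`, distance-to-higher-density `delta`, centers by
  `gamma = rho * delta`, chain assignment, border-density halo (noise)
  exclusion, compactness = mean Pearson correlation of members with
  the cluster mean profile, hypergeometric gene-set annotation.
* **Ternary deregulation patterns** — per-gene vectors over stromal
  types in {-1, 0, +1} (FDR < 0.1 rule), grouped by an EM-fitted
  mixture of ternary prototypes with symmetric flip noise `eps`.
* **Secretome** — quantile normalization, log2, moderated t-statistics
  with Smyth-style variance moderation (inverse-trigamma moment
  matching), BH adjustment.
* **Interactome** — ligand-receptor pairing of significant secretome
  proteins with significant stromal genes per population, coherence
  filter (same direction in both layers), weighted bipartite graph.
* **Layout** — deterministic under-damped force dynamics (spring
  attraction along weighted edges, inverse-square repulsion,
  damping; semi-implicit Euler).
* **Synthetic data** — a generator stating the whole world (7
  populations x ctrl/AML, NB counts with 8 archetype clusters,
  ternary effects as log2 fold-changes, log-normal secretome, planted
  coherent L-R pairs) with every ground-truth assignment recorded.

## Worked example

```r
library(bmniche)

cfg <- sim_config(n_genes = 500, n_proteins = 120, seed = 1)
sim <- simulate_counts(cfg)

sf <- size_factors(sim$counts)
round(head(sf, 4), 3)
#> CD31_ctrl_r1 CD31_ctrl_r2 CD31_ctrl_r3 CD31_ctrl_r4
#>        0.682        1.167        0.769        0.608
```

Per-sample scaling constants; the simulation drew true factors
log-uniformly in [0.5, 2], and these estimates track them.

```r
expr <- regularized_log(sim$counts, sf)
de <- de_condition_per_type(sim$counts, sim$meta)   # AML vs ctrl per type
head(de$NesLow[de$NesLow$padj < 0.1,
               c("feature", "log2FC", "wald_stat", "padj", "call")], 2)
#>     feature    log2FC wald_stat         padj call
#> 193  G00193 0.6506738  3.684022 0.0573955175   up
#> 458  G00458 0.7664252  4.860785 0.0005846061   up
```

Genes deregulated in the Nes-low mesenchymal population at FDR < 0.1.

```r
zp <- z_profiles(expr, sim$meta, condition = "ctrl")
z <- zp$z[!zp$flat & sim$truth$cluster_of_gene != "noise", ]
ds <- density_stats(z)                 # auto bandwidth: 2% neighborhood
asg <- exclude_halo(assign_clusters(ds, K = 8), ds)
comp <- compactness(asg, z)
comp$summary
#>   cluster size compactness
#> 1       1   51   0.9922097
#> 2       2   61   0.9904759
#> ...
#> 8       8   54   0.9844481

core <- asg[!asg$is_halo, ]
adjusted_rand_index(sim$truth$cluster_of_gene[core$gene], core$cluster)
#> [1] 1
```

The eight archetype clusters embedded by the generator are recovered
exactly (adjusted Rand index 1), each highly compact (mean member
correlation with the cluster profile > 0.98).

```r
Y <- ternarize(de)                     # genes x types in {-1, 0, +1}
fit <- fit_pattern_model(Y, M_max = 5, seed = 1)
fit$patterns
#>      CD31 NesHigh NesLow Ng2 Osx ColLow ColHigh
#> [1,]    0       0      0   1   0      1       1
#> [2,]    0      -1      0   0   0      0       0
#> ...
round(fit$weights, 3)
#> [1] 0.114 0.110 0.093 0.102 0.581
```

The mixture recovers the planted deregulation patterns (rows with
non-zero entries; `pattern_sharing()` labels them specific or shared)
plus the null pattern carrying the 58% of genes with no AML effect.

```r
sec <- simulate_secretome(cfg, sim$truth)
sec_de <- moderated_t(quantile_normalize(log2(sec$intensities)),
                      sec$meta, c("AML", "ctrl"))
sum(sec_de$call != "ns")
#> [1] 62

edges <- coherence_filter(build_edges(sec_de, de, sec$lr_pairs))
nrow(edges)
#> [1] 69

g <- build_graph(edges, group_by = "pathway")
lay <- layout_graph(g, layout_params(seed = 1))
attr(lay, "converged")
#> [1] TRUE
```

62 secretome proteins are called deregulated; 69 ligand-receptor edges
are coherently deregulated (ligand and receptor moving the same way in
some stromal population) and collapse into a pathway-level bipartite
graph whose force layout converges to equilibrium coordinates.

The whole pipeline, including writing every table to TSV, is one call
(or `bmniche_cli(c("run-all", "--outdir", "out", "--seed", "1"))` from
the command line):

```r
res <- run_pipeline(cfg, "out/")
```

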