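# stagecluster

Stage-wise differential expression and co-expression clustering for
source–sink transcriptomics of storage-organ development.

Storage-root crops shift carbon between tissues as the root bulks: the
question of *which genes change with developmental stage, in which tissue,
and in which coordinated groups* is answered by a chain of statistics —
normalization, per-tissue stage tests, co-expression graphs, community
detection, profile summaries — plus measurement-side models for sugar and
starch contents and for subcellular compartment fractions. `stagecluster`
implements that chain as a tested R package with a synthetic-data module
that carries full ground truth, so every step can be validated by parameter
recovery instead of by eye.

## The statistics at the core

* **Normalization** — median-of-ratios size factors `s_j` (geometric mean
  anchored to 1) and the transform `v = log2(count/s_j + 1)`.
* **Stage test** — per tissue and gene, a negative-binomial GLM
  (log link, `var = mu + alpha mu^2`, offset `log s_j`) with full model
  `~ stage (+ batch)` against reduced `~ 1 (+ batch)`;
  `LRT = 2(llf − llr) ~ chi²(k−1)`; calls at BH-FDR < 0.001. Dispersions are
  empirical-Bayes moderated: Cox–Reid profile-likelihood genewise estimates
  shrunk toward a parametric `a0 + a1/mu` trend (see the methods vignette
  for why the raw moment estimator cannot keep this test calibrated).
* **Network** — Pearson correlation on scaled profiles; edges where
  `r > t*`, with `t*` the median over 1,000 replications of the 99.995%
  quantile of correlations between independently permuted profiles; nodes
  with fewer than 50 edges removed.
* **Clustering** — Louvain maximization of resolution-scaled modularity
  `Q = Σ_c [e_c/m − γ(d_c/2m)²]` at `γ = 0.75`, with a refinement pass,
  seeded restarts, and an exhaustive Bell-enumeration oracle for graphs of
  ≤ 10 nodes.
* **Summaries** — per-cluster stage z-score profiles, exclusive (UpSet)
  intersection counts across tissues, adjusted Rand index against ground
  truth.
* **Measurements** — Gamma GLM (log link) per tissue × analyte with
  scaled-deviance type-II ANOVA, BH across models, Tukey–Kramer
  studentized-range comparisons on the link scale and insert-and-absorb
  compact letter displays; ordinary linear models for compartment
  fractions.

## Worked example

```r
library(stagecluster)

cfg <- sim_config(n_genes = 1000, tissues = c("SR", "Wood"),
                  modules_per_tissue = 3, module_size = 60,
                  module_fold_change = 4, seed = 42)
sim <- generate_counts(cfg)
sim$counts
#> <count_matrix> 1000 genes x 24 samples
#>   tissues: SR, Wood
#>   stages:  PB, EB, DB

deg <- lrt_stage(sim$counts, tissue = "SR")
sum(deg$is_deg)
#> [1] 180        # the 180 planted module genes, at FDR < 0.001

norm <- transform_counts(sim$counts)
keep <- norm$meta$tissue == "SR"
prof <- scale_profiles(norm$values[deg$gene_id[deg$is_deg], keep])
thr  <- permutation_threshold(prof, replications = 1000, seed = 42)
thr
#> [1] 0.919      # null 99.995% quantile of r at 12 samples

g <- build_graph(prof, thr, min_degree = 20)
part <- louvain(g, resolution = 0.75, seed = 42)
part
#> <partition> 29 nodes in 3 communities, Q = 0.5431 (gamma = 0.75)

truth <- sim$truth$module_membership[names(part$membership), "SR"]
adjusted_rand_index(part$membership, truth)
#> [1] 1          # recovered clusters = planted modules

round(stage_zscore_profiles(norm, part$membership, tissue = "SR")$profile, 2)
#>      PB    EB    DB
#> 0 -0.97 -0.05  1.02   # monotone up through bulking
#> 1  1.05 -0.12 -0.93   # monotone down
#> 2 -0.57  1.15 -0.58   # early-bulking peak
```

The three recovered cluster profiles are the planted stage templates: genes
rising through bulking, genes falling, and an early-bulking peak. With the
default whole-study design (5 tissues × 3 stages × 4 replicates, four
100-gene modules per tissue), `run_pipeline()` chains all stages, writes
every table as TSV plus a checksummed `manifest.json`, and reports the ARI
per tissue when ground truth is supplied.

A command-line wrapper over the same functions ships at
`inst/cli/stagecluster.R`
(`simulate | normalize | deg | network | cluster | profiles | upset | stats | naf | run-all`).

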