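---
title: "Methods: stage-wise differential expression and co-expression clustering"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`stagecluster` re-implements, as a tested and reusable pipeline, the
transcriptome- and measurement-side statistics of a source–sink study of a
storage-root-forming crop: five tissues (source leaf, stem bark, stem wood,
fibrous root, storage root) sampled at three stages of storage-root bulking
(pre-bulking PB, early-bulking EB, during-bulking DB). The pipeline takes a
gene-level count matrix plus sample metadata and chains:

1. library-size normalization and a variance-stabilizing log transform;
2. a per-tissue negative-binomial likelihood-ratio test (LRT) of the stage
   effect, with Benjamini–Hochberg FDR control at 0.001;
3. a co-expression graph over the differentially expressed genes, with a
   permutation-calibrated Pearson edge threshold and a minimum-degree filter;
4. Louvain community detection at resolution 0.75;
5. cluster stage-profile summaries (z-scores of stage means) and exclusive
   cross-tissue intersection counts (UpSet semantics);
6. Gamma GLMs with type-II ANOVA, cross-model FDR and Tukey-HSD compact
   letter displays for phenotype tables, and linear models for subcellular
   compartment fractions.

Because the sequencing data behind such a study is external and its printed
gene counts depend on the exact read-processing chain, correctness here is
established by property-based testing on synthetic data with known ground
truth: parameter recovery, null calibration, power, and agreement with
independent oracles (closed forms, exhaustive enumeration, brute force).

# The synthetic-data generator

`generate_counts()` draws counts from a negative binomial with
`var = mu + alpha * mu^2` (dispersion `alpha`), the same parameterization the
LRT uses. The expected value of gene *g* in sample *s* is

```
mu[g, s] = size_factor[s] * baseline[g] * profile[g, stage(s)] * batch[g, batch(s)]
```

Defaults, chosen once as typical of bulk plant RNA-seq and then held fixed:

* `baseline` ~ log-normal(meanlog `log(100)`, sdlog 1.2) — median gene at
  ~100 counts with a long right tail;
* `alpha` ~ log-normal(meanlog `log(0.05)`, sdlog 0.5) — biological CVs of
  ~20–30% between replicate plants;
* size factors log-uniform on [0.5, 2], rescaled to geometric mean 1 so the
  truth is identifiable by the median-of-ratios estimator;
* four replicate plants per tissue–stage (the study sampled 3–5);
* per tissue, four planted modules of 100 genes (disjoint within a tissue,
  drawn independently across tissues) sharing one of four stage templates —
  monotone up `(1, sqrt(f), f)`, monotone down, EB peak `(1, f, 1)`, EB dip —
  with fold change `f = 4` between extreme stages;
* optional two-batch mode: a per-gene log-normal (sdlog 0.5) multiplicative
  offset shared within a batch, batches assigned by replicate parity so batch
  and stage stay unconfounded — the simplest structure that exercises the
  batch-covariate path.

`generate_phenotypes()` draws strictly positive measurements from a Gamma
distribution (shape 10, log-link mean structure) per tissue × stage ×
analyte; the default mean table encodes the qualitative biology (sugars and
starch ramp up ~4-fold in the storage root during bulking, wood starch
declines, leaf sucrose high and flat). `generate_naf()` draws per-sugar
compartment compositions from a Dirichlet with mean (vacuole 0.40, plastid
0.35, cytosol 0.25) and concentration 200 across 7 replicates.

What the generator does *not* emulate: gene–gene correlation outside planted
modules, GC/length biases, outlier samples, isoform structure, and count
dependence across tissues from shared plants. Passing tests therefore show
that the algorithms are implemented correctly and are calibrated under their
stated model, not that the model captures every feature of real data.

# Normalization

`estimate_size_factors()` is the median-of-ratios estimator: per sample, the
median over genes expressed in every sample of `count / geometric mean`.
Factors are anchored to geometric mean 1; this makes recovery well-posed and
leaves the transformed scale comparable across runs.

`transform_counts()` uses `log2(count/size_factor + 1)`. A
dispersion-dependent variance-stabilizing transform would need the fitted
mean–dispersion relation; the simple log shift is monotone, maps 0 to 0, and
is consumed generically downstream, so it can be swapped without touching the
rest of the pipeline.

`expression_filter()` keeps genes whose *linear-scale* mean normalized count
reaches 50 in at least one condition (tissue × stage); `by = "sample"` gives
the global variant. The pipeline applies it before network construction
(configurable) — testing is not gated on it.

`remove_batch()` removes per-gene batch-mean offsets by ordinary least
squares with the condition design retained (delegated to
`limma::removeBatchEffect`) and then restores each gene's grand mean exactly.
A batch perfectly confounded with condition is rejected.

# The stage LRT and its dispersions

For each gene the full model is a log-link NB GLM on the stage factor (plus
the batch factor when requested), with `log(size_factor)` offsets, fitted by
iteratively reweighted least squares with step halving; the reduced model
drops the stage term. The statistic `2 * (llf - llr)` is referred to a
chi-square with `levels(stage) - 1` degrees of freedom, and calls are made at
BH-FDR < 0.001. All-zero and non-converged genes get `NA` p-values and are
never called.

**Dispersion estimation is the one place the package departs from the most
naive construction.** A raw per-gene method-of-moments estimate
(`estimate_dispersions()`, kept available via `dispersion = "moment"`) has
only ~9 residual degrees of freedom at this design; plugging it into a
chi-square LRT makes the null strongly anticonservative, while switching to
an F reference with so few denominator df destroys power. Both failure modes
were measured, not assumed. The default (`shrink_dispersions()`) therefore
shares information across genes, the standard remedy in this field:

1. genewise Cox–Reid-adjusted profile-likelihood estimates (alternating mean
   fits and profile optimization);
2. a parametric mean–dispersion trend `a0 + a1/mu`, fitted by an iterated
   Gamma GLM with outlier trimming (flat trimmed-mean fallback);
3. per gene, the maximum-a-posteriori dispersion under a log-normal prior
   centered on the trend, prior variance = robust spread of the genewise
   estimates around the trend minus their expected sampling variance
   `trigamma((m - p)/2)`, floored at 0.25.

With this default the null is calibrated (and the planted-effect power
retained) at the study's replication level. One caveat is documented: the
trend and prior are shared across genes, so null p-values are not exactly
i.i.d. uniform — a Kolmogorov–Smirnov test on 2,000 null genes is rejected on
a minority of realizations even for reference implementations of moderated
NB tests; the relevant error-control property (essentially zero calls at
FDR < 0.001 on null data) holds throughout.

# Co-expression network

Profiles are the scaled-and-centered transformed values (per gene: mean 0,
SD 1 across the tissue's samples; constant rows are dropped with a warning).
The edge threshold is estimated under a permutation null: per replication,
every gene's profile is permuted independently across samples (destroying
between-gene correlation, preserving marginals), Pearson correlations are
computed for up to 200,000 random gene pairs, and the 99.995% quantile is
recorded; the threshold is the median over 1,000 replications. On
standardized rows the correlation is a scaled dot product, which the
implementation verifies against direct correlation to 1e-12.

Edges are drawn for `r > threshold` — *signed*, strict. The study frames the
graph as a co-regulation network, so only positive co-expression forms
edges; an absolute-value mode is available behind a flag. The degree filter
removes nodes with fewer than 50 edges in a single pass (an
iterate-to-fixpoint mode exists and is off by default, since nothing
suggests iteration in the source procedure).

# Community detection

Modularity is the resolution-scaled Newman–Girvan quality
`Q = sum_c [e_c/m - gamma (d_c/2m)^2]` on the unweighted thresholded edge
set (the procedure thresholds rather than weights; a weighted mode would be
a one-line change in the internal representation). The resolution variant is
the gamma-scaled null term, not CPM; `gamma = 0.75` is the default.

`louvain()` is the classic two-phase algorithm: greedy local moves to the
neighboring community with the largest gain (ties broken toward the lowest
community id), aggregation into super-nodes, repeated to a fixed point — then
a final local refinement pass over the original nodes, and the whole
procedure restarted 5 times with seed-derived visiting orders, keeping the
best partition. The one-community and all-singleton partitions are always
candidate states, so the result never falls below either baseline. The
refinement-plus-restarts construction is what makes the optimizer match the
exhaustive Bell-enumeration oracle (`exhaustive_best_partition()`, ≤ 10
nodes) on essentially every small random graph, rather than ~80% of them.

# Cluster summaries

`stage_zscore_profiles()` averages transformed values per stage within a
gene, then z-scores across stages (constant genes map to zero); the cluster
profile is the member mean. The z-before-average order matches the heatmap
statistic "z-score of the average log-transformed values per stage" read per
gene; the cluster-mean-then-z alternative is behind a flag.

`cluster_intersections()` uses exclusive (UpSet) semantics: each gene counts
toward exactly the pattern of tissue-clusters containing it, so pattern
counts partition the universe; pattern keys are locale-independent
(radix-sorted). `adjusted_rand_index()` is the standard pair-counting ARI
used for recovery benchmarks.

# Measurement statistics

Phenotype values (mg per g dry weight, strictly positive) are fitted per
tissue × analyte with a Gamma GLM (log link, base `glm()`), dispersion by
Pearson chi-square over residual df. `anova_typeII()` tests each term by
dropping it from the model containing all others; for GLMs the statistic is
the scaled-deviance likelihood-ratio chi-square (deviance difference over
the full model's dispersion — the same quantity `car::Anova(type = "II",
test.statistic = "LR")` reports, which a test verifies). For a single factor
this is exactly the full-vs-intercept test. P-values are BH-adjusted across
the model family and the letter displays are produced only for models
passing FDR < 0.05.

`tukey_letters()` performs all pairwise Tukey–Kramer comparisons on the
*link* scale (the response-scale alternative is not provided; the link scale
keeps SEs model-based and symmetric) with studentized-range p-values at the
model's residual df, and encodes the result by insert-and-absorb. The letter
groups produced this way are exactly the maximal cliques of the
non-significance graph, so the defining invariant — two levels share a
letter iff their comparison is non-significant — holds by construction and
is re-checked against a brute-force clique enumeration in the tests.

`naf_test()` fits, per sugar, an ordinary linear model of the compartment
fraction on the compartment factor (fractions validated to sum to 1 per
replicate and sugar), BH-adjusts the per-sugar ANOVA p-values, and attaches
Tukey letters for significant models. The compositional dependence between
fractions is noted but deliberately not modeled — the plain linear model is
what the source procedure states.

# Numerical choices and degenerate inputs

* IRLS: linear predictor clamped to ±30, convergence at relative
  log-likelihood change < 1e-10, step halving on likelihood decreases,
  aliased design columns dropped (coefficient 0).
* Dispersions floored at 1e-8 (the NB→Poisson limit).
* Constant profiles: dropped before correlation; constant stage profiles:
  z-scores 0.
* Correlations clamped to [−1, 1] so a threshold of 1.0 with strict
  inequality yields an empty edge set.
* Modularity ties in the oracle resolve to the first (lexicographically
  smallest restricted-growth-string) partition.
* One master seed is split into per-stage sub-seeds by a polynomial hash
  (`derive_seed()`), so any stage can be re-run in isolation and reproduce
  the full-pipeline result; all derived seeds stay below 2^31.

# Problem sizes in the test suite

The suite exercises the pipeline at sizes chosen to make every distributional
claim measurable while keeping a full run in the low minutes on one core:
2,000-gene single-tissue designs for calibration/power/recovery checks, the
full 5-tissue default design (2,000 genes, 4 × 100-gene modules per tissue,
fold 4, minimum degree scaled to 20) for end-to-end recovery, 8-node graphs
against the exhaustive oracle, and 200–1,000-fold replication for
Monte-Carlo rates. `scripts/acceptance.R` recomputes the same quantities
from scratch at a caller-supplied seed.

# Known limitations

* The log-shift transform is a surrogate for a dispersion-aware VST; at very
  low counts its variance is not fully stabilized.
* The chi-square LRT relies on moderated dispersions; with fewer than ~3
  replicates per stage no moderation can rescue calibration.
* Louvain with restarts is a heuristic; optimality is only guaranteed where
  the exhaustive oracle can check it (≤ 10 nodes).
* The NAF linear model treats compositional fractions as unconstrained
  responses, as in the source procedure.
* Exclusive intersection counts grow with the number of tissue-clusters;
  only the `top_k` largest patterns are reported by default.
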