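---
title: "Group comparison of gray-matter structural covariance networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group comparison of gray-matter structural covariance networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnet)
```

## The model

A structural covariance network (SCN) treats brain regions as nodes and the
between-subject correlation of a morphometric measure — here regional
gray-matter volume — as the basis for edges. Because an SCN is defined at the
group level (one correlation matrix per group of subjects, not per subject),
group comparison cannot rely on subject-level variance estimates and is done
by permutation of group labels instead.

`scnet` implements the full chain:

1. **Residualization.** For every region independently, volumes are regressed
   on an intercept, age, sex (treatment-coded), education and — by default —
   the subject's mean overall gray-matter volume (the unweighted mean of the
   region columns), and replaced by the OLS residuals. This is done *once on
   the pooled sample*, before any group split. Pooled fitting is what makes
   the downstream permutation scheme exchangeable: permuted groups are drawn
   from one common corrected dataset rather than from per-group fits that
   would themselves depend on the labels.
2. **Network construction.** Each group's region-by-region Pearson
   correlation matrix is computed from the corrected volumes and binarized
   over a density grid (default 0.05 to 0.50 in steps of 0.01; at density
   *d* exactly `round(d * N(N-1)/2)` edges are kept, rounding half away from
   zero so edge counts are platform-stable). Edges are ranked by *signed*
   correlation by default — keeping the largest positive covariances, the
   dominant convention in the gray-matter covariance literature — with an
   `edge_rank = "absolute"` switch for the |r| convention. Because the
   ranking is computed once per matrix, the edge sets along the grid are
   nested by construction.
3. **Topology.** Clustering coefficient `Cp`, characteristic path length
   `Lp`, global efficiency `Eglob`, local efficiency `Eloc`, and the
   small-world indices `gamma = Cp / <Cp_rand>`, `lambda = Lp / <Lp_rand>`,
   `sigma = gamma / lambda`, where the random ensemble consists of
   degree-preserving Maslov–Sneppen rewirings of the observed graph.
   Regionally, betweenness centrality (Brandes counting, fractional credit
   for tied geodesics), normalized by the network mean for group comparison.
4. **Inference.** Subject-relabelling permutation tests (default 1000
   permutations) at every density, with empirical null confidence bands, the
   `+1` p-value convention `p = (1 + #{|null| >= |obs|}) / (n_perm + 1)`, and
   Benjamini–Hochberg FDR — across the regions for the nodal map, across the
   densities for each global-metric curve. Uncorrected and corrected
   significance are always reported side by side.
5. **Hubs.** A region is a hub when its betweenness is at least one sample
   standard deviation above the network mean (inclusive threshold). The
   default basis is the trapezoidal AUC of normalized betweenness over the
   whole grid, a threshold-free summary.

## Numerical and convention choices

Several conventions in this literature are routinely left unstated; the
package pins them down as follows.

- **Disconnected graphs.** At low densities the binarized graph need not be
  connected. `Lp` averages over *connected* pairs only (an infinite-path
  convention would leave the low-density end of every curve undefined);
  `Eglob` handles disconnection natively, disconnected pairs contributing 0.
  A strict mode (`disconnected = "error"`) is available for users who want
  connectivity enforced.
- **Local efficiency** of a node is the global efficiency of the subgraph
  *induced on its neighbors* — shortest paths are confined to the
  neighborhood. This matters: allowing detours through the rest of the graph
  gives systematically different values. Nodes with fewer than 2 neighbors
  score 0, as do nodes with degree < 2 for the clustering coefficient.
- **Matched random networks** preserve the full degree sequence via repeated
  double-edge swaps (10 attempted swaps per edge), the field-standard null.
  Matching only N and E (Erdős–Rényi) would inflate gamma on graphs with
  heterogeneous degrees.
- **Betweenness normalization** divides by the mean raw betweenness; when
  that mean is zero (e.g. a complete graph) the normalized vector is defined
  as all zeros and flagged rather than NaN.
- **Hub threshold** uses the sample (n−1) standard deviation and an
  inclusive `>=` comparison. At 90 regions the population-SD alternative
  differs negligibly, but the choice is pinned for reproducibility.
- **Ties** in the edge ranking are broken lexicographically by region-pair
  index, so binarization is fully deterministic.
- **Seeding.** One master seed is expanded into per-stage and per-iteration
  seeds through a fixed integer mixing function, so any permutation or any
  rewired network can be regenerated in isolation, and adding permutations
  does not shift earlier ones.

## The synthetic cohort generator

No subject-level data ship with the package; the generator provides cohorts
with *known* ground truth so that every stage can be validated end to end.
Its defaults describe the study design the package targets: two groups of 38
(control) and 32 (patient) subjects, 90 regions in 6 covariance modules, and
volumes built as

```
volume = baseline + effects . (age, sex, education) + noise_sd * L z
```

where `L` is the symmetric PSD square root of a block-structured target
correlation matrix (within-module correlation 0.6 for controls, 0.4 for
patients, 0.1 between modules) and `z` is standard normal — so the population
correlation of the covariate-free volumes equals the planted target exactly.
Covariates are drawn as age ~ U(55, 80) years, sex ~ Bernoulli(0.5),
education ~ U(6, 16) years, bracketing a typical elderly clinical cohort; the
default linear effects (−0.05 volume units per year of age, +0.5 for male
sex, +0.02 per education year, on a baseline of 10 with unit noise SD) are
chosen so that covariate structure is a visible but not dominant share of
variance. The within-module gap (0.6 vs 0.4) is a free design choice — the
magnitude of real covariance differences in clinical cohorts is unknown — so
planted-effect tests are checks of *direction and localization*, not of
effect size. Group sizes may be 0 (with at least one group of ≥ 3), which is
how single-group calibration cohorts are produced.

Draws follow a documented stream order (per subject: covariates, then the
noise vector), so enlarging a group appends draws without perturbing earlier
subjects.

What the generator deliberately does **not** emulate: spatial autocorrelation
of neighboring parcels, heavy-tailed or skewed volume distributions,
site/scanner batch effects, atrophy gradients correlated with covariates, or
hub structure beyond what block covariance induces. Tests passing on these
cohorts therefore validate the *machinery* — they are not evidence about any
real population.

## Worked example

A deliberately small cohort keeps this vignette fast; study-scale analyses
just change the spec and grid.

```{r example}
spec <- cohort_spec(n_regions = 30, n_per_group = c(control = 40, patient = 40),
                    n_modules = 5, seed = 42)
cohort <- generate_cohort(spec)
res <- residualize(cohort$table)

ctrl <- which(cohort$table$group == "control")
pat <- which(cohort$table$group == "patient")
net <- group_correlation(res, ctrl)
g <- binarize_at_density(net, 0.2)
small_world_indices(g, n_random = 50, seed = 1)[c("gamma", "lambda", "sigma")]
```

The modular control network is strongly small-world (sigma well above 1).
The planted group difference — weaker within-module covariance in the
patient group — expresses itself as lower clustering:

```{r test}
spec_p <- permutation_spec(n_perm = 99, seed = 7)
out <- global_metric_difference_test(res, ctrl, pat, grid = c(0.1, 0.2, 0.3),
                                     metric_name = "Cp", spec = spec_p)
as.data.frame(out)
```

Positive observed differences (control − patient) with small p-values at the
lower densities recover the planted direction — at high density both graphs
approach completeness and the contrast fades, the usual reason curves are
summarized over a whole grid. `run_pipeline()` composes all stages and
writes the tidy CSV/JSON bundle; `inst/cli/scnet.R` wraps `simulate`, `run`
and `hubs` for shell use.

## Problem sizes and costs

The expensive stages scale as: permutations × densities × (correlation +
binarization + metric). `Cp` is matrix-algebra cheap; `Eloc` costs roughly
one small BFS per node; `gamma/lambda/sigma` multiply everything by the
ensemble size, which is why permutation tests of the small-world indices
default to a reduced ensemble (`n_random` in `permutation_spec()`, default
20, against 1000 for direct curve estimates) — the ensemble size only adds
Monte-Carlo noise to the null means, and this is reported alongside results.
The package's own validation uses 90-region cohorts for calibration and
power checks (199–permutation tests; 500 null replicates for the type-I-error
check) and 20–30-region cohorts for structural tests.

## Known limitations

- Binary, undirected graphs only; no weighted, directed or multilayer
  metrics, and no modularity/rich-club statistics.
- Group-level networks mean no subject-level network parameters, hence no
  correlation of topology with individual clinical scores.
- The "mean overall GM volume" covariate is the mean of the supplied region
  columns, a proxy for total gray matter that depends on the parcellation.
- Betweenness-based localization is intrinsically noisy at clinical sample
  sizes; the package's validation aggregates over replicate cohorts for that
  reason, and single-cohort nodal maps should be read with the same caution.
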