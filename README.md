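# scnet — structural covariance network analysis

`scnet` builds and compares **gray-matter structural covariance networks
(SCNs)**: graphs whose nodes are brain regions and whose edges reflect the
between-subject correlation of regional gray-matter volume within a study
group. SCN topology is a standard lens on large-scale structural brain
organization in aging and neurodegenerative cohorts; because the network is
defined per *group* rather than per subject, group differences must be tested
by permutation of subject labels. The package is aimed at neuroimaging
researchers who already have a subjects × regions volume table (e.g. AAL-90
parcel volumes from any morphometry pipeline) and want a reproducible,
tested implementation of the downstream graph analysis.

## What it computes

Given a table with columns `subject_id, group, age, sex, education` plus one
column per region:

1. **Residualization** — per-region OLS removal of age, sex, education and
   mean overall GM volume, fitted once on the pooled sample.
2. **Network construction** — per-group Pearson correlation matrix
   *R*, binarized at each density *d* in a grid (default 0.05–0.50, step
   0.01) by keeping the `round(d·N(N−1)/2)` largest signed correlations.
3. **Global topology** — clustering coefficient *Cp*, characteristic path
   length *Lp*, efficiencies *Eglob*, *Eloc*, and small-world indices against
   degree-matched rewired random networks:
   γ = Cp/⟨Cp_rand⟩, λ = Lp/⟨Lp_rand⟩, σ = γ/λ (σ > 1 ⇒ small-world).
4. **Regional topology** — betweenness centrality, mean-normalized, with a
   trapezoidal AUC-over-densities summary per region.
5. **Inference** — subject-relabelling permutation tests (observed A−B
   difference against the relabelled null; `p = (1+#{|null|≥|obs|})/(n_perm+1)`),
   empirical null confidence bands, Benjamini–Hochberg FDR.
6. **Hubs** — regions whose betweenness is ≥ mean + 1 SD, compared between
   groups (common / group-specific), with BrainNet Viewer `.node`/`.edge`
   export.

A synthetic-cohort generator (`cohort_spec()` / `generate_cohort()`)
produces volume tables with known modular covariance, covariate effects and
planted group differences, so the whole chain can be validated against
ground truth.

## Worked example

```r
library(scnet)

spec <- cohort_spec(n_regions = 30, n_per_group = c(control = 40, patient = 40),
                    n_modules = 5, seed = 42)
cohort <- generate_cohort(spec)
res <- residualize(cohort$table)

ctrl <- which(cohort$table$group == "control")
pat  <- which(cohort$table$group == "patient")

g <- binarize_at_density(group_correlation(res, ctrl), 0.2)
unlist(small_world_indices(g, n_random = 50, seed = 1)[c("gamma", "lambda", "sigma")])
#>    gamma   lambda    sigma
#> 5.197496 1.272719 4.083772
```

γ ≈ 5.2 with λ ≈ 1.3 gives σ ≈ 4.1: the modular control network has far more
clustering than its degree-matched random nulls at essentially random path
length — strongly small-world.

```r
out <- global_metric_difference_test(res, ctrl, pat, grid = c(0.1, 0.2, 0.3),
                                     metric_name = "Cp",
                                     spec = permutation_spec(n_perm = 99, seed = 7))
as.data.frame(out)
#>    at   observed p_raw p_fdr     ci_low   ci_high flagged
#> 1 0.1 0.29222222  0.02  0.03 -0.2070000 0.1429444   FALSE
#> 2 0.2 0.29997354  0.01  0.03 -0.1975648 0.1820423   FALSE
#> 3 0.3 0.02730122  0.80  0.80 -0.1328168 0.1189510   FALSE
```

The cohort was generated with weaker within-module covariance in the patient
group (0.4 vs 0.6), and the test recovers exactly that: the control-minus-
patient clustering difference is positive and significant at the lower
densities (observed ≈ 0.29 lies outside the 95% null band; p = 0.01–0.02)
and fades by density 0.3 where both graphs densify.

`run_pipeline(run_config(...))` composes every stage and writes a bundle of
tidy CSVs (metric curves, per-density and per-region test tables,
significance markers), JSON summaries (hubs, ground truth, config) and
BrainNet Viewer files. `inst/cli/scnet.R` exposes `simulate`, `run` and
`hubs` subcommands for shell use.

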