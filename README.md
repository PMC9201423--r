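# scnet

Structural covariance network (SCN) analysis of regional gray-matter
volumes. From a subject-by-region volume table, `scnet` builds one
correlation network per group, thresholds it to a sequence of fixed-density
binary graphs, computes global and nodal graph metrics with
random-network normalization, and tests group differences by label
permutation — the complete pipeline used in SCN studies of clinical
cohorts, plus a synthetic-cohort generator so every stage can be exercised
and validated without subject data.

## What the pipeline does

1. **Adjustment** — each region's volume is residualized on total
   intracranial volume (TIV) by linear regression, within group.
2. **Association** — Pearson correlation between all region pairs of the
   residuals gives one association matrix per group.
3. **Thresholding** — each matrix is binarized at every density of a grid
   (default 0.27–0.50 in steps of 0.01) by keeping exactly the top
   `floor(d·N(N−1)/2 + 0.5)` signed correlations; graphs are nested across
   the grid. `find_dmin()` reports the smallest density at which both
   group networks are fully connected.
4. **Metrics** — clustering coefficient, characteristic path length,
   global/local efficiency, transitivity, degree assortativity, modularity,
   and normalized nodal betweenness; gamma, lambda and sigma are
   normalized against connected degree-preserving rewired null networks.
5. **Inference** — group labels are permuted and the whole pipeline re-run
   per permutation; two-tailed add-one p-values are reported per density,
   for the area under each metric-versus-density curve (AUC), and per
   region (BH-FDR corrected).
6. **Resilience** — relative largest-component curves under targeted
   (betweenness-ranked) attack and random failure, compared between groups
   by the same permutation scheme.

## Worked example

Simulate a 49 + 49 cohort over 90 regions in which group B's within-module
covariance is weakened (`effect_within_b = 0.6`), then run the comparison:

```r
library(scnet)

spec   <- cohort_spec(effect_within_b = 0.6, seed = 7)
cohort <- generate_cohort(spec)
cohort
#> Synthetic/observed cohort: 98 subjects, 90 regions, groups A (n=49), B (n=49)

demographic_matching(cohort)
#>    variable       test statistic df p
#> 1       sex chi-square       0.0  1 1
#> 2       age     t-test       0.0 96 1
#> 3 education   rank-sum    1200.5 NA 1

# choose the density grid from the data: lower bound = smallest density at
# which both group networks are connected
grp <- function(g) {
  s <- cohort[cohort$group == g, ]
  attr(s, "atlas") <- attr(cohort, "atlas")
  class(s) <- class(cohort)
  s
}
a <- build_association(residualize_tiv(grp("A")), "A")
b <- build_association(residualize_tiv(grp("B")), "B")
dmin <- find_dmin(a, b)      # 0.11 for this cohort

cfg <- perm_config(n_perm = 99, seed = 42,
                   grid = density_grid(dmin, 0.5, round((0.5 - dmin) / 2, 10)),
                   n_null = 5)
permutation_test(cohort, cfg)    # ~half a minute on one CPU
#> SCN group comparison (B - A), 99 permutations, densities 0.11-0.5
#>  metric    auc_diff    p
#>      cp -0.06228099 0.01
#>      lp -0.21459738 0.01
#>   eglob  0.01514046 0.01
#>    eloc -0.03608509 0.01
#>   trans -0.06716300 0.01
#>  assort -0.03416375 0.19
#>       q -0.05684198 0.01
#>   gamma -0.38823162 0.01
#>  lambda -0.09731847 0.01
#>   sigma -0.12072715 0.05
#> regions significant after FDR: none

res <- resilience_comparison(cohort, cfg, "targeted")
c(res$auc_diff, res$auc_p)
#> [1] 0.2023457 0.0100000
```

The designed effect is recovered: group B shows lower clustering,
transitivity and local efficiency (negative `auc_diff`, `p = 0.01`), and
its network is *more* resilient to targeted attack (positive AUC
difference) because weakening within-module covariance flattens the hub
structure.

To analyze real data instead, write a CSV with columns `subject_id`,
`group`, `tiv` and one column per region label, and load it with
`read_volume_table()`; `extract_roi_volumes()` sums gray-matter maps over
a NIfTI label image if you start from segmentations.

## End-to-end runs and the CLI

`run_pipeline(pipeline_config(...))` executes all stages and writes a
results bundle (`global_metrics_A/B.csv`, `per_density_p.csv`,
`auc_tests.csv`, `nodal_bc.csv`, resilience tables, `manifest.json`).
Identically configured runs are byte-identical. The same thing from a
shell, driven by a YAML file:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "scn-pipeline.R", package = "scnet"))')" \
  run --config config.yaml --out results/
```

## Acceptance script

`scripts/acceptance.R` runs the default-scale synthetic study end to end
against the installed package and writes the principal quantities (AUC
differences and p-values per metric, small-world minima, resilience
tests) as a flat JSON file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`.

## Tests

```r
testthat::test_dir("tests/testthat", package = "scnet", load_package = "installed")
```

The suite checks every graph metric against brute-force oracles (including
exhaustive modularity maximization on small graphs), closed-form values on
canonical graphs, exact thresholding counts, BH-FDR against the textbook
step-up, type-I error calibration of the permutation test on 200 null
cohorts, detection of a designed covariance effect, small-worldness of
lattice-like cohorts, resilience-curve theory, and byte-identical
reproducibility. The simulation blocks take roughly 15–20 minutes on one
CPU; everything else finishes in seconds. See `vignettes/scnet-methods.Rmd`
for the numerical conventions and the rationale behind each default.
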