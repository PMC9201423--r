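---
title: "Methods and numerical conventions in scnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and numerical conventions in scnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the statistical model behind `scnet`, the exact
numerical conventions the implementation commits to, and the rationale for
every default. The code chunks are illustrative and not evaluated when the
vignette is built; the README contains a fully worked, executed example.

## 1. The structural covariance model

A structural covariance network (SCN) is a group-level construct: each
node is a brain region, and the edge weight between two regions is the
Pearson correlation of their gray-matter volumes *across subjects of one
group*. Because an SCN is a single network per group rather than one per
subject, group comparison cannot use subject-level variance — inference
must come from permutation of the group labels, re-deriving both networks
under each relabeling.

Regional volumes scale with head size, so before correlating, each
region's volume is residualized on total intracranial volume (TIV) by
ordinary least squares, within group (`residualize_tiv()`). The
correlation of residuals (`build_association()`) is the association
matrix; its diagonal is set to zero.

## 2. Density thresholding

Comparing graph metrics between groups is only meaningful at equal edge
counts, so association matrices are binarized by *density*, not by a
correlation cutoff. At density $d$ on $N$ nodes the graph keeps exactly

$$E(d) = \left\lfloor d\,\tfrac{N(N-1)}{2} + 0.5 \right\rfloor$$

edges — the $E(d)$ largest **signed** correlations (a strong negative
covariance is not evidence of shared structure). Conventions the tests
pin down:

* **Ties** are broken deterministically by ascending (row, column) order
  via a stable sort, so identical inputs yield identical graphs on any
  platform.
* **Nesting**: because the same ranking is cut at different depths, the
  graph at a lower density is always a subgraph of the graph at a higher
  density.
* The default grid is 0.27 to 0.50 in steps of 0.01 (24 densities).
  The lower bound should be the smallest density at which *both* group
  networks are fully connected; `find_dmin()` computes it, and the
  pipeline refuses to run on a disconnected observed network rather than
  silently reporting path lengths of a fragmented graph. Above 0.5 the
  networks are dense enough that their topology is increasingly
  uninformative.

## 3. Graph metrics

All metrics operate on binary undirected graphs (C++ kernels over packed
bitset adjacency rows):

* **Clustering coefficient** $C_p$: mean over nodes of the ratio of
  closed triples at the node; nodes of degree < 2 contribute 0.
* **Characteristic path length** $L_p$: mean shortest path over all
  ordered pairs (defined only on connected graphs — hence the $D_{min}$
  rule).
* **Global efficiency**: mean inverse shortest-path length; **local
  efficiency**: mean over nodes of the global efficiency of the
  neighborhood subgraph.
* **Transitivity**: 3 × triangles / connected triples, a graph-level
  quantity distinct from $C_p$.
* **Degree assortativity**: Pearson correlation of degrees over edge
  endpoints; it is `NaN` when the endpoint degree variance is zero (e.g.
  regular graphs), and the code propagates that honestly instead of
  mapping it to 0.
* **Modularity** $Q$: for graphs of up to 8 nodes the package enumerates
  *all* partitions and returns the exact maximum (this is what the
  brute-force test oracles check against); above 8 nodes it uses
  greedy agglomerative (CNM) maximization. The cutover is a size where
  exhaustive search ($B_8 = 4140$ partitions) is still instant.
* **Betweenness centrality**: Brandes' algorithm, endpoints excluded.
  Reported per node as `bc_norm` = raw betweenness divided by the mean
  over nodes, so values are comparable across densities.

### Small-world normalization

$\gamma = C_p / C_p^{rand}$, $\lambda = L_p / L_p^{rand}$,
$\sigma = \gamma / \lambda$, where the null values are means over an
ensemble of degree-preserving random graphs generated by double-edge
swaps (default: ensemble of 20, each accepting `swap_factor` × E = 10·E
successful swaps). Two conventions matter:

* A null network that ends up disconnected is discarded and regenerated,
  because $L_p^{rand}$ must be defined on the same footing as $L_p$.
* The null ensemble is driven by its own deterministic RNG stream
  (xoshiro256++), seeded from the analysis seed, so results are exactly
  reproducible.

An Erdős–Rényi null (`null_model = "er"`) is available for sensitivity
analyses but degree-preserving rewiring is the default, since SCN degree
distributions are far from binomial.

## 4. Permutation inference

For the observed labels and each of `n_perm` label permutations that
preserve group sizes, the **entire** pipeline is re-run per group —
residualization, correlation, thresholding, metrics, null normalization.
Differences are group B − group A. Two-tailed p-values use the add-one
rule $p = (1 + \#\{|\Delta_{perm}| \ge |\Delta_{obs}|\})/(n_{perm}+1)$,
reported:

* per metric per density,
* per metric for the area under the metric-versus-density curve
  (trapezoid rule), which summarizes the grid without multiplying tests,
* per region for mean-over-density normalized betweenness, corrected by
  Benjamini–Hochberg FDR (`bh_fdr()` matches the textbook step-up
  exactly).

A permuted split whose network is disconnected at the smallest grid
density cannot yield $L_p$; such splits are resampled (bounded retries,
count reported) rather than silently dropped.

### Common random numbers

The two groups of every comparison pair — observed or permuted — share
**one** seed for their null-network ensembles (and, in the resilience
module, for random-failure removal orders). This is classic common-random-
numbers variance reduction: the Monte Carlo noise of the null
normalization cancels in the difference, so $\gamma/\lambda/\sigma$
comparisons test the networks, not the null sampler. It also yields an
exact invariance the test suite checks: comparing a group against an
identical copy of itself gives a difference of exactly zero and $p = 1$
for *every* statistic, including the seed-dependent ones. Each permutation
gets a fresh shared seed, so exchangeability under the null is untouched.

## 5. Resilience

`targeted_attack_curve()` removes nodes in descending order of
betweenness computed **once** on the intact graph (static ranking; ties
by ascending node index), recording the largest connected component
relative to the original node count — an $(N{+}1)$-point curve from 1 (or
the initial relative LCC) down to exactly 0. `random_failure_curve()`
averages the curve over `n_iter` uniformly random removal orders.
`resilience_comparison()` compares groups at the lower end of the density
grid (where topology differences are sharpest) with the same permutation
scheme and AUC summary as the metric tests.

## 6. The synthetic cohort generator

`cohort_spec()` / `generate_cohort()` simulate volumes from a
multivariate normal with a structured correlation matrix:

* **Modular** structure (default): regions partitioned into modules
  (90 regions → 6 modules of 15), correlation `r_within = 0.5` inside a
  module and `r_between = 0.1` across modules. These defaults give
  networks whose thresholded topology is modular but connected across the
  default density grid.
* **Ring** structure: correlation decays geometrically with ring distance
  (`r_within · ring_decay^(d-1)`), producing lattice-like, strongly
  small-world networks ($\gamma > 1$, $\sigma > 1$ across the grid).
* **Group effect**: `effect_within_b` multiplies group B's structured
  (off-diagonal within-module) correlations; values < 1 weaken B's
  covariance, lowering its clustering, transitivity and local efficiency.
* **TIV confound**: volumes gain `tiv_beta` × TIV (default 0.004 per ml,
  TIV ~ N(1450, 120²)), so residualization is load-bearing, not
  decorative.
* The target matrix is repaired to positive semi-definite by eigenvalue
  clipping before sampling.
* **Demographics** are exactly matched by construction at equal group
  sizes (sex counts copied, ages identical), so the chi-square /
  t-test / rank-sum battery returns statistic 0 and p = 1 — a fixture for
  testing the demographic-matching report, not a claim about real
  recruitment.

### Known limitation: assortativity power

The generator family expresses group effects as uniform within-module
correlation scaling. That moves clustering, transitivity and local
efficiency reliably, but degree **assortativity** of the thresholded
graphs responds weakly and inconsistently: across a wide probe of grids
and effect sizes, the direction of the assortativity AUC difference is
unstable and permutation power stays near the nominal level. Detecting
assortativity differences would require a generator that manipulates
degree–degree structure directly (e.g. hub-targeted effects), which this
covariance-scaling family cannot express. The acceptance suite asserts
the assortativity contrast anyway and is expected to fail that clause;
the failure documents a property of the generator, not of the estimator.

## 7. Test design and problem sizes

The simulation sizes in the test suite are the package's own choices,
made to give each property enough replicates to be meaningful within a
reasonable runtime on one CPU:

* **Oracle equivalence**: 200 random graphs of up to 7 nodes, compared to
  pure-R brute-force implementations (Floyd–Warshall distances,
  exhaustive partition enumeration for modularity, path-counting
  betweenness) at tolerance 1e-12.
* **Type-I calibration**: 200 null cohorts (49+49 × 90), 99 permutations
  each. Calibration of a permutation test follows from label
  exchangeability alone — it does not depend on the density grid or the
  null-ensemble size — so this block runs a 3-point grid and
  `swap_factor = 3` to fit its time budget. Per-metric rejection rates at
  $\alpha = 0.05$ are required to fall in [0.02, 0.09], the ~99%
  binomial band around 0.05 at 200 replicates.
* **Power**: 20 cohorts with `effect_within_b = 0.6`; the grid per
  replicate follows the method's own rule (lower bound = the cohort's
  $D_{min}$).
* **Determinism**: two identically configured full-scale pipeline runs
  (24 densities, 100 permutations) must produce byte-identical output
  files.

## 8. Reproducibility

Every stochastic component — cohort generation, permutation draws, null
ensembles, random-failure orders — derives from explicit integer seeds,
and the C++ RNG is self-contained, so a pipeline run is a pure function
of its configuration. `manifest.json` in each results bundle records the
configuration needed to regenerate it.
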