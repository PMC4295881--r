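---
title: "Inferring and analyzing multi-omics association networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and analyzing multi-omics association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicfuse)
```

## The problem

Longitudinal nutrition studies routinely measure several *blocks* of
variables on the same subjects — clinical risk factors, tissue lipid
composition, targeted gene-expression panels — and ask how these layers
interact as a system rather than variable by variable. The statistical
obstacle is heterogeneity: the blocks differ in units, in dimension (a
clinical panel of ~15 variables versus a transcript panel of ~221, measured
on ~135 subjects), and in within-block correlation structure, so no single
global estimator treats them fairly.

`omicfuse` implements a three-step inference strategy for this setting:

1. **Within each block**, a sparse Gaussian graphical model. Assuming the
   block's variables are jointly Gaussian, the graphical lasso maximizes the
   penalized log-likelihood
   $\log\det\Theta - \mathrm{tr}(S\Theta) - \lambda \sum_{j\neq k}|\Theta_{jk}|$
   over positive-definite precision matrices $\Theta$ (diagonal
   unpenalized). Nonzero off-diagonals are edges; their weights are partial
   correlations $\rho_{jk} = -\Theta_{jk}/\sqrt{\Theta_{jj}\Theta_{kk}}$,
   which measure direct association after removing the linear effect of all
   other variables in the block.
2. **Between each pair of blocks**, ridge-regularized canonical correlation
   analysis (rCCA). Ridge terms $(S_{xx}+\lambda_x I)$, $(S_{yy}+\lambda_y I)$
   make the CCA eigenproblem well-posed when variables outnumber subjects.
   Cross-block variable pairs are scored through the canonical subspace:
   with $Z_d$ the average of the two blocks' $d$-th canonical variates,
   $M_{jk} = \sum_{d} \mathrm{cor}(x_j, Z_d)\,\mathrm{cor}(y_k, Z_d)$, the
   standard relevance-network construction for rCCA.
3. **Merging under an edge budget.** Each of the six component networks is
   thresholded to carry as many edges as it has nodes — the transcript
   network keeps 221 edges, the clinical network 15, the clinical-transcript
   bipartite network 15+221 — before the union is taken. Without this
   density calibration the largest block would dominate the merged graph.
   Edge weights are kept but tagged by estimator family
   (`ggm:<block>` / `cca:<pair>`); weights are **never** compared across
   families, because a partial correlation and a canonical-variate relevance
   score are not on a common scale.

Downstream, the global network is clustered by modularity maximization with
a spin-glass annealer, clusterings and node centralities are tested against
degree-preserving permutation nulls, per-cluster hubs are extracted, and
clusters are compared across networks (or against gene-set collections) with
one-sided Fisher exact tests.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- run_config(
  sim = simulation_config(seed = 421),
  B = 100, seed = 421
)
res <- run_pipeline(cfg, out_dir = "run1")
res$modularity_test$significant
res$hubs
```

The run directory contains the simulated blocks, the six component
networks and the merged graph (GraphML and GEXF, ready for force-based
layout in an external viewer), the partition, the betweenness report, the
null ensembles, and a JSON manifest with per-stage summaries and file
checksums; a rerun with the same config and seed reproduces the checksums.

## What the synthetic cohort emulates

The generator stands in for a cohort whose fatty-acid and clinical data are
not publicly deposited. It reproduces the statistical *shape* of the study,
not its values:

* **Dimensions.** 135 subjects; blocks of 15 (bio-clinical), 30
  (fatty-acid) and 221 (transcript) variables. The fatty-acid panel size
  varies between studies, so 30 is a configurable default rather than a
  claim.
* **Intra-block structure.** Each block's noise is Gaussian with a sparse
  precision matrix: off-diagonal support drawn uniformly at rate
  `intra_density` (default 0.1) with magnitudes in ±[0.5, 1], and the
  diagonal set to the row's absolute sum plus one. Diagonal dominance
  guarantees positive definiteness *without* disturbing the declared
  support, which the recovery tests depend on; the price is that implied
  partial correlations are modest (|ρ| mostly below 0.5), a regime
  comparable to real tissue data.
* **Cross-block structure.** Blocks share `n_latent` (default 3) standard
  normal latent factors through sparse loadings (each variable loads on a
  factor with probability 0.2, loading sd 0.5). A low-rank factor model is
  the canonical structure rCCA is designed to detect, which makes recovery
  of the induced cross-block pairs a meaningful benchmark; the true pairs
  are exactly the support of $L_x L_y^\top$.
* **Weight trajectories.** Baseline weights are drawn near 94 ± 15 kg
  (truncated to 66–150 kg, the observed range of the emulated cohort), the
  calorie-restriction phase removes 8–13% of body weight (the trial
  required ≥ 8% loss for continuation), and the maintenance-phase change is
  drawn per group: losers at −2 − |N(5, 2.5)| kg, regainers at
  +2 + |N(3, 2)| kg, stable subjects uniform on (−2, 2). These means match
  the reported group averages (−7 and +5 kg); group probabilities default
  to the observed stratification 45/39/51 of 135. By construction the ±2 kg
  classifier recovers the drawn labels exactly.

What the generator does **not** emulate: real covariance magnitudes,
block-specific marginal distributions (skewed biomarkers, percentage
compositions that sum to ~100), batch structure, or missingness. Passing
recovery tests on this cohort therefore demonstrates correctness of the
estimators under their own model assumptions — not performance on real
adipose-tissue data.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| intra edge budget | block's node count | density calibration of step 3 |
| pair edge budget | sum of the two node counts | same rule for bipartite networks |
| `lam` (GGM) | calibrated | l1 penalty, bisected to hit the budget |
| `lam_x`, `lam_y` (rCCA) | 5-fold CV on {1e-3…1}, or fixed 0.1 | ridge weights |
| `ncomp` | 3 | canonical dimensions summed into the relevance score |
| `spins` | 25 | maximum clusters per annealed component |
| `gamma` | 1 | resolution; ground state = max modularity |
| `t_start`, `t_stop`, `cool` | 1, 0.01, 0.99 | geometric annealing schedule |
| `B` | 100 | permutation replicates for both null tests |
| `swap_factor` | 10 | attempted double-edge swaps per edge |
| transform gate | KS p < 0.05 | log-transform trigger (positive data only) |

The budget rule, the spin-glass/annealing approach, B = 100, and the
KS-gated log transform are fixed parts of the method; the rCCA ridge
values, `ncomp`, and the annealing constants are genuinely free, so their
defaults follow long-standing conventions of the field's packages, and all
are exposed.

## Numerical choices

* **Graphical lasso.** Block coordinate descent over columns with an inner
  lasso solved by coordinate descent (compiled code); convergence when the
  working covariance changes by less than `tol` (default 1e-5) times the
  mean absolute off-diagonal of S, with a 500-sweep cap that raises an
  error carrying the residual. An edge is "selected" when
  |Θ_jk| > 1e-8 — penalized solvers produce exact zeros only up to machine
  precision. Fitting is on the correlation scale by default since blocks
  mix units.
* **Budget calibration.** The edge count along the penalty path is a step
  function, so an exact hit is not guaranteed; the bisection starts from
  the fully shrunk end (warm-starting each fit) and returns the closest
  attainable count, preferring the larger penalty among ties, with the
  deviation reported. On cohorts of the default dimensions the node-count
  budgets are attained exactly.
* **rCCA.** Solved by regularized whitening + SVD; canonical correlations
  clipped to [0, 1] with an assertion that clipping only ever absorbs
  numerical noise (≤ 1e-10). A zero ridge with a singular block covariance
  is an error instructing a positive ridge. Relevance-score ties at the
  budget cutoff break by lexicographic variable-name order so runs are
  reproducible.
* **Annealer.** Per connected component (cluster ids offset; modularity
  reported on the full graph): |V| Metropolis single-spin proposals per
  temperature, geometric cooling, then a zero-temperature polish of greedy
  single-node moves *and* greedy cluster merges. The merge moves matter: a
  community split across two spin states is a local optimum for single-node
  dynamics. If annealing still underperforms the one-cluster or
  all-singletons baselines, the better baseline is returned. The annealer
  uses a private seeded RNG, so results are reproducible independent of R's
  RNG state. Note that clustering a component in isolation maximizes the
  component-local modularity; a graph that is itself one dense module will
  be subdivided, which is the expected behavior of modularity on such
  graphs.
* **Null models.** Degree-preserving rewiring uses `swap_factor·|E|`
  attempted double-edge swaps, rejecting self-loops and parallel edges;
  attributes are dropped, since null graphs are structural. Modularity
  nulls re-run the full annealer on each replicate with a fresh sub-seed —
  reusing the observed partition would bias the null downward. The
  betweenness null records each replicate's *maximum* betweenness;
  permutation p-values are add-one, `(1 + #{null ≥ obs})/(B + 1)`, hence
  never zero and never below 1/(B+1). A node whose degree forces its
  centrality (a star center, a path midpoint) is correctly *not*
  significant under this null: its p-value is 1 because every
  degree-preserving rewiring reproduces its betweenness. A pooled per-node
  null is available as an option.
* **Seeds.** Every stochastic operation takes an explicit integer seed;
  multi-replicate procedures derive per-replicate sub-seeds from it, so
  individual replicates are reproducible, and R's global RNG state is
  always restored.

## Design choices that were genuinely open

* The relevance-matrix construction (correlations with averaged canonical
  variates, summed over `ncomp` dimensions) is the established bipartite
  construction of the rCCA framework. Under the null this score does not vanish — the averaged variate
  mixes within-block correlation into Z, so uncoupled blocks still show
  scores up to ≈ 0.3 — which is why edge selection is by budgeted top-k
  rather than a fixed threshold.
* The betweenness permutation test's "top 5%" rule is read as the
  per-replicate-maximum null described above, which reproduces the
  reported pattern of per-node p-values; the pooled alternative is exposed.
* Pair budgets are read as the *summed* node count of both blocks.
* Boundary weight changes of exactly ±2 kg are classified WL/WR (the rule
  is "greater or equal").
* Community/centrality computations default to unweighted structure
  precisely because merged weights mix estimator families.
* Cluster significance uses the strict rule — observed modularity above the
  *maximum* of the null replicates — with the add-one p-value reported
  alongside.

## Problem sizes used in validation

The test suite exercises the full study dimensions (135 × 15/30/221) for
the edge-budget checks, and smaller graphs (40–60 nodes, 10–20 seeds,
B = 100 nulls) for the stochastic calibration checks: planted two-clique
recovery on 20 seeds, planted cross-block pair recovery on 10 seeds,
barbell bridge significance on 10 seeds, false-positive calibration of the
modularity test on 10 Erdős–Rényi graphs, and the BH false-discovery rate
over 200 null repetitions. These sizes give the binomial bounds asserted in
the tests reasonable power while keeping the suite quick to run.

## Limitations

* The graphical lasso assumes joint Gaussianity after the log-transform
  gate; heavy-tailed or compositional variables violate this, and no
  nonparanormal extension is provided.
* The edge-budget rule fixes network density a priori. It makes blocks
  comparable but is not a sparsity *estimate*; edges near the budget cutoff
  are sensitive to sampling noise.
* Modularity maximization has a resolution limit; small modules attached to
  a large graph may be absorbed. `gamma` is exposed but defaults to 1.
* Permutation nulls condition on the degree sequence only; they do not
  preserve the intra/inter edge-type partition unless the stratified option
  is requested, and B = 100 bounds attainable p-values at ≈ 0.01.
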