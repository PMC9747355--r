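---
title: "Methods: from single-cell clusters to drug combinations"
author: "scRepurpose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from single-cell clusters to drug combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

scRepurpose chains five analyses: single-cell clustering with automatic
resolution selection, cluster annotation, survival stratification of a bulk
cohort, latent-factor drug-response prediction, and combination search over
a perturbation screen. This vignette explains each model, the parameters
that matter, the numerical choices, and what the synthetic-data generators
do and do not establish.

## Clustering and automatic resolution

Counts are assumed to be raw UMI-like non-negative integers. QC removes
cells with fewer than 200 detected genes or a mitochondrial count fraction
of 30% or more (genes recognized by the configurable symbol prefix,
default `"MT-"`, the human convention), then genes detected in fewer than
3 surviving cells. Cell filters run before the gene filter, so gene
support is counted on QC-passing cells only — the order matters for genes
carried mainly by low-quality cells, and it is fixed and tested. Filtering
is idempotent.

Normalization scales each cell to 10,000 total counts and applies
`log1p`. Highly variable genes are selected by the common dispersion
convention: per-gene dispersion = variance/mean on the de-logged scale,
log-dispersion z-scored within 20 equal-width bins of `log1p` mean
expression, then either thresholded (mean window 0.0125–3, normalized
dispersion ≥ 0.5) or capped at `nTop`. The equal-width binning is a real
choice, not a detail: with equal-frequency bins a block of strong marker
genes can occupy a bin alone and be z-scored against itself, erasing its
signal. Selected genes are centered and scaled to unit variance with
values clipped at ±10 to bound the leverage of expression outliers.

The embedding uses the top 20 principal components (reduced with a warning
when the matrix rank is lower); the graph connects each cell to its 15
nearest Euclidean neighbors in PC space, union-symmetrized with unit
weights. Louvain community detection at resolution $\gamma$ yields labels,
renumbered 0..K−1 by descending cluster size so labels are stable across
runs. Both defaults (15 neighbors, HVG thresholds) are conventional rather
than derived; they are exposed as parameters.

Resolution is selected on the grid 0.4–1.4 in steps of 0.2. For each
candidate, the dataset is clustered 5 times on random 80% cell subsets
(drawn without replacement; neighbors recomputed on the subset embedding),
giving a co-clustering frequency $f(i,j)$ = co-cluster count / co-sample
count. The robustness score is the mean silhouette of the *full-data*
labels under the dissimilarity $1-f$; the resolution with the highest
score wins, ties going to the smallest (coarsest) resolution. Whether the
silhouette should be taken against full-data or subsample labels was an
open choice; full-data labels are used because they are the object being
scored. Pairs never co-sampled in any repetition are excluded from the
silhouette terms rather than imputed; a cell left with no valid term is
dropped from the mean, and a single-cluster solution is defined to score 0
with a warning. Seeds are structured as master + 1000·(grid index) +
(repetition), so every repetition is reproducible independently.

## Annotation

Differential expression is one-vs-rest per cluster. The default test is a
vectorized Welch t-test on log-normalized values (matching the default of
the standard single-cell ranking function; Wilcoxon is available by flag),
with Benjamini–Hochberg adjustment within each cluster and genes ranked by
test score. The log2 fold change compares de-logged cluster and rest means
with a 1e-9 floor. Single-cell clusters are skipped with a warning.

Gene-set enrichment is a local hypergeometric over-representation test: the
query is the DEGs passing log₂FC > 2 and raw and adjusted p < 0.01 (all
strict), the background defaults to all analyzed genes, and term p-values
are BH-adjusted. Cell typing correlates each cluster's mean expression
profile (GEP) against a user-supplied reference panel by Spearman
correlation on shared genes — rank correlation makes the assignment
invariant to monotone transformations, so the panel need not share the
query's normalization; fewer than 50 shared genes triggers a warning.
Tumor clusters are those where tumor-origin cells are more than 2× (strict)
over-represented relative to normal-origin cells, with representation
measured as the within-cluster fraction of each origin's total cells so
dataset-level imbalance cancels; the wording of "percentage" is genuinely
ambiguous, so this convention is explicit and configurable.

## Survival stratification

Each cluster's signature is its top-20 DEGs restricted to cohort genes;
missing genes are back-filled from the next ranks to keep the score scale
comparable across clusters. The activity score of a patient for a cluster
counts signature genes expressed strictly above the gene's cohort median —
a patient at the median everywhere scores 0. High/low groups are the top
and bottom quartiles (linear-interpolation percentiles, type 7; quartile
ties included in the extreme groups); all-equal scores are an error. The
two groups are compared by the product-limit estimator and the two-sample
log-rank test, and the hazard ratio is estimated from the log-rank table
as $(O_h/E_h)/(O_l/E_l)$ rather than a Cox fit — the simplest estimator
consistent with the log-rank statistic; `survival::coxph` can be used as a
cross-check. Raw log-rank p-values are reported per cluster by default; BH
across clusters is a flag.

## Drug-response model

Training data are a panel of cell lines with expression and per-drug
responses: −log IC50 for GDSC-style screens, or 1−AUC for PRISM-style
screens rescaled by the affine map $D' = 240D - 120$ so its dynamic range
matches the IC50 scale (the inverse map is applied for reporting).
PRISM-style feature genes are those whose expression correlates with the
per-line mean response at |r| ≥ 0.2 — the aggregation to per-line means is
a documented choice where the aggregation rule was ambiguous; GDSC-style
models use all non-constant genes.

A sample is represented by kernel features: Pearson correlations between
its fold-change profile (expression minus the panel's per-gene mean) and
each training line's fold-change profile, so the feature dimension is the
number of training lines, not genes. The prediction is
$\hat{s}_{iu} = b_i + q_i\cdot(x_u W)$ with objective
$L = \frac{1}{2K}\sum m_{iu}(s_{iu}-\hat s_{iu})^2 + \lambda\|W\|^2 +
\lambda\|Q\|^2$, $K$ the number of observed pairs (missing responses are
masked, not imputed). Per-sample biases and the global mean are excluded
from prediction by construction: a bias learned for training lines says
nothing about an unseen cell cluster.

Optimization is bold-driver gradient descent: full gradients; a step that
increases the objective is rejected and the learning rate halved, an
accepted step grows it by 5%. The accepted-loss trace is therefore
monotone non-increasing by construction, which makes the descent property
checkable rather than probabilistic — the reason this was chosen over
momentum methods. Defaults: initial rate 0.01, at most 100,000 epochs,
early stop when the relative loss change stays below 1e-8 for 100 accepted
epochs; divergence to non-finite loss is an error suggesting a smaller
rate. Initialization: $W, Q \sim N(0, 0.01)$, biases at per-drug means,
all seeded. $\lambda$ defaults to 0.01; exact-recovery tests use 1e-4
because at 0.01 the regularized optimum visibly shrinks a noiseless fit.
Latent dimension follows the screen type (10 for GDSC-style, 140 for
PRISM-style, capped at the number of lines).

Per-cluster prediction has two modes. `per_cell_mean` computes kernel
features per cell and averages predictions within clusters;
`cluster_wise` builds one fold-change profile per cluster against the mean
of the *other* clusters (against the panel reference when only one cluster
exists, which also makes the two modes coincide on degenerate one-cluster
input). Drugs whose per-drug Spearman between predicted and observed
training responses falls strictly below the first quartile of the
coefficient distribution are dropped; with fewer than 4 drugs no filtering
occurs. Held-out evaluation splits off 24 lines, trains on the rest and
reports median absolute error and Pearson r.

The query expression must be on the same log scale as the panel
expression; the package does not attempt cross-platform harmonization.

## Combination search

Cluster GEPs are de-logged into a non-negative signature matrix restricted
to the screen's gene space. Each experiment's bulk profile is deconvolved
by non-negative least squares into mixture weights, normalized to
proportions — a deliberately transparent constrained-linear stand-in that
honors the same input/output contract as reference-based deconvolution
services; a rank-deficient signature warns about non-uniqueness. Control
proportions are averaged over all control experiments. The reduction of
subpopulation $s$ under an experiment is $1 - p_{treated,s}/p_{control,s}$;
a kill requires reduction > 0.90, confirmed only if every same-compound
experiment at a strictly higher concentration (same unit; unit mismatches
skip the check with a warning) shows reduction ≥ 0.75 — vacuously
confirmed when no higher dose exists. The 90% rule is applied per
experiment, not per compound-best-dose (an open choice; configurable).
Subpopulations with zero control proportion are excluded with a warning.

The greedy search repeatedly selects the perturbation killing the most
not-yet-killed subpopulations, breaking ties by the larger sum of its
reductions over *all* subpopulations (the all-subpopulation reading of the
efficacy rule), and branching into separate plans on exact double ties;
killed subpopulations are removed each round, and the search stops when
nothing new dies. Perturbations are processed in lexicographic
(compound, concentration) order so output order is deterministic. The
first step provably kills the single-perturbation maximum, and on disjoint
kill sets greedy coverage equals the exhaustive optimum (asserted against
brute force in the tests).

## Synthetic data: what it shows and what it does not

The generators provide truth-labelled inputs for every stage.

* `simulateCounts`: negative-binomial counts (dispersion 0.5), log-normal
  library sizes (sd 0.3), k equal clusters each up-regulating a disjoint
  marker set 4-fold, ~5,000 counts/cell. Defaults produce clearly
  separated but noisy populations — the regime the clustering chain is
  designed for. Not modelled: doublets, ambient RNA, batch effects,
  continuous trajectories.
* `simulateDrugPanel`: low-rank expression; sample latents are a planted
  linear projection of the panel's own kernel features, i.e. exactly the
  function class the model fits, with response noise scaled relative to
  the noiseless response sd. This is intentional: it makes recovery
  properties (noiseless training Spearman ≥ 0.99, held-out medians ≥ 0.8
  at 10% noise) meaningful model checks. It does *not* show the model
  recovers responses whose structure lies outside the kernel-feature
  class, nor anything about real GDSC/PRISM generalization.
* `simulatePerturbationScreen`: treated proportions are base proportions
  with planted reductions applied and renormalized, bulk profiles are
  exact signature mixtures plus optional Gaussian noise. Because of
  renormalization the *measured* reduction is smaller than the planted
  one, so round-trip fixtures plant ≥ 0.96.
* `simulateSurvivalCohort`: per-cluster latent activities, signature genes
  tracking them with sd-0.6 noise, exponential survival with hazard
  $h_0 \cdot HR^{z}$ in the effect cluster's latent, independent
  exponential censoring calibrated to the requested censoring fraction at
  HR = 1.

Passing tests on these generators demonstrates internal correctness and
statistical calibration (null log-rank p-values are uniform; ~5% false
positives at $\alpha = 0.05$), not performance on real tumors, real
screens, or real cohorts.

Test and acceptance problem sizes are chosen to exercise the asymptotics
that matter while staying desk-sized: 750 cells × 2,000 genes × 5 clusters
for end-to-end clustering (5 seeds), 60 lines × 25 drugs × rank-4 latents
for the drug model (24-line holdout, 5 seeds), 200-patient cohorts with
100 seeds for survival power and calibration, and ≤ 6-compound screens
where exhaustive search is feasible as an oracle.

## Known limitations

* Louvain on a kNN graph is order-sensitive in ambiguous regimes; label
  stability under cell permutation holds for well-separated structure but
  is not guaranteed in general.
* Imputation and batch-correction are pass-through hooks; data requiring
  them should be corrected upstream.
* The deconvolution stand-in assumes bulk profiles are non-negative linear
  mixtures of cluster signatures on the anti-log scale; platform effects
  between screen and single-cell data are not modelled.
* The O/E hazard-ratio estimator is biased toward the null in small
  samples relative to a Cox fit; it is reported because it derives
  directly from the log-rank table.
* Greedy combination search is optimal for disjoint kill sets but can be
  suboptimal for overlapping ones; branching mitigates but does not
  eliminate this.
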