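---
title: "Small-world topology of white-matter functional connectomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-world topology of white-matter functional connectomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmtopo)
```

## The analysis in one paragraph

`wmtopo` implements a graph-theoretical analysis of white-matter (WM)
functional connectomes for case-control studies. A binary WM voxel mask is
randomly subdivided into N contiguous, size-balanced nodes (region growing;
N = 128 by default). Node-averaged BOLD time series give a Pearson
correlation matrix per subject, variance-stabilized by the Fisher r-to-z
transform. Each matrix is proportionally thresholded across sparsities 0.10
to 0.30 (step 0.01) and, at each sparsity, weighted clustering Cp and
characteristic path length Lp are normalized against degree-preserving
random networks to give gamma = Cp/Cp_rand, lambda = Lp/Lp_rand and
sigma = gamma/lambda. Each metric's curve is reduced to its trapezoidal
area under the curve (AUC) — a threshold-independent per-subject scalar.
AUC features feed covariate-adjusted group tests, symptom correlations in
patients, a cross-validated linear support vector regression (SVR) of
severity, and a balanced-subsample sigmoid-kernel SVM ensemble classifier
applied to an independent replication sample.

## Parcellation

`grow_parcels()` draws N seed voxels uniformly without replacement, then
repeatedly gives one unlabeled neighboring voxel to the currently smallest
parcel until the mask is exhausted. This smallest-first rule is what keeps
parcel sizes nearly uniform. Choices the method description leaves open, and
how the package resolves them:

* **Voxel connectivity** — not specified upstream; the default is the
  26-neighborhood, the common choice for 3D region growing. 6 and 18 are
  available via the `connectivity` argument.
* **Ties** (several equally small parcels, or several candidate voxels) are
  broken by the seeded random stream, consistent with the method's
  explicitly random character; parcellations are reproducible given the
  seed.
* **Disconnected masks**: if a mask component contains no seed, the orphan
  component is attached to the parcel with the nearest centroid and a
  warning is raised. Masks should normally be connected.

## Connectivity and thresholding

`fc_matrix()` clips correlations to ±(1 − 1e-7) before `atanh`, so perfectly
correlated node pairs map to a large finite z instead of infinity.
`threshold_proportional()` keeps the top `round(s · N(N−1)/2)` edges at
sparsity s. Two policies are deliberately explicit because the upstream
description is silent on them:

* **Negative correlations** are ranked by signed value by default; surviving
  negative edges contribute their absolute value to the weighted metrics
  (which require nonnegative weights). At sparsities up to 0.3 the retained
  edges are overwhelmingly positive, so the policy rarely binds; `absolute`
  and `zero` alternatives are provided.
* **Ties** at the cut are resolved by a stable sort on (value, edge index),
  so the edge count is exact and runs are reproducible.

## Graph metrics

Weighted clustering uses the Onnela geometric-mean-of-triangles form on
max-normalized weights (the convention of the graph-analysis toolboxes used
in this literature); the Barrat form is a config alternative. Path length
uses edge length 1/weight. Unreachable node pairs — possible at sparsity
0.10 — are excluded from the Lp mean by default (the reachable fraction is
reported), because infinite distances would destroy the AUC; a harmonic
(efficiency-style) alternative is available.

Null networks are Maslov–Sneppen rewirings (10 swap attempts per edge,
rejecting self-loops and multi-edges) of the binary topology, with the
original weight multiset randomly permuted onto the rewired edges. Every
null therefore preserves each node's degree and the weight distribution
exactly. The null count defaults to 100; the package's own test suite uses
2–20 nulls to keep runtimes in minutes, which widens the sampling noise of
gamma and lambda slightly but leaves their expectations unchanged.

All stochastic steps take explicit seeds; per-subject seeds are derived from
a root seed plus a hash of the subject id, so cohort results do not depend
on subject order.

## The synthetic cohort generator

No imaging data ship with the package; `simulate_cohort()` generates
cohorts with the statistical structure the analysis assumes, so the entire
chain is testable. Each subject's "true" network is a weighted
Watts–Strogatz graph: a ring lattice (even degree `k_ring`, chosen as the
smallest degree giving edge density above 0.3 so every sparsity in the sweep
is attainable) rewired with per-subject probability p, with i.i.d.
lognormal(0, 0.5) weights scaled to (0, 1]. Patients receive
`p = base_rewiring + randomization_shift` (defaults 0.2 + 0.4), controls
`base_rewiring`; every subject's p is jittered to emulate inter-individual
topological variability (SD 0.12 for controls and 0.2 for patients — the
wider patient spread reflects the heterogeneity of disease expression in
clinical cohorts and is also what makes per-patient clustering vary enough
for the planted clustering-symptom coupling to be recoverable).

Two further ingredients make the generated cohorts behave like empirical
connectivity rather than like noiseless graph families:

* **Connectivity estimation noise.** The observed matrix is the true network
  plus dense symmetric Gaussian noise with SD `1/sqrt(T − 3)` — the sampling
  SD of a Fisher-z correlation at the configured scan length (T = 242
  volumes by default). Observed matrices are therefore dense, noisy and
  contain negative entries, as real Fisher-z connectivity does.
* **Strong long-range connections.** Rewired (long-range) edges are
  strengthened by `shortcut_strength` (default 5), making them the
  strongest entries, so they survive proportional thresholding at every
  sparsity. This mirrors empirical functional connectomes, where long-range
  (e.g. homotopic) connections are among the strongest, and it reproduces
  the empirical group signature this generator is required to emulate:
  patients' extra rewiring clearly lowers normalized clustering and
  small-worldness while normalized path length stays near 1 in both groups
  and differs only within sampling noise. A plain Watts–Strogatz family
  (uniform weights) cannot reproduce that dissociation at realistic sample
  sizes: any rewiring difference large enough to move clustering also moves
  path length detectably, because both metrics are then monotone in the
  single rewiring knob while between-subject variance stays tiny. The
  strengthened shortcuts decouple the two by pinning path length at the
  random limit for every subject. The strength default (5) and the control
  rewiring default (0.2) were calibrated jointly against this target
  pattern — clustering effects detectable at two-digit group sizes, path
  length differing only within sampling noise — and then frozen.

Symptom scores follow `round(22.3 + b·z(Cp) + e)`, where `z(Cp)` is the
patient's standardized clustering of the plain (pre-strengthening)
noise-free network — the generator's segregation variable, `b = symptom_effect`
(default −2.5 score points per SD) and `e` is Gaussian with SD `noise_sd`
(default 3). Scores are clipped to [8, 52]; the generator refuses
configurations in which more than a quarter of raw scores fall below the
floor of 8, because such a cohort would violate its own inclusion rule. The
defaults give mean ≈ 22.3 and SD ≈ 4, matching the reference cohort's
severity distribution, and plant the negative clustering-severity
correlation the downstream correlation and SVR stages are meant to recover.
Covariates (age, sex, education, mean framewise displacement) are drawn to
match the reference cohort's group summaries and are independent of
topology by construction, so covariate adjustment is exercised without
confounding.

What the generator does **not** emulate: spatial autocorrelation and
hemodynamics of real BOLD signals, realistic WM geometry, scanner- or
site-specific artifacts, and any coupling between head motion and
connectivity. Passing tests therefore demonstrate that the pipeline
recovers planted effects of realistic size and direction from data with the
assumed statistical structure — not that it would behave identically on any
particular empirical dataset.

The optional voxel-rendering path (`render_voxel_series()`) converts a
network into a 4D series on a toy mask: node-level latent signals are drawn
from a multivariate normal whose correlation is the rescaled,
positive-definite-corrected target, each parcel's voxels share their node's
signal, and i.i.d. voxel noise is added. It exists to exercise the full
parcellation → extraction → connectivity path; its empirical node
correlations converge to the target as T grows.

## Statistics

Group comparisons follow a normality-routed design: Shapiro–Wilk at
alpha = 0.05 per group (the routing rule is configurable); both groups
normal → pooled-variance t-test, otherwise Mann–Whitney U. The U statistic
is reported in the min(U1, U2) convention, with exact p values for small
tie-free groups (both ≤ 20) and the continuity-corrected normal
approximation otherwise. Covariate control for both routes is
residualize-then-test: each metric is regressed on an intercept plus age,
sex, education and mean framewise displacement over the pooled sample, and
the tests run on residuals — the conventional reading of "adjusted by"
alongside a rank test. Bonferroni correction multiplies by the number of
planned comparisons (3). The replication check is a 2 (group) × 2 (sample)
fixed-effects ANOVA on the AUC features, reporting the interaction term.

## Prediction and classification

The SVR (linear kernel, C = 1, epsilon = 0.1 — the library defaults, since
no values are specified upstream) predicts severity from the three AUC
features under unstratified random k-fold cross-validation (k = 5).
Features are standardized with training-fold statistics only; each subject
is predicted exactly once, by a model that never saw it. Performance is the
Pearson correlation of observed vs predicted scores.

The classifier addresses class imbalance by an ensemble: three trials each
draw 80% of patients and an equal number of controls, train a
sigmoid-kernel SVM (C = 1, gamma = 1/3 features, coef0 = 0), and an
external sample is labeled by majority vote (three voters, so no ties).
Feature standardization (per trial) is applied for the same
scale-robustness reason as in the SVR; both can be disabled.

## Problem sizes in the test suite

The statistical test suite runs scaled-down but structurally faithful
versions of the analysis: 64-node networks with 3 nulls per sparsity for
the 40-vs-40 group-recovery check and (with an 11-point sweep) for the
91-patient symptom-correlation check, and 128-node graphs for the random-network calibration checks (20 nulls) and
small-world detection (5 nulls). The acceptance script runs the full
pipeline at the study's sample sizes (91/225 and 34/25) on 64-node networks
with 5 nulls. These sizes were chosen so the complete suite runs on a
single CPU in minutes while keeping every statistical conclusion at
realistic power.

## Known limitations

* The generator is a one-dimensional disease model (rewiring plus its
  calibrated weight structure); real depression-related connectome
  differences are certainly higher-dimensional.
* AUC summarization inherits the usual caveat that different curve shapes
  can give equal areas.
* With small null ensembles, gamma and lambda carry Monte Carlo noise of a
  few percent; studies wanting publication-grade point estimates should use
  the default 100 nulls.
* The Mann–Whitney p value is approximate in the presence of ties (the
  exact branch requires tie-free data), matching the behavior of the
  standard R test.
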