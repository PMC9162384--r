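---
title: "Methods: multimodal regional MRI group analysis with extended-NBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal regional MRI group analysis with extended-NBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msanet)
```

# The analysis

msanet reimplements the statistical core of a case-control multimodal MRI
study design: two groups (a patient cohort with cerebellar-type multiple
system atrophy and healthy controls) are compared over a fixed 116-region
parcellation in five regional metrics — grey and white matter weighted
volume (the mean of a tissue probability map over a region), fractional
anisotropy, mean diffusivity, and tractography fiber-bundle counts — and
in region-to-region functional connectivity (Pearson correlation of
region-averaged BOLD time series). Downstream, significant features are
correlated with clinical severity (UMSARS-total) and fused per region into
feature vectors for a linear-SVM diagnostic classifier.

The pipeline assumes its inputs are already spatially normalized: atlas
and metric volumes must share one voxel grid, and no registration,
smoothing, filtering or tractography is performed here.

## Region-wise statistics

Each metric is tested per region with a two-sided pooled-variance
Student t (patients minus controls). The pooled test, rather than Welch's,
matches the "independent samples test" convention of common clinical
statistics software; Welch is available via `welch = TRUE`. Within one
metric, the 116 raw p-values form one Benjamini–Hochberg family
(`bh_fdr()`, delegating to `stats::p.adjust`), and a region is declared
significantly different when its adjusted p is strictly below
`alpha_discovery` (default 0.001). Keeping the FDR family per metric —
rather than pooling all five metrics — mirrors testing "all regions across
the whole brain" separately per feature; a joint correction can be had by
adjusting the concatenated p-vector with `bh_fdr()` directly.

Regions with fewer than two usable values in either group are excluded
with a warning and propagate as `NA`, never as silent zeros, so they
cannot bias the family size invisibly: the BH family is the set of
actually tested regions.

## Clinical correlation and outlier screening

Significant features are correlated (Pearson, two-sided) with
UMSARS-total among patients; a feature is selected when its raw p is
strictly below `corr_alpha` (default 0.001, uncorrected — the selection is
a screening step, not a confirmatory family). Before correlating, the
clinical scores are screened for outliers. The classical procedure —
inspecting a normal quantile–quantile plot — is irreproducible as stated,
so `qq_outlier_screen()` both emits the Q-Q coordinates for plotting and
applies the standard modified-z rule: flag subjects with
|x − median| / (1.4826 · MAD) > k, default k = 3.5. Manual exclusion lists
are honored on top of the automatic flags and are the only mechanism when
MAD = 0 (the rule is then disabled with a warning).

A caveat worth knowing: at n ≈ 28 the modified-z rule flags at least one
subject in roughly 10% of perfectly Gaussian samples, because the MAD is
noisy in small samples. k is therefore a screening knob, not a test with
a controlled error rate; raising k to 5 essentially silences false flags.

## Extended network-based statistics

For every unordered region pair the edge's connectivity values are
compared by the same pooled t-test, giving a symmetric "difference
network" of p-values. Edges with p strictly below the threshold form a
binary graph; its connected components (node count = component size,
isolated nodes are not components) are the candidate effects. Group
labels are then permuted — a uniform permutation of the pooled subject
list preserving group sizes, 5,000 times by default — and the full
edgewise→binarize→components chain is re-run per permutation, storing the
maximal component size. Each observed component's empirical p-value is
the fraction of permutations whose maximal size strictly exceeds that
component's size, and components with empirical p < 0.05 are significant.
The threshold ladder 0.0001…0.0010 (step 0.0001) is swept with one shared
permutation stream, so results across thresholds are nested and
comparable; `nbs_permutation_test()` is the single-threshold special case.

Two estimator details are deliberate:

* **Strict inequality.** The published formula counts permutations whose
  maximal size is *larger than* the observed size, and that is the
  default. Note what this implies under a sparse null: a lone significant
  edge (size 2) is only "beaten" by permutations reaching size 3, which
  are rare when the expected edge count is far below 1, so small
  components can reach small empirical p even in null data. The classical
  network-based-statistics convention counts ties (≥); it is available as
  `inclusive = TRUE` and restores the usual replicate-level calibration.
  The package default stays with the strict published formula; users
  running calibration studies should know the difference.
* **One shared null.** All observed components are compared against the
  same maximal-size null (only the per-permutation maximum is stored), and
  edge signs (increased/decreased connectivity in patients) are
  annotation only — components may and do mix both directions.

Ties at the edge threshold (p exactly equal) are excluded, matching the
strict inequality used everywhere else. The permutation RNG stream is
seeded independently of the data-generation streams.

## Per-region classification

A region's feature vector contains every metric significant at that
region under the looser gate `alpha_feature` (default 0.05, FDR-adjusted,
strict), in the fixed order GMV, WMV, FA, MD, fiber count, plus — when the
region belongs to a significant component at the feature threshold
(default 0.0010) — that component's edges incident to the region, ordered
by (i, j), each contributing the subject's connectivity value. Regions
with no features are unclassifiable and excluded from ranking.

Classification is a linear SVM under nested leave-one-out
cross-validation: the outer loop holds out each subject once; the inner
loop runs leave-one-out over the remaining subjects for every cost C in
{0.001, 0.01, 0.1, 1, 10, 100, 500, 1000, 5000, 10000}; the C with the
best inner accuracy is chosen, ties going to the smallest C (the
strongest regularization); the model is refit on all inner subjects and
applied to the held-out subject. Confusion counts aggregate over outer
folds with patients as the positive class; the ROC curve pools the outer
decision values (ties grouped, trapezoidal AUC, equivalent to the
rank/midpoint convention).

Standardization `(x − mu)/s` (sample SD, n−1) is fit on each outer fold's
training subjects only, so the held-out subject never touches mu, s or
the C choice. The single-pass variant — one global standardization before
cross-validation, which is how the procedure reads verbatim — is
available as `paper_literal_scaling = TRUE`; it leaks the test subject's
location into the scaler and tends to flatter estimates, which is why it
is not the default. Constant features are dropped with a warning
(s = 0); a training fold collapsing to one class is an error, not a
silent skip.

### The SVM formulation

The solver is written for determinism: the L2-regularized squared-hinge
("L2-loss") linear SVM — the default formulation of LIBLINEAR and of
scikit-learn's `LinearSVC` — with the intercept folded in as an augmented
constant (hence regularized) feature, minimized by a damped Newton method
on the generalized Hessian with Cholesky steps and Armijo backtracking.
The objective is smooth and strongly convex, the algorithm involves no
sampling or data ordering, and it converges in a few dozen iterations for
every C on the grid (relative gradient tolerance 1e-10, iteration cap
200), so a fit — and therefore the whole nested cross-validation — is
bit-reproducible. The unit tests verify the optimum against an
independent BFGS minimization of the same objective and check prediction
agreement with libsvm (e1071) on separated data. The hinge-loss (L1)
variant solved by libsvm is ill-conditioned at the large end of this C
grid on non-separable data (its dual coordinate descent does not converge
in any practical number of passes), which is the practical reason the
smooth loss is the engine here.

Decision values exactly at 0 predict the patient class; this matters only
for degenerate fits at extreme regularization.

# The synthetic cohort generator

The generator exists so that every downstream stage is testable without
patient data. It emulates, by construction:

* two groups, default 29 patients / 27 controls, 116 regions;
* independent Gaussian regional metrics per region at realistic baselines
  (GMV 0.45 ± 0.05 and WMV 0.30 ± 0.04 as probability-map means, FA
  0.45 ± 0.04, MD (8 ± 0.5)·10⁻⁴ mm²/s, fiber counts 500 ± 80), with
  planted standardized group differences (default: the cerebellar block
  91–116 loses GMV at d = −2; focal WMV loss plus one increased cerebral
  region; FA loss, MD increase and fiber-count loss over cerebellar
  subsets, the MD effect extending to two cerebral regions, all |d| = 1.5
  — effect sizes are free parameters of the generator, not estimates from
  any study, since group effect sizes are not published);
* functional connectivity generated the way real pipelines produce it:
  T = 170 multivariate-normal time points per subject (compound-symmetric
  base correlation 0.1; planted edges shifted by delta_r in patients, two
  default components mixing +0.3/−0.3), then `fc_matrix()` — matrices are
  therefore always valid correlation matrices, and infeasible plants
  (indefinite implied covariance) are rejected with an instructive error;
* clinical scores built backwards from realized features: UMSARS-total =
  34.41 + 10.1·(Σ ρ_k z_k + √(1−Σρ²)·ε) with default targets FA@107
  ρ = −0.5, FA@108 ρ = −0.5, fiber-count@96 ρ = −0.45, then split into
  UMSARS-I/II (17.34 ± 5.65 / 17.07 ± 5.66, assumed inter-part
  correlation 0.6, which fixes the total SD at ~10.1) such that
  I + II = total holds exactly per patient; ages 57.6 ± 6.0 vs
  57.4 ± 5.6; gender counts fixed at 18/11 and 11/16.

One master seed expands into per-stage child seeds (`derive_seed()`, a
Lehmer step on the seed plus a stage-name offset), so stages regenerate
individually and cohorts regenerate bit-identically.

What the generator does **not** emulate — and what green tests therefore
do not certify about real data: spatial structure and registration error
(regional metrics are independent across regions, real atrophy is
spatially correlated), heavier-tailed and heteroscedastic clinical
scores, scanner/site effects, motion artifacts, autocorrelated BOLD
noise (time points are i.i.d., so T = 170 carries more effective
information than 170 real volumes), and any coupling between modalities
beyond the planted means.

The phantom generator (`generate_phantom()`) exercises the volume-space
operations with known ground truth: an ellipsoidal mask partitioned into
contiguous nearest-seed labels, piecewise-constant metric volumes,
straight polyline streamlines, and per-region BOLD series copied to every
voxel. Streamline-to-voxel lookup is floor(p / voxel size) + 1 in a
corner-origin grid — the simplest reproducible convention — and a
streamline counts at most once per region it touches.

# Numerical and design choices

* Strict inequalities everywhere a threshold is compared (significance,
  binarization, ranking filter); ties are excluded by convention.
* Pearson correlation via `stats::cor`; constant series are errors naming
  the region, never NaN.
* Empty atlas labels yield NA entries plus a warning and are excluded
  from downstream tests.
* BH adjustment keeps NA entries out of the family.
* Region ranking orders by accuracy, then AUC, then region index; the
  "top" view keeps accuracy strictly above 0.90.
* `run_pipeline()` writes a manifest carrying every stage parameter,
  derived stage seeds and MD5 checksums of all outputs; two runs with the
  same config and seed produce byte-identical outputs (the manifest's
  timestamp aside).
* Subject exclusions (e.g. from outlier screening or a manual list) are
  applied once, before all statistics and classification, so every stage
  sees the same cohort.

## Problem sizes in the test suite

The suite validates calibration and recovery by simulation at sizes
chosen to estimate each property adequately while keeping a full run in
the low minutes: null-calibration of the permutation test uses 200
replicate cohorts of 30 regions (T = 170, 200 permutations each);
planted-component recovery uses 50 seeds of a 5-edge path (delta_r = 0.5
over an uncorrelated background — a 5-edge hub at that shift would be an
indefinite correlation matrix and is rejected by the generator);
exact-recovery of the 26-region planted GMV deficit uses 100 seeds at the
full 116-region scale; classifier chance-level behavior uses 200 seeds of
pure-noise features at the full 56-subject scale; end-to-end determinism
runs the complete pipeline twice at 30 regions with the full
5,000-permutation null. Component detection is verified exhaustively
against enumeration on all 4-node graphs and against breadth-first-search
and igraph oracles on random 8- and 116-node graphs.

# Known limitations

* The strict (>) empirical-p estimator is anticonservative for small
  components under sparse nulls (see above); use `inclusive = TRUE` for
  calibrated screening.
* Power at the study's sample size is modest for some published-style
  thresholds: a true feature-score correlation of ρ = −0.6 at n = 29 is
  selected at p < 0.001 only slightly more than half the time — the
  selection threshold is aggressive relative to the design.
* No covariate adjustment (age/sex) is implemented, matching the original
  models; group differences in demographics must be checked (and are, via
  `demographic_tests()`), not regressed out.
* The parcellation layer requires pre-aligned volumes and nearest-voxel
  streamline lookup; partial-volume weighting and anti-aliased streamline
  traversal are out of scope.
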