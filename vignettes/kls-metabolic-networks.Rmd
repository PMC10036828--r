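---
title: "Individualized metabolic brain networks: methods and design choices"
author: "klsnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized metabolic brain networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(klsnet)
```

# Overview

`klsnet` constructs a metabolic connectome for a *single subject* from a
parcellated volumetric uptake image, by comparing the probability
distributions of voxel intensities between every pair of atlas regions.
The package covers five stages — ROI extraction, similarity-network
construction, graph characterization, group statistics, and outcome
prediction — plus a synthetic-cohort simulator that exercises all of them.
This vignette records the modeling conventions and the choices made where
the design was genuinely open.

# From image to regional samples

Inputs are NIfTI volumes already registered to the template grid of the
label atlas; spatial normalization is out of scope, and
`extractROISamples()` warns when image and atlas affines disagree by more
than `1e-4`. Processing order is smoothing first, then intensity
normalization (the common preprocessing convention; the order is
configurable via the individual functions).

* **Smoothing** (`smoothGaussian()`): separable 3D Gaussian, default
  `fwhm = 6` mm, per-axis `sigma = fwhm / (2 sqrt(2 log 2)) / voxel size`.
  The boundary is constant-zero padding: mass near the edge leaks out of
  the volume rather than being reflected. This is the simplest
  well-defined convention; it is testable (interior impulses keep their
  mass to 1e-6) and configurable only through padding the input volume.
  Kernels are truncated at 4 sigma and renormalized to sum 1.
* **Global-mean normalization** (`normalizeGlobalMean()`): every voxel is
  divided by the mean over *in-atlas* voxels (nonzero label). The
  whole-brain mask is not part of the input specification, so the atlas
  support stands in for it by default; an explicit logical mask can be
  supplied. After normalization the in-atlas mean is 1 to 1e-9, and the
  operation is idempotent.
* **Extraction**: voxels are collected per region in ascending
  linear-index (column-major storage) order, so every downstream density
  estimate is reproducible. A region with zero voxels is an error, never a
  silently empty sample.

# The similarity network

For each unordered region pair the two voxel samples are pooled to define
a shared evaluation grid: 512 equally spaced points spanning the pooled
range padded by three bandwidths on each side (padding prevents truncating
either density at the support boundary; 512 points keep any similarity
value stable to < 0.01 against doubling the resolution, which is tested).
Each sample's density is estimated on that grid by Gaussian KDE and
converted to a discrete distribution: density times grid step, floored at
`1e-10`, renormalized to total 1. The floor exists because
Kullback–Leibler divergence is undefined at zero probabilities; it only
influences grid points where a density is effectively zero.
Renormalization rescales the un-floored entries, so the floor holds
exactly and the total is 1 to floating-point accuracy.

* **Bandwidth**: the default automatic rule is Silverman's rule of thumb,
  `h = 0.9 min(sd, IQR/1.34) n^(-1/5)` (`stats::bw.nrd0`). Automatic
  bandwidth selectors differ across implementations and no equivalence
  with any particular external one is claimed; the Sheather–Jones
  solve-the-equation bandwidth (`bwMethod = "SJ"`) is available as a
  second, more adaptive automatic mode. For unimodal,
  roughly Gaussian regional distributions the two agree closely. A
  zero-variance sample falls back to `h = max(1e-6, 1e-3 |v|)` so a
  degenerate region cannot abort network construction.
* **Divergence**: the symmetric form `KL(P,Q) + KL(Q,P)` in natural
  logarithms (nats keep `exp(-KL)` scale-consistent), computed as
  `sum((P - Q)(ln P - ln Q))`, which is bitwise symmetric in its
  arguments. The edge weight is `KLS = exp(-KL)`, in `(0, 1]`, exactly 1
  for identical distributions.
* **Diagonal**: fixed at 0. Self-similarity is trivially 1 and plays no
  role in any graph analysis, so self-loops are excluded at the source.

# Graph characterization

Networks are thresholded across a sparsity sweep (default 0.02–0.50 in
steps of 0.01, 49 points): at sparsity S the strongest `round(S R(R-1)/2)`
connections keep their weights and the rest are zeroed. Ties at the cutoff
are broken by (strength descending, row, column) so the retained edge set
is deterministic. At S = 0.02 a 90-node network has only 80 edges and is
necessarily fragmented; path-based metrics therefore average over
*connected* pairs only (disconnected pairs contribute 0 to efficiency, and
are excluded from the characteristic path length).

The toolbox-style weighted conventions are fixed as follows, each verified
against an exhaustive brute-force implementation on small fixtures to
1e-9:

| metric | convention |
|---|---|
| Cp | Onnela geometric-mean triangle clustering on weights rescaled by the network maximum; nodes with binary degree < 2 contribute 0 |
| Lp | mean shortest-path length over connected pairs, edge length `1/w` |
| Eglobal | mean of `1/d` over all pairs |
| Elocal | mean efficiency of each node's neighbour subgraph |
| Q | modularity of the partition found by greedy modularity optimization on the weighted graph |
| Ar | Pearson correlation of endpoint strengths across edges (both orientations) |
| Hr | exponent β of `log C_i ~ -β log k_i` over nodes with `k > 1` and `C_i > 0` |
| Sr | Laplacian eigenratio `λ2/λmax` of the binarized graph |
| γ, λ, σ | `Cp/Cp_rand`, `Lp/Lp_rand`, `γ/λ` against degree-preserving nulls |

Null networks (default 100 per threshold) are generated by double-edge
swaps that preserve the exact binary degree sequence (at least 10 attempted
swaps per edge), with the original weights randomly permuted onto the
rewired topology. Each null's seed is derived from the analysis master
seed by a fixed offset, so entire runs are reproducible. A z-scored
summary `(metric − mean_null)/sd_null` is available for any metric with a
null distribution.

Every metric is summarized over the sweep by a *mean-height* area under
the curve: the trapezoidal integral divided by the sweep range, keeping
the AUC on the metric's own scale. AUC conventions vary across studies
(plain integrals, range-normalized means, per-metric rescalings); this
one convention is applied uniformly to all metrics and no cross-study
scale equivalence is claimed. Metrics undefined at some thresholds (hierarchy on triangle-free
sparse graphs, assortativity with fewer than two edges) yield `NA` AUCs
and are excluded from group comparisons rather than imputed.

# Group statistics

Feature-wise comparison (`edgewiseComparison()`) residualizes each feature
on age and sex across the pooled sample, then applies a pooled-variance
two-sample t test with degrees of freedom reduced by the number of
estimated covariates (`n_A + n_B − 2 − k`), followed by Benjamini–Hochberg
FDR. Welch's form is available by option. Edges (R(R−1)/2 features), nodal
metrics, and global metrics are corrected as *separate families* — the
conservative reading of per-analysis reporting; a single pooled family
would mix scales and effect structures. Constant covariate columns are
absorbed by the intercept rather than raising an error, so the procedure
reduces exactly to an unadjusted t test when covariates carry no
information.

# Survival prediction

The linear SVR minimizes `½‖w‖² + C Σ max(0, |y_i − wᵀx_i| − ε)²` — the
L2-regularized squared ε-insensitive loss, with no bias term (the features
and outcome are centred by the deconfounding step, which makes an
intercept redundant). Defaults `C = 1`, `ε = 0.1` are the conventional
linear-SVR tool defaults; no tuning is performed anywhere. The objective
is smooth and convex and is minimized by BFGS with an analytic gradient
from a ridge warm start; tests verify the optimum against the closed-form
least-squares limit (large C, ε = 0) and against random local
perturbations.

Leave-one-out cross-validation re-estimates, inside every training fold:
(1) deconfounding regressions of features and outcome on age and sex, with
the training-fold weights applied unchanged to the held-out patient;
(2) feature selection — the connections significantly different between
the training-fold patients and *all* controls at level α (FDR-corrected by
default); (3) per-feature z-scaling. A leakage instrumentation test
verifies that perturbing a held-out patient's outcome cannot change that
fold's trained weights. A fold selecting zero features predicts the
training-fold mean outcome.

Two open readings were resolved as follows:

* **Feature-selection placement.** Selecting connections once from all
  patients before cross-validation is the literal reading of the published
  procedure but leaks the held-out patient into selection; per-fold
  selection is the default here, with `selection = "fixed"` reproducing
  the literal reading for comparison.
* **Correlation scale.** Predicted and observed survival are compared on
  the deconfounded scale (each patient's observed value residualized with
  their fold's training coefficients). Comparing on the raw scale would
  let the shared age/sex component — present in both the covariate-based
  part of a prediction and the observed outcome — generate spurious
  correlation under the connectivity null, and the permutation test would
  then be anticonservative. Raw-scale predictions (`rawPredicted`, months)
  are returned alongside for clinical interpretation.
* **Permutation mode.** The permutation test (`p = (1 + #{r_perm ≥
  r_obs})/(n_perm + 1)`, add-one so p is never 0) offers a fast mode that
  re-pairs the fixed predictions with shuffled outcomes (practical at
  10,000 permutations) and a full mode that re-runs the entire
  cross-validation per permutation. Because cross-validated predictions
  share training data with every outcome, the fast mode's null is
  slightly wide; the full mode is the calibrated reference and is what
  the package's calibration tests use.

Connection weights are averaged across all folds (zero where a fold did
not select the connection) and aggregated into six lobar groups — frontal,
temporal, parietal, occipital, central structures, insula-and-cingulate —
by adding each connection's absolute mean weight to both endpoint lobes.

# The synthetic cohort simulator

`simulationConfig()` defaults encode the reference study conditions: 78
patients, 60 controls, 90 regions. Two generators share the demographic
and outcome model (age uniform 45–75; sex Bernoulli 0.35; survival in
months = mean 16 + age/sex confounding + connection coupling + Gaussian
noise, truncated below at 1 month, matching an advanced-cancer cohort's
observed floor):

* **Voxel level** (`simulateROISamples()`): each region draws
  `voxelsPerRegion` (default 300, a realistic parcel size at 2 mm
  resolution) Gaussian voxel values; a planted edge `(i, j, d)` shifts
  region j's mean by `d` standard deviations in patients, which moves the
  pair's similarity relative to controls.
* **Direct matrices** (`simulateConnectivityDirect()`): edge weights drawn
  logit-normal in (0, 1) (respecting the similarity range); planted
  effects are applied on the similarity scale, either as `d` times the
  edge-level sd (computed by numerical integration of the logit-normal
  moments) or as an explicit raw `shift`, clamped into (0, 1). This mode
  exists because voxel-level simulation of full cohorts is orders of
  magnitude more expensive and the statistical and predictive stages only
  consume matrices.

What the simulator does *not* emulate: spatially correlated noise,
partial-volume effects, scanner or acquisition physics, censored
follow-up, and realistic inter-regional dependence of uptake
distributions (edges are independent given group). Passing tests
therefore certify the pipeline's statistical machinery — calibration,
power at designed effect sizes, absence of leakage, determinism — not its
behaviour on real PET cohorts.

# Problem sizes and reproducibility

The test suite runs the structural checks at full reference scale (90
regions, 78/60 subjects for the matrix-level stages; 90-region voxel
networks are built with 60 voxels per region), statistical calibration at
100–200 replicates with reduced region counts (4–20 regions), and oracle
equivalence on ≤ 10-node fixtures — sizes chosen so the whole suite
completes in a few minutes while keeping every Monte-Carlo margin
comfortable. All randomness flows from explicit seeds: the simulators
re-seed from their config, null-network and permutation seeds derive from
a master seed by fixed offsets, and byte-identical regeneration of an
entire cohort plus downstream outputs from one (config, seed) pair is
itself a test.

# Known limitations

* KLS compares marginal intensity *distributions*; two regions with
  identical histograms but different spatial patterns are maximally
  similar. This is intrinsic to the method, not an implementation limit.
* Exact numerical equivalence with the MATLAB toolboxes commonly used for
  such analyses (GRETNA-style weighted metrics, public kernel-density
  estimators) is not claimed; each convention is instead pinned by its own
  oracle tests.
* Overall survival is treated as a fully observed continuous outcome; no
  censoring model is provided.
* The greedy modularity optimizer is deterministic but not guaranteed
  globally optimal on large graphs; on test fixtures with unambiguous
  structure it attains the exhaustive optimum.
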