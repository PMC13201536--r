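---
title: "Quantifying skin tissue architecture with skinarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying skin tissue architecture with skinarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinarch)
```

# The problem

Healthy skin is a polarized, layered tissue: the epidermis sits on a
undulating dermal–epidermal interface whose upward projections (dermal
papillae, flanked by epidermal rete ridges) carry capillaries and
nerve endings; the papillary dermis directly below has a distinct
fibroblast repertoire from the deeper reticular dermis. Fibrotic
remodeling flattens this interface, depletes superficial vessels and
aligns collagen fibers. `skinarch` quantifies these architectural
features from two kinds of input: segmented single-cell spatial data
(per-cell coordinates plus counts or intensities) and annotated
histology (interface contours, fiber orientation angles).

All coordinates are in micrometers with **depth increasing downward**
from the skin surface; this matches "distance from the epidermal basal
membrane" semantics throughout.

# Models and procedures

## Normalization

Counts from imaging-based spatial transcriptomics are normalized by a
shifted logarithm, `ln(1 + x * s / total)` with scaling factor
`s = 300`: per-cell totals are rescaled to a common value before
`log1p`, making profiles proportion-invariant. Mass-cytometry
intensities use `asinh(x / cofactor)` with cofactor 1, followed by a
feature-wise z-score against the whole dataset and — for fibroblast
subclustering — a second z-score restricted to the fibroblasts.
Z-scores use the unbiased (n−1) standard deviation; per-sample scaling
is applied by passing a grouping factor. A zero-variance feature in
the reference is an error rather than a silent NaN.

## Phenotyping

The gating hierarchy evaluates rules in a fixed order: epithelial
(E-cadherin+), immune (CD45+, E-cadherin−), endothelial (CD31+,
E-cadherin−), vascular smooth muscle (SM22^high, αSMA^high,
E-cadherin−), with fibroblasts as the residual, so the five labels
always partition the cells. Thresholds on z-scored intensities default
to z > 0 for "+" and z > 1 for "high" — the tails of a standardized
intensity distribution — and are configurable per condition.

Unsupervised subclustering builds the exact Euclidean knn graph and
runs Leiden modularity optimization. **Resolution default:** we use
0.1, not the optimizer-conventional 1.0. At resolution 1 the
modularity optimum fragments even a perfectly homogeneous,
well-separated group into several communities (a well-known property
of modularity on knn graphs); at 0.1, disconnected homogeneous groups
are returned whole while well-separated mixtures are still recovered
exactly, which is the behavior the pipeline's contracts require.
Merging of near-duplicate communities is deliberately manual (a
`merge_map` argument), mirroring curation practice. Label transfer
between datasets is a k = 10 majority vote in the shared marker space;
ties break to the lexicographically smallest label and are flagged.

## Compartments and papillary vessels

The epidermal layer is detected as connected components of
keratinocytes (linkage radius 30 µm, configurable; the radius is not
printed in the source method and 30 µm ≈ 2–3 cell diameters) with at
least 10 members, keeping the components whose mean depth is above the
mean depth of the dermal cells — this excludes mid-dermal hair
follicles. Every other cell's distance to the epidermis is the
Euclidean distance to the nearest epidermal member cell (a documented
approximation of distance to the basal membrane; with compactly packed
keratinocytes the approximation error is a few micrometers). Cells
closer than 100 µm are papillary, all others reticular; **the boundary
value 100 µm itself is reticular** (the source rule leaves the tie
open; we document "strictly less than 100" as papillary).

Vessel patches are connected components of a knn-reachability graph
(k = 10) over the papillary endothelial cells, keeping components with
at least 3 cells. We additionally require linked cells to lie within
30 µm of each other: a pure rank-based knn rule has no length scale,
so two small vessels would be linked no matter how far apart they are;
"neighborhood" in the source method implies spatial proximity, and the
cap makes small-patch detection scale-aware. Patch orientation is the
first principal component of member coordinates versus the first
principal component of the epidermal points within 200 µm of the patch
centroid (papillae-scale locality; the global epidermis axis is the
documented fallback, with a warning, when no local points exist). The
reported angle is the acute angle between the two axes, in [0°, 90°],
and patches at **strictly more than 45°** are flagged perpendicular —
the hallmark of papillary capillary loops. PCA on 2-D coordinates is
exactly the total-least-squares line fit, and the test suite
cross-checks it against an independent TLS oracle.

Response maps use isotropic Gaussian kernels (bandwidth 50 µm, grid
10 µm — unstated in the source; 50 µm is papilla-scale smoothing) on a
grid padded by 4 bandwidths so the Riemann sum recovers the total
weight.

## Signature scores

The treatment response score regresses a cell's normalized expression
on the signature's log2 fold-change weights (ordinary least squares
with intercept) and reports the slope's t-statistic. When one
signature is scored, the "multivariate linear model" of the source
framework reduces to exactly this univariate regression, and the
t-statistic is that family's documented estimator. The score is
invariant to positive affine transformations of the weights,
antisymmetric under negation, and saturates at ±1e6 (flagged) when the
fit is exact. Signatures keep DEGs with adjusted p < 0.05 and use
log2FC as weights.

Module scores compare the mean expression of a gene set to bin-matched
controls (25 equal-frequency average-expression bins, 100 controls per
set gene — tool-family defaults; the source does not state them).
Controls are sampled from the set genes' bins *excluding the set
itself*; undersized bins are sampled with replacement and warned
about. AUCell scores a profile by the area under the set-recovery
curve within the top 5% of the ranking (configurable; the source's
maxRank is not printed), normalized by the maximum attainable area,
with ties broken by gene name for determinism.

Preranked GSEA uses the weighted Kolmogorov–Smirnov statistic (hit
increments ∝ |stat|^p, p = 1 by default; miss decrements
1/(G − |S|)). The null permutes gene labels — phenotype permutation is
not available at cell level — and the p-value is the +1-corrected
same-sign tail; NES divides the ES by the mean |ES| of same-sign
permutations, and batch FDR follows the same-sign pooled-NES
procedure. The implementation computes ES from hit positions in
O(|S|) per permutation and is verified against an O(G) cumulative-walk
oracle.

## Compositional contrast

Cell-type proportion shifts between conditions use a simplified
Bayesian stand-in for beta-binomial compositional regression: per
posterior draw, samples are bootstrap-resampled within each condition,
a Dirichlet(counts + 1/2) is drawn per selected sample (Jeffreys
prior), and sample-level proportions are averaged. This captures both
multinomial noise and between-donor variability without a
probabilistic-programming runtime; it does not reproduce the exact
posterior of the original mixed-effects model, but shares its decision
rule: effect = posterior mean of `logit π_b − logit π_a` (the **logit
scale is this package's convention** for the ±0.1 minimum effect,
since the original model's internal parameterization is not printed),
q from the running mean of sorted tail probabilities
`P(|Δ| ≤ 0.1)`, and a significant call requires q < 0.05 *and*
|effect| > 0.1. Calibration (null false-call rate ≤ 7%) and coverage
of planted shifts are tested explicitly.

## Morphometry

Papillae per mm is the apex count over the section width; the papilla
base is the line through the two flanking rete-ridge vertices and the
height is the apex's perpendicular distance to that infinite line
(`|cross| / |base|`). The collagen alignment coefficient is the
circular resultant of doubled angles,
`c = sqrt(mean(cos 2θ)² + mean(sin 2θ)²)`; the exact formula of the
curvelet tool that inspired it is not published, so this definition is
adopted as a convention validated by its endpoints — 1 for perfect
parallelism, 0 for isotropy — and by the closed form
`E[c] = I1(κ)/I0(κ)` for von Mises-distributed doubled angles.
Per-section summaries report the median across regions of interest,
matching the 3-ROI measurement design. Fiber extraction itself is out
of scope: angles enter as data.

## Spatial ligand–receptor scores

For each ordered source/target type pair (both with ≥ 10 cells) and
each ligand–receptor pair, expression is summarized by the truncated
mean (10% at both ends) and the score is the ligand × receptor
product, emitted as nonzero only when at least one source–target cell
pair lies within the mode's cutoff (250 µm secreted, 20 µm contact).
This is a documented simplification of the Hill-function mass-action
model of the original framework; the admissible-pair fraction is
reported so users can filter by spatial support. "At least 10 cells"
is interpreted as per-type totals (the source wording is ambiguous).

# The synthetic tissue generator

The generator emulates exactly the structure the analysis assumes: an
epidermis band above a sinusoidal interface
`y = e + A sin(2πx/P)` (defaults e = 40 µm, A = 30 µm, P = 250 µm —
papillae of realistic 30 µm amplitude every 250 µm), uniform cell
placement per compartment with exact per-type counts (so planted
composition equals empirical frequencies identically), vessels as
elongated endothelial point clouds (cells evenly spaced along the axis
with 2 µm longitudinal and 1.5 µm perpendicular jitter, giving the
high aspect ratio of capillary sections), negative-binomial expression
(mean 2, dispersion 2 — sparse, overdispersed imaging-assay counts)
with multiplicative marker enrichments and a planted two-fold
(±1 log2) treatment shift, and Poisson negative controls at rate 0.05.
Everything is deterministic given the seed.

What it does **not** emulate: segmentation artifacts (overlapping or
fragmented cells), doublets, ambient transcripts, batch effects beyond
per-sample scaling, or pixel-level image content. A green test on
synthetic tissue therefore establishes algorithmic correctness against
known geometry and planted effects — not robustness to segmentation
error, which is upstream of this package's inputs.

# Numerical choices and degenerate inputs

- Patch angles are snapped at 1e-9 degrees so constructed exact-45°
  patches are not flagged by floating-point noise; the flag uses a
  strict inequality.
- Zero-total cells are an error in shifted-log normalization (named in
  the message); the QC filter removes them first in the normal flow.
- A tie in knn label transfer is resolved lexicographically and
  flagged rather than broken at random.
- Dirichlet draws use `rgamma` with shape ≥ prior = 1/2, so posterior
  proportions are almost surely positive and logits finite.
- `detect_vessel_patches` returns an empty list (not an error) when
  fewer than `min_size` cells are supplied; `detect_epidermis` errors
  when no qualifying patch lies above the dermis.
- The von Mises sampler is Best–Fisher rejection; κ = 0 falls back to
  the uniform distribution exactly.

# Known limitations

- Distance-to-epidermis uses member cells, not a fitted basal
  membrane; with sparse keratinocytes the measured distance is biased
  upward by roughly the inter-cell spacing.
- The compositional contrast approximates, and is not exchangeable
  with, the original beta-binomial random-intercept posterior; only
  the decision rule is shared.
- Gene-permutation GSEA p-values are discrete (resolution
  1/(n_perm + 1)) and less conservative than sample permutation when
  genes are co-expressed.
- The ligand–receptor score has no significance machinery; it is a
  descriptive, spatially masked summary.
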