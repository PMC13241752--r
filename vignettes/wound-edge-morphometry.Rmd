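---
title: "Quantifying wound-edge morphology in a standardized band"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying wound-edge morphology in a standardized band}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periwound)
```

## The problem

Clinical scoring of chronic wounds includes an "edge" item: the border is
classed as indistinct, attached, not attached, rolled-under, hyperkeratotic
or fibrotic. The call is made by eye from a two-dimensional photograph and
is notoriously variable between clinicians. `periwound` implements an
image-analysis pipeline that makes the edge quantitative: given a
photograph, a binary wound mask and a monocular depth map, it standardises
the peri-wound region geometrically, extracts a depth profile across the
border, summarises that profile with a small set of trend templates, and
derives per-wound descriptors that feed two kinds of evaluation —
unsupervised grouping of wounds by edge geometry, and supervised
reproduction of raters' labels. Because rolled-under and fibrotic edges are
hard to tell apart on photographs, the package works throughout with the
merged five-category vocabulary (`mergedCategories()`); `mergeCategories()`
performs the collapse on a raw six-category annotation table.

Segmentation and depth estimation themselves are out of scope: masks and
depth maps are inputs, produced upstream by whatever segmentation and
monocular-depth models are in use.

## The standardisation model

Wound contours are irregular, so profiles taken at different border
locations or on different wounds are not directly comparable. The package
resolves this with *rectification*:

1. `largestComponent()` keeps the single largest 8-connected mask component
   and fills interior holes.
2. `transitionBand()` builds the peri-wound annulus
   `dilate(mask, d_out) \ erode(mask, d_in)` with disk structuring elements.
3. `extractContour()` traces the border at the 0.5 iso-level of the lightly
   smoothed mask and resamples it to `K` points equally spaced in arc
   length, with outward unit normals.
4. `detrendDepth()` removes a least-squares plane `z = ax + by + c` from the
   depth map, so overall wound orientation relative to the camera does not
   masquerade as edge relief.
5. `rectifyBand()` samples the detrended depth (and the RGB image) at
   `p_k + delta * n_k` for `delta = d_out, ..., 0, ..., -d_in`, producing a
   `K x (d_in + d_out + 1)` rectangle in which every row crosses the border
   at the same column and columns run from outside the wound to inside.

`aggregateProfile()` then takes the per-column median over rows — one
robust outside-to-inside depth trace per wound — and
`normalizeProfile()` subtracts the outer-end value and divides by the
robust amplitude (90th minus 10th percentile), making later steps invariant
to depth offset and positive scaling.

### Trend templates

`fitTemplates()` summarises a normalized profile with four trends:

* **flat** — constant `c` (1 parameter);
* **linear** — `alpha + beta * delta` (2 parameters);
* **abrupt** and **smooth** — logistic steps
  `A / (1 + exp(-(delta - delta0)/w)) + c` (4 parameters), split by the
  fitted transition width: `w <= w_abrupt` reads as a step, `w > w_abrupt`
  as a gradual transition.

The winner minimises `BIC = n log(RSS/n) + p log(n)`. Logistics are fitted
by bounded Levenberg–Marquardt least squares from a fixed 3 x 3 multi-start
grid (three `delta0` positions x three widths), which makes the fits
bit-reproducible. Two constraints encode the domain: all four trends
describe a *descent* from peri-wound skin into the wound bed, so the linear
slope and the logistic amplitude are constrained non-ascending inward
(`beta >= 0`, `A >= 0`). Without this, about 6% of genuinely flat profiles
are stolen by a noise-fitted trend (for the linear template this is exactly
`P(F(1, n-2) > (n^{1/n}-1)(n-2))`, about 6% at profile length 41); with it,
flat recovery on pure noise is ~97% while recovery of true trends is
unaffected, since real profiles descend by construction.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `dIn`, `dOut` | 20 px | band half-widths inside/outside the border; the profile has `dIn + dOut + 1` samples at 1 px spacing |
| `K` | 360 | contour samples (rows of the rectified band) |
| `wAbrupt` | 3 px | logistic width separating abrupt from smooth; 3 px is well below half the default band so a sub-resolution transition reads as a step |
| `epsFlat` | 1e-6 | robust-amplitude threshold (depth units) below which a profile is degenerate-flat and only offset-corrected |
| `detrendRegion` | `"band"` | plane fitted over the transition band (skin orientation dominates; crater depth does not bias the fit); `"full"` uses the whole raster |
| `k` | 5 | cluster count for the unsupervised experiment; 5 matches the merged vocabulary so the post-hoc comparison is one-to-one |
| `folds`, `repeats` | 5, 10 | repeated stratified cross-validation scheme |

The band width is deliberately a configuration parameter: it is not fixed
by any published protocol, and the defaults correspond visually to a
~40 px band on 1440 x 1080 photographs, scaled down proportionally for the
synthetic frames used in the tests.

## Descriptors

Two named groups support the geometry-versus-appearance comparison:

* **geometry** (`geometricFeatures()` + `profileFeatures()`): area,
  perimeter, circularity `4 pi A / P^2`, solidity, eccentricity, border
  irregularity (perimeter over convex-hull perimeter), radial-distance
  coefficient of variation; winning template (one-hot), logistic step
  location/width/amplitude, per-template residuals, gradient statistics,
  inside-minus-outside mean, rim prominence, raw profile amplitude.
* **visual** (`visualFeatures()`): per region (wound bed = mask eroded by
  `dIn`; inner band; outer band) mean/SD of R, G, B and of hue (circular
  statistics), saturation, value, plus a redness index `R/(R+G+B)`;
  texture on the grayscale rectified band via gray-level co-occurrence
  contrast/homogeneity/energy/correlation (32 levels, offset 1 px along the
  band) and gradient-magnitude mean and entropy.

This explicit, auditable list stands in for feature sets whose exact
composition is typically not published; it covers the three axes that
matter clinically — wound shape, colour appearance and surface pattern.

## The two experiments

**Unsupervised.** `profileMatrix()` concatenates the normalized profile
values with the template parameters and residuals; `reduceEmbedding()`
(PCA by default, a deterministic Laplacian-eigenmap neighbour embedding as
the alternative) and `clusterEmbedding()` (k-means++ with 10 restarts)
group the wounds with no access to labels. `evaluateUnsupervised()`
compares the groups post hoc with each rater: clusters are matched to
categories by exact optimal assignment (`alignLabels()`, enumeration over
injective mappings — exact, not greedy, and cheap at k <= 6), then Cohen's
kappa is computed on the relabeled clusters; the Adjusted Rand Index needs
no matching. The headline ARI is reported against a configurable reference
rater (the first, by default), since a single-number ARI must pick one
annotation set.

**Supervised.** `trainEval()` trains one classifier per rater
(gradient-boosted trees by default, random forest as the alternative) on
that rater's labels under repeated stratified cross-validation; per repeat,
pooled out-of-fold predictions give one kappa value, and class-weighted
loss plus stratification handle imbalance without resampling. Geometry-only
and full-feature runs with the same seed share identical fold assignments.
`compareFeatureSets()` applies the pooled two-sample Student's t-test to
the two sets of per-run kappa values.

A caveat the package is explicit about: within one dataset, repeated-CV
kappa values are *correlated* (they reuse the same rows), so the per-run
t-test is anti-conservative and will flag small systematic finite-sample
differences. The package's own null check therefore replicates the whole
comparison over independent seeds and tests the per-seed differences
against zero; the per-run test is reserved for effects large enough to
dwarf this caveat.

## The synthetic generator

`generateScene()` builds wounds whose ground truth is known — something no
clinical dataset provides. The contour is a radial-Fourier perturbation of
a circle, `rho(theta) = r0 (1 + sum a_m cos(m theta + phi_m))` (harmonics
2–5, amplitudes up to 0.06). Depth is
`g_x x + g_y y + crater(s) + N(0, sigma)` with `s` the signed distance to
the contour and `crater` one of five archetype profiles
(`craterFunction()`): a shallow wide ramp (indistinct), a linear ramp
(attached), an abrupt logistic drop (not attached), a raised rim just
outside the border (rolled/fibrotic), and an elevated plateau over a thick
outer band (hyperkeratotic). The planar tilt exercises detrending; colours
separate a reddish bed from skin-toned surroundings, with a whitened
callus ring and per-archetype texture noise; `colourArchetype` lets colour
and geometry be decoupled, which is how the package constructs datasets
where appearance carries label information that geometry does not (and
vice versa). Crater parameters default to archetype-specific values with
+/-10% per-scene jitter; all randomness flows through the seed and
regeneration is bit-exact.

`annotatorModel()` and `simulateAnnotations()` add raters defined by
confusion matrices, and `expectedKappa()` gives the exact closed-form
agreement implied by two confusion matrices and a truth prior — the oracle
against which simulated agreement is tested (Monte-Carlo error at
n = 10000 is well within the 0.03 tolerance used).

What the generator does *not* emulate: perspective and lens distortion,
lighting gradients, specular highlights, depth-estimation artefacts
correlated with appearance, anatomical context, multiple wounds, and the
label noise structure of real clinicians (real disagreement is not a
symmetric uniform confusion). Passing tests therefore demonstrate that the
pipeline is correct and that its statistics behave as designed — not that
clinical edge categories are recoverable from real photographs; on the
study that motivated this package the correspondence between geometry-only
groups and clinical labels was in fact near chance.

## Numerical choices

* **Coordinates.** Pixel centres at integer (row, col), `x = col`,
  `y = row`, 1-based (R convention). The rectified band's border column is
  `dOut + 1`.
* **Contour.** The 0.5 iso-level is traced on the mask after a sigma = 1 px
  Gaussian blur, then densely resampled (4K points), position-smoothed with
  a 9-point circular moving average, and finally resampled to K uniform
  points. The blur and smoothing remove the pixel staircase (a raw
  marching-squares trace overestimates a disk's perimeter by ~5%); the
  light touch keeps square corners within the 5% perimeter tolerance.
  Binary rasterization still leaves ~ +/-0.15 px radial jitter, so columns
  of the rectified band are constant to ~1% of crater amplitude only for
  transitions a few pixels wide or wider; the location of steeper
  transitions is accurate but their rectified spread is limited by
  half-pixel contour localisation.
* **8-connectivity** for components (diagonal contact connects), disk
  structuring elements, ties in `largestComponent()` broken by the
  lexicographically smallest (row, col) pixel.
* **Degenerate inputs.** Empty masks, border-contact components,
  annihilating erosions, collinear detrend regions and sub-50% valid band
  coverage are errors with actionable messages; out-of-frame band samples
  are flagged invalid, not fatal; empty colour regions yield zero sentinels
  with a warning.
* **Determinism.** Every stochastic step (scene generation, rater
  simulation, k-means restarts, fold assignment, classifier training) is
  seeded; template fits use fixed multi-start grids; PCA and eigenmap signs
  are fixed by convention.
* **Agreement edge cases.** Kappa is undefined when both raters are
  constant and equal (error); the SD over a single rater pair is 0 by
  convention; sample SD (ddof = 1) is used over rater pairs and runs.

## Problem sizes used by the test suite

Unit and acceptance tests generate scenes at 160 x 160 px with r0 = 40,
dIn = dOut = 12 and K = 180 — the same geometry as the 512-px defaults at
~1/3 scale. End-to-end recovery runs on 500 archetype-balanced scenes;
template recovery uses 200 profiles per template at noise sigma = 0.05;
agreement oracles use n = 10000 simulated items. On this synthetic,
fully separable material the unsupervised pipeline reaches mean kappa ~1
and the supervised models kappa >= 0.95, which is the designed behaviour:
near-zero agreement observed on clinical data is then attributable to the
data, not to the pipeline's construction.

## Known limitations

* All sizes are in pixels; physical calibration from rulers or colour
  cards is out of scope.
* One wound per image; multi-component masks are reduced to the largest
  component.
* Monocular depth is relative, so depth-derived features are scale-free
  by normalization rather than metrically calibrated.
* The visual descriptor set is fixed and explicit; learned embeddings are
  deliberately excluded.
* `alignLabels()` enumerates assignments and is intended for small
  category counts (k <= ~8).
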