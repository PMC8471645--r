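---
title: "Methods: inter-scan reproducibility of 3D segmentation shape features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inter-scan reproducibility of 3D segmentation shape features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(maskrepro)
```

## The problem

When the same patient is scanned twice within a short interval, the prostate
gland has not biologically changed, so any variation in morphological
measurements extracted from the two segmentations reflects measurement
error: scanner positioning, probe-induced deformation, slice placement, and
— most importantly for automated pipelines — the behaviour of the
segmentation method itself. Test–retest reproducibility of radiomics shape
features is therefore a practical proxy for the reproducibility of the
segmentation masks, and a prerequisite for using features such as gland
volume (and the PSA density derived from it) in longitudinal clinical
decisions.

`maskrepro` implements the full analysis chain for such a paired two-scan
design: label-map I/O and region handling for a whole gland (WP) split into
a peripheral zone (PZ) and the remaining zones (non-PZ); largest-component
post-processing; extraction of 14 morphological shape features in physical
units; and the agreement statistics — Dice similarity (DSC), two-way random
single-score intraclass correlation ICC(2,1) with 95% confidence intervals,
Bland–Altman limits of agreement, paired Wilcoxon tests with
Benjamini–Hochberg correction, Spearman correlation, and a permutation test
for quality-control-based cohort filtering. Because clinical two-scan
datasets are rarely shareable, the package also contains a synthetic cohort
generator that reproduces the statistical structure of the design, so that
every stage is testable end to end.

## Label conventions and post-processing

A `label_volume` is a 3D integer grid in slice × row × column order with
values 0 (background), 1 (PZ) and 2 (non-PZ); WP is the union of the two
zones, so the foreground counts always satisfy |WP| = |PZ| + |non-PZ|.
NIfTI-1 files are read through RNifti, reoriented to a canonical RAS
orientation from the header affine, with spacing taken from `pixdim`.
Methods that predict WP and PZ independently are composed by
`compose_label_volume()`: PZ voxels outside WP are clipped (the conservative
set-difference reading), and non-PZ = WP minus PZ.

Post-processing retains only the largest 3D connected component at
26-connectivity (voxels sharing a face, edge or corner are neighbours). It
is applied per zone — cleaning PZ and non-PZ separately and re-deriving WP
by merging — because cleaning WP directly could retain a PZ satellite glued
to non-PZ. Ties between equal-sized components are broken deterministically
in favour of the component containing the lexicographically smallest
(slice, row, column) index.

## Shape features

The 14 features of `extract_features()` fall into three groups.

**Moment-based.** The eigenvalues λ₁ ≥ λ₂ ≥ λ₃ of the population
(divisor-N) covariance of the foreground voxel-centre coordinates give the
axis lengths 4√λᵢ, elongation √(λ₂/λ₁) and flatness √(λ₃/λ₁). For a uniform
solid ellipsoid with semi-axes (a, b, c) the eigenvalues are a²/5, b²/5,
c²/5, which the tests use as an analytic oracle. Rank-deficient masks give
zero lengths; a single voxel leaves elongation and flatness undefined
(reported as `NA` with a warning).

**Mesh-based.** Mesh volume (by signed tetrahedra against the origin —
the divergence theorem), surface area (cross-product triangle areas),
sphericity (36πV²)^⅓ / A, and the surface-area-to-volume ratio.

**Diameters.** The maximum pairwise Euclidean distance between mesh
vertices in 3D and in each image plane (the "slice" diameter ignores the
slice coordinate, and analogously for row and column). The in-plane
maxima are found exactly by restricting to the 2D convex hull; the 3D
maximum by an exact KD-tree branch-and-bound, seeded with a
farthest-point/direction-grid lower bound.

### Mesh construction

Surface meshing of a binary mask is the one step with real numerical
freedom, and the naive choice fails quantitatively: an iso-surface
extracted directly from the 0/1 voxel field inherits the staircase of the
voxel grid and overestimates the surface area of a digitized sphere by
about 8%, which propagates into sphericity and the surface-area-to-volume
ratio. `build_mesh()` therefore:

1. crops the mask to its bounding box plus a fixed pad and smooths the
   binary field with a small separable Gaussian (σ = 0.7 voxels,
   truncated at 3 voxels). σ is deliberately fixed in *voxel* units, not
   mm, so that rescaling the spacing rescales every feature exactly
   (volumes × s³, areas × s², lengths × s) — a property the test suite
   asserts at 10⁻⁹ relative tolerance;
2. extracts the 0.5 iso-surface by marching tetrahedra on the Kuhn
   six-tetrahedra decomposition of each grid cube, with linear
   interpolation along tetrahedron edges. Because adjacent cubes share
   face diagonals in this decomposition, the triangulation is conforming
   and the mesh is closed and watertight *by construction* — there are no
   marching-cubes face ambiguities to resolve. Interpolation weights are
   clamped to [10⁻⁶, 1 − 10⁻⁶] so no triangle degenerates to zero area;
3. applies 10 iterations of Taubin λ|μ smoothing (λ = 0.5, μ = 0.53),
   which removes the residual triangulation bumps without the volume
   shrinkage of plain Laplacian smoothing.

With this pipeline, on a digitized r = 10 mm sphere at 0.5 mm spacing the
enclosed volume, surface area and diameters are recovered to well under
1%, 2% and 2% respectively, and sphericity lands just below 1 — the
acceptance tests recompute these numbers on every run. Masks too small to
survive the Gaussian kernel (a single voxel, say) fall back to meshing the
raw binary field so the pipeline never crashes on simulated failures.

Diameters are computed on mesh vertices (consistent with the mesh-based
volume and area); the alternative convention of boundary voxel centres
differs by less than a voxel.

## Agreement statistics

**ICC(2,1).** "Two-way random, single score" is read as the
Shrout–Fleiss ICC(2,1) / McGraw–Wong ICC(A,1) absolute-agreement form:
with row (subject), column (scan) and error mean squares MSR, MSC, MSE
from the two-way ANOVA decomposition,

ICC = (MSR − MSE) / (MSR + (k−1) MSE + (k/n)(MSC − MSE)).

The absolute-agreement form is the appropriate one here because a
systematic shift between scans (for example a probe-compressed second
scan) *should* count against reproducibility. The 95% CI uses the F-based
Shrout–Fleiss procedure with Satterthwaite degrees of freedom; when
MSE = 0 the degrees of freedom are taken at their analytic limit (k − 1).
The implementation is validated three ways: against a brute-force
`stats::aov` oracle to 10⁻¹⁰ on random tables, by parameter recovery on
simulated subject-plus-noise tables, and by CI coverage (93–97% band at
the study size n = 62). Rows with missing values are dropped
(complete-case), since a single-score ICC needs a full n × k table. A
zero-variance table returns ICC 1 with a degenerate [1, 1] interval and a
warning.

**Significance between methods** uses overlap of 95% CIs, with touching
intervals counting as overlap (the conservative reading); the
"14/14 features comparable" style summary in `compare_methods()` counts
features whose interval overlaps the reference method's.

**Wilcoxon, BH, Spearman, Bland–Altman.** The paired Wilcoxon signed-rank
test drops zero differences (classical handling, not the Pratt variant),
uses the exact distribution up to 25 untied non-zero differences and the
tie-corrected normal approximation beyond; it delegates to
`stats::wilcox.test`. Benjamini–Hochberg adjustment delegates to
`stats::p.adjust`; the family is per-region by default (the alternative,
pooling across regions, is a `run_analysis()` option, since the choice of
family is a genuine analysis decision). Spearman correlation uses average
ranks and the t-approximation; Bland–Altman reports the mean difference
and ±1.96 sample-SD limits.

**Quality-control permutation test.** Subjects scoring below 85 (strict)
on either scan are excluded. To ask whether that exclusion improved the
ICC more than excluding the same number of subjects at random, the test
redraws the excluded set uniformly without replacement in each run,
recomputes the ICC, and counts runs at or above the observed post-filter
ICC (ties count, per the "higher or equal" rule); significance is declared
when fewer than 5% of runs reach it (fewer than 50 of 1000). Exclusion is
at subject level — both scans leave together — because quality filtering
removes patients, not individual scans. The test is seeded and replayable;
calibration (≈5% type-I error under uninformative scores) and power
(≥90% when gross failures sit exactly on the excluded subjects) are both
exercised in the test suite.

## The synthetic cohort generator

`synthetic_config()` encodes the study conditions the package is designed
around: 62 subjects, two scans each, 3 mm slices with 0.5 mm in-plane
spacing, and a manual reference plus three simulated automatic methods.
The organ model is deliberately geometric rather than anatomical — a
superellipsoid (exponent 2.5) whole gland with a posterior-crescent PZ
shell — because a closed-form ground truth permits analytic checks
(rasterized volume within 3% of the drawn target; exact volume
preservation under deformation) that an atlas could not provide.

Defaults and what they emulate:

* **Gland volume** log-normal, mean 55 000 mm³ (CV ≈ 0.35): places the
  median gland at about 14 occupied 3 mm slices, matching the segmented
  slice extent of the emulated design, with realistic between-subject
  spread for an elderly screening cohort.
* **Scan-2 compression** 0.9 (±0.03 per-subject jitter): the second scan
  is acquired with an endorectal needle guide and in prone position, which
  compresses the gland anterior–posteriorly without changing its volume.
  The generator scales the AP semi-axis by the compression factor and both
  other axes by its inverse square root, so true volume is preserved
  exactly while flatness, elongation and sphericity shift — the
  generator-level basis for shape ratios reproducing worse than volume.
* **Slice dropout** probability 0.3 on scan 2: one occupied end slice of
  the mask is removed, emulating the slightly smaller segmented slice
  extent observed on the second scan.
* **Boundary noise** per method (manual 0.5, nnU-Net-3D-like 0.8,
  nnU-Net-2D-like 1.0, V-Net-like 1.8 mm RMS): a smooth random radial
  displacement field on the sphere of directions (a dozen
  von-Mises–Fisher-type bumps, normalized to the stated RMS amplitude in
  mm). The ordering — manual best, V-Net-like worst — echoes the relative
  segmentation accuracy of the emulated methods; only the ordering, not
  any printed DSC value, is treated as a design property. The RMS
  normalization includes the field's global mean component, so part of
  each method's error budget is a global over/under-segmentation, as real
  CNNs exhibit.
* **Spurious components** (probability 0.15 per automatic-method mask): a
  disconnected blob of at most 2% of the gland volume, at least a few mm
  clear of the gland — the failure mode that largest-component
  post-processing exists to remove. Its clearest reproducibility signature
  is in the maximum 3D diameter, which a distant blob inflates by tens of
  mm.
* **Gross failures** (probability 0.08 per automatic-method mask): global
  erosion or dilation by 3–5 mm. At subject level this yields roughly
  10 of 62 subjects excluded per method by the quality filter, matching
  the exclusion scale of the emulated design. Post-processing correctly
  does *not* remove these (they are connected), which is why the
  post-processing benefit is assessed on diameter-type features rather
  than volume.
* **Quality scores** are 100 − 4·(error in mm-equivalents) plus Gaussian
  noise (SD 2), clipped to [0, 100]: gross failures land far below the
  85 threshold, ordinary noise stays above it, and a small spurious blob
  costs only one mm-equivalent (a quality-control system keyed to overall
  mask plausibility barely notices a tiny distant island).

The PZ shell occupies the posterior half of the gland with thickness
0.35 of the local radius, tapering toward the lateral rim but with an
abrupt minimum-thickness edge. An earlier version tapered smoothly to
zero; at 3 mm slices the rasterized rim then fragmented into genuine
sub-voxel PZ islands, so largest-component cleaning removed real tissue
and added noise of its own. The abrupt rim keeps the crescent connected,
so that disconnected components in the generated masks are (almost
always) the injected spurious blobs.

What the generator does **not** emulate: image intensities (there are no
images, only masks), biomechanically realistic deformation, lesions,
inter-observer manual variability structure, and anatomically shaped
glands. Consequently, passing tests demonstrate that the *statistical
machinery* behaves correctly under the design's error structure — not that
any particular CNN is reproducible on clinical data.

## Numerical choices and degenerate inputs

* Tie-breaks: equal-sized largest components resolved by smallest
  lexicographic voxel index; permuted ICC values exactly equal to the
  observed one count toward significance.
* Empty masks are errors at feature extraction (and for DSC when both
  masks are empty); empty *regions* inside a cohort run are warnings that
  produce `NA` feature rows, which the complete-case ICC then drops.
* All randomness (generator, permutation test) flows through explicit
  seeds; per-subject seeds derive from the master seed so any subject can
  be regenerated independently, and both the generator and the
  permutation test restore the caller's RNG state.
* NIfTI-1 stores spacing as float32, so a 0.6 mm spacing survives a
  round trip only to header precision (~10⁻⁷); voxels and
  float32-representable spacings round-trip bit-exactly.
* Problem sizes in the shipped tests: analytic phantoms at 0.5 mm
  isotropic spacing (up to ~500k voxels); the end-to-end cohorts at the
  full study design (62 subjects, 3 mm × 0.5 mm × 0.5 mm), with the unit
  tests using coarser 1 mm in-plane grids where only code paths, not
  accuracies, are at stake.

## Known limitations

* The mesh surface-area error, while comfortably within 2% on smooth
  phantoms, is resolution-dependent; very thin structures (one to two
  voxels) are meshed from the raw binary field and carry staircase bias.
* The ICC confidence bounds follow one specific F-based convention;
  other statistics environments may differ in the third decimal.
* The 2D-diameter plane conventions assume the canonical
  slice × row × column axis order that `read_label_volume()` establishes;
  exotic NIfTI orientations are handled by reorientation to RAS, which has
  only been exercised on standard affines.
* `run_analysis()` holds one subject-scan's volumes in memory at a time,
  but the feature table for very large cohorts is still built in memory.
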