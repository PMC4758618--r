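---
title: "Quantifying kinetochore foci: models, geometry and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying kinetochore foci: models, geometry and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinetoquant)
```

## The measurement problem

Budding-yeast kinetochores cluster into one or two diffraction-limited
foci per cell when a kinetochore protein is fluorescently tagged. The
relative amount of protein at the kinetochore is estimated per focus as
a background-subtracted mean intensity, and the apparent size of the
focus as the width of a fitted Gaussian profile. Because absolute counts
depend on exposure, camera gain and fluorophore, every quantity is
normalized to the mean of a matched wild-type/control population imaged
under the same conditions: the unit of all comparisons is a *fold versus
the control mean*.

This package implements that measurement chain for 3D widefield
z-stacks (by default 0.205 µm lateral pixels and 17 slices at 0.4 µm
spacing) and pairs it with a simulator that plants known effect sizes,
so the whole chain can be validated by parameter recovery.

## Dual-ROI intensity measurement

For each focus, two voxel sets are built around the detected peak voxel
(`buildROI()`):

* the **kinetochore box**, an axis-aligned box of fixed voxel
  dimensions. At the default voxel size the published 1.36 µm³ volume
  forces 81 voxels. Two factorizations are consistent with a "box"; the
  default is 3 × 3 px laterally × 9 slices axially (0.615 × 0.615 ×
  3.6 µm), which spans the axial extent of a diffraction-limited focus
  across slices and makes the region genuinely three-dimensional. The
  flat 9 × 9 × 1 alternative is available through
  `roiGeometry(boxDim = c(1, 9, 9))`.
* the **background shell**: the N nearest voxels (anisotropic Euclidean
  distance in µm, ties broken lexicographically by (z, y, x)) outside
  the box dilated by a **gap** of 2 voxels. The published 23.51 µm³ is
  not an integer multiple of the voxel volume for any concentric box, so
  the shell is defined by a fixed count, N = 1399 (23.517 µm³, within
  0.03% of the printed value). A fixed count keeps the geometry
  deterministic and identical for every focus.

The per-focus value is `corrected = mean(box) − mean(shell)`. Negative
values are preserved — clipping would bias population means upward.
The corrected value is exactly invariant to adding a constant to the
stack and exactly equivariant to scaling, which the test suite asserts.
Increasing the gap (moving the shell further from the kinetochore)
changes control-normalized results by well under 2% in simulated fields,
mirroring the robustness check of the original protocol.

Voxel coordinates are 1-based (z, y, x) throughout, matching R's array
indexing; voxel centres sit at integer coordinates and a voxel spans
±0.5 around its centre.

## Focus detection

The underlying spot finder of the original (proprietary) analysis is
unspecified beyond "finds the brightest spots". The implementation here
is deliberately simple and oracle-verifiable:

1. Gaussian pre-smoothing, σ = 1 voxel per axis (truncated at 3σ,
   renormalized at the boundary);
2. local maxima over the 26-neighbourhood;
3. removal of candidates within 3 voxels of any x, y or z boundary (the
   published edge-exclusion rule; a spot *n* voxels from an edge is kept
   iff *n* ≥ 3);
4. greedy selection in descending smoothed intensity with non-maximum
   suppression at a minimum separation of 5 voxels (about one ROI
   half-width, so the paired anaphase foci of one cell resolve
   separately), ties broken lexicographically by (z, y, x).

The test suite checks this against an independent exhaustive
local-maximum scan with greedy re-selection on random small grids.
Constant stacks yield no candidates. Sub-voxel localization is left to
the morphometry stage; manual selection of post-anaphase cells in the
original workflow is replaced by ground-truth labels in simulation and
by user-supplied focus lists on real data.

## Morphometry: 5-px patch, marginal sums, 1D Gaussian fits

Focus size is measured exactly as the published procedure describes: a
5 × 5 pixel window centred on the peak voxel is taken from the z-slice
containing it (the slice choice is unstated in the original; the peak
slice maximizes signal and is deterministic). A local background — the
median of the window's 16 border pixels, a robust statistic using only
in-window data — is subtracted. Row sums and column sums each give a
5-point profile, and each profile is fitted with

y = a + (b − a)·exp(−(x − c)² / (2d²)),

the four-parameter form used by ImageJ's Gaussian fitter. Fits start at
a = min, b = max, c = argmax, d = 1 px, with bounds 0.3 ≤ d ≤ 5 px and
c inside the window, optimized by Levenberg–Marquardt. Per focus,
FWHM = 2√(2 ln 2)·d from the two axes is averaged, as is the height
b − a. Five points constrain four parameters weakly, so fits that fail
or pin d at a bound are flagged and excluded from population summaries
with a logged count — exclusion with logging was chosen over clamping
because clamped values would bias population means silently. In
simulated stacks with constant planted width the failure rate is below
2%; when a wide planted width *distribution* is simulated, its narrow
tail (below ~0.3 px after pixel integration) is what gets excluded.

Two systematic properties of this estimator are worth knowing. Fitting
a point-evaluated Gaussian to voxel-integrated data inflates the fitted
d by roughly the 1/12-voxel variance of pixel integration, which
partially cancels in control-normalized folds but leaves width-fold
estimates a few percent conservative (biased toward 1). And the height
of a focus whose z-centre falls between slices is attenuated relative
to a slice-centred focus; the attenuation applies to all arms equally
and cancels in the fold.

## Population statistics

Normalized populations are summarized as mean ± sample s.d. (n − 1),
formatted at two decimals as in the source legends. Comparisons use the
two-sided two-sample t test; the *Welch* unequal-variance form is the
default because the published arm s.d.s differ markedly (e.g. 0.25 vs
0.57), with the pooled-variance variant behind a flag. Significance is
flagged `***` iff p < 0.0001, the convention of the source figures; no
multiple-testing correction is applied, matching the original analysis.
Tests are computed per focus, matching the plotted distributions.
`mindCopies()` implements the copy-number arithmetic: with 6.5 complexes
per kinetochore (midpoint of the 6–7 estimate), additional complexes =
round(baseline × (fold − 1)).

## The simulator and what it does (not) emulate

`simulateField()` generates one 16-bit stack per channel and genotype
arm. Cells sit on a lattice with 26-voxel spacing and two foci per cell
13 voxels apart — post-anaphase clusters, spaced so that no two
background shells overlap another focus. Each focus is an anisotropic
3D Gaussian (default σ_xy = 0.12 µm, σ_z = 0.35 µm, a diffraction-
limited widefield PSF at this pixel size) rendered by per-axis
error-function differences, i.e. integrated exactly over each voxel
rather than point-sampled; planted photons are conserved to numerical
precision. Positions get uniform sub-voxel jitter on all three axes.
Per-focus brightness is lognormal — intensities are positive and the
published populations are right-skewed — parameterized by mean fold and
CV taken from the source populations. A diffuse background (default
100 counts, optionally with a linear gradient), Poisson photon noise,
Gaussian read noise (default 2 counts), clipping and integer
quantization complete the camera model. The photon baseline (5000 per
control focus) is arbitrary but fixed; no absolute calibration exists
to reproduce, and every validated quantity is a ratio.

Scenario presets come in two modes because the real enlarged-focus
phenotype is not a single Gaussian: its published intensity (1.83×),
peak-height (1.71×) and FWHM (1.16×) folds are mutually inconsistent
for one Gaussian profile. *Intensity* presets plant an integrated-
brightness fold at control width; *morphometry* presets plant FWHM and
marginal-peak-height folds, and the generator solves each focus's 3D
amplitude through the forward model (analytic noiseless patch + the
same 1D fit used in measurement) so the planted height is realised in
the observable the pipeline measures. Each preset records its source
and per-arm CVs; per-arm width CVs in morphometry presets reproduce the
published FWHM population spreads.

The simulator does **not** model optical aberrations or a vectorial
PSF, photobleaching, time-lapse, cell outlines or autofluorescence
texture, and its foci are ideal Gaussians rather than the irregular
chromatin-proximal structures of real kinetochores. Passing recovery
tests therefore demonstrates that the *measurement chain* is unbiased
and correctly implemented under the stated imaging model — not that the
model captures every property of real micrographs.

## Numerical choices and degenerate inputs

* Rendering uses a 6σ support window per axis (truncation < 10⁻⁸ of the
  mass); conservation is asserted to 0.1%.
* Smoothing kernels are truncated at 3σ and renormalized per position.
* Constant grids detect no foci (every voxel ties); plateau ties are
  resolved lexicographically.
* A reference population with zero mean corrected intensity raises a
  degenerate-reference error rather than returning infinities.
* Zero-variance/equal-mean comparisons return t = 0, p = 1.
* ROIs that would cross a stack boundary raise an error naming the
  focus; they are never silently truncated.
* Fixed seeds make every simulation bit-reproducible; `simulateField()`
  refuses to run without an explicit seed.

## Problem sizes

Validation runs use 150 foci per arm (75 simulated cells on a
248 × 248 × 17 grid), the scale of the published per-panel populations;
unit and property tests use 6–60 foci and 10–16-voxel grids where an
exhaustive oracle is the comparison. Recovery checks at n = 150 carry
the sampling error of a 150-draw lognormal mean (about 2.5% s.e. at
CV ≈ 0.3), which is the dominant uncertainty in any single seeded
replicate; unbiasedness is asserted separately by averaging replicates.

## Known limitations

* The detection stage reports integer peak voxels only; real-data use
  with sub-voxel focus lists is supported by passing centres directly
  to `measureFoci()`/`measureFocusSizes()`.
* Whether the original background shell was voxel-count-derived or an
  analytic volume is unrecoverable; the fixed-count shell documented
  above is this package's deterministic reconstruction.
* FWHM folds from the 5-point marginal fit are slightly conservative at
  default widths (pixel-integration bias, above); the effect is shared
  by the original procedure, which used the same profile model.
* Per-cell (as opposed to per-focus) aggregation is not implemented;
  the source populations are per focus.
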