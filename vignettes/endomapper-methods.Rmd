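---
title: "Methods: object-based colocalization with a randomized null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: object-based colocalization with a randomized null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Deciding whether a protein of interest localizes at a class of
endomembrane compartments from a two-channel image is harder than it
looks. Overlay inspection and pixel-correlation coefficients (Pearson,
Manders) are sensitive to the relative brightness of the two channels and
to how much of the image the compartments occupy. The approach
implemented here is object-based: compartments are segmented from a
dedicated marker channel, the protein channel is quantified inside each
object, and two devices control for the obvious failure modes — a
positivity threshold anchored to the image's own intensity statistics,
and a randomized null that measures how much "colocalization" arises from
dropping regions of the same size at random.

## The workflow

Given a two-channel image (marker + protein), a rectangular region of
interest (conventionally 300 × 300 px, drawn to contain the cell area
where the compartments live), and a pixel calibration in µm/px:

1. **Segmentation** of the marker channel: Gaussian smoothing
   (`gaussian_sigma_px`, default 1 px), binarization (pixels strictly
   above the threshold are foreground; Otsu's histogram split on the
   smoothed ROI by default, or a fixed value), morphological closing with
   a disc (`closing_radius_px`, default 1), hole filling, 8-connected
   component labeling, and rejection of components smaller than
   `min_area_px` (default 4 px).
2. **Measurement**: mean and population standard deviation of the protein
   channel over each compartment's exact pixel set.
3. **Null model**: `n` rasterized disks of radius
   `round(sqrt(area_px / pi))` placed uniformly at random with the disk
   fully inside the ROI (defaults `n = 1000`, `area_um2 = 1.2` at
   endosome/autophagosome scale; `n = 10`, `area_um2 = 9.2` at
   trans-Golgi scale), measured identically.
4. **Positivity**: a region is positive when its mean protein intensity
   strictly exceeds `mean + k * sd` of the protein channel over the
   entire ROI (`k = 1` by default). The percentage of positive real
   compartments is the headline localization estimate; the same
   percentage over pseudo-compartments shows what chance placement
   yields.
5. **Inference**: a two-sided Mann–Whitney rank-sum test compares the
   real and pseudo per-region mean intensities. The protein is considered
   genuinely localized only when this difference is significant.

```{r}
library(endomapper)
fx  <- generate_colocalization_fixture(synthetic_params(seed = 42))
rep <- endomapper(fx$image, seed = 42)
summary(rep)
```

## Parameters that matter

| parameter | unit | default | notes |
|---|---|---|---|
| `pixel_size_um` | µm/px | user-supplied | all µm² parameters convert through it |
| ROI | px | 300 × 300 | axis-aligned rectangle; 1-based (row, col) origin |
| `gaussian_sigma_px` | px | 1 | typical confocal blur at endosome scale |
| threshold method | — | Otsu | automatic and reproducible; `fixed` override |
| `closing_radius_px` | px | 1 | bridges 1-px gaps before hole filling |
| `min_area_px` | px | 4 | "very small debris" cutoff; deliberately small and configurable |
| `n`, `area_um2` | —, µm² | 1000, 1.2 | null-model size/number (10, 9.2 at Golgi scale) |
| `k` | — | 1 | positivity multiplier; sweep `{0, 0.5, 1, 1.5, 2}` to probe sensitivity |
| `bin_factor` (FRET) | — | 1 | 2 for endosomes, 3 for autophagosomes |
| `edge_band_um` (FRET) | µm | 1.67 | plasma-membrane-proximal rim width |

Two conventions are fixed deliberately. The standard deviation is the
population SD (divide by *N*) everywhere, matching common image-analysis
measurement semantics; switching to the sample SD would only rescale the
threshold marginally. The positivity comparison is strict (`>`), so on a
constant image (SD = 0) no compartment is ever positive.

## Design choices where the procedure was open

* **Threshold baseline.** The reference statistics can be taken over the
  entire ROI (default) or over the union of segmented compartment pixels
  (`baseline = "compartments"`). Both readings are defensible; the
  ROI-wide version is the default because it is the operational
  description of the measurement, and the alternative is one flag away.
* **Morphology order.** "Fill holes and close" is implemented as
  close → fill-holes: closing first bridges broken rims so that their
  interiors become fillable holes. The order is fixed, not configurable,
  so results are comparable across runs.
* **Connectivity.** Components are labeled with 8-connectivity (the
  particle-analysis convention). The labeling is implemented in-package
  as a vectorized minimum-label propagation and is verified in the test
  suite against an independent stack-based flood fill.
* **Pseudo-compartment shape and overlap.** Disks, because compartment
  cross-sections are near-circular and disks make the area exact up to
  rasterization; overlap between pseudo-compartments (and with real
  compartments) is allowed, because the null asks what *unconstrained*
  random placement picks up. A rejection-sampled non-overlap mode exists
  for sensitivity analysis.
* **Rank-sum convention.** `U` counts pairs with the real-sample value
  larger (ties count ½). The p-value is exact (full permutation
  distribution) for `n1 + n2 <= 12` without ties, and a tie-corrected
  normal approximation (no continuity correction) otherwise; the exact
  branch is validated against exhaustive enumeration, the approximate
  branch against `stats::wilcox.test(correct = FALSE)`.
* **Coordinates.** Everything is 1-based (row, col) with closed extents,
  the native R convention; ROI JSON files and CLI channel indices use the
  same convention.
* **Ratio-map export.** Ratio maps are written as plain-text CSV matrices
  (`NA` marks invalid pixels) rather than a float TIFF, keeping every
  artifact of a run human-readable and diffable.

## FRET quantification

Both emission channels are background-subtracted by the mean of a
user-provided region outside the cell (per channel), binned by block
averaging (trailing partial blocks dropped, pixel size scaled by the
factor), and divided per pixel: ratio = YFP(FRET)/CFP. Pixels outside the
cell mask or with CFP at or below a small positive floor (10⁻⁶ of the
binned CFP maximum) are invalid and excluded from every summary; negative
numerators are kept (clamping would bias low-signal ratios upward). The
cell-edge band is the cell mask minus its erosion by a disc of radius
`round(edge_band_um / pixel_size_um)` pixels, so band ∪ interior
reconstitutes the mask exactly and the band is always a subset of it.
Per-pixel ratios are averaged within regions (not ratios of region
means); on a uniform-ratio image the two agree, and the per-pixel order
matches how ratiometric images are rendered.

## What the synthetic generator emulates — and what it does not

`generate_colocalization_fixture()` builds a 300 × 300 px field at
0.1 µm/px containing ~50 non-overlapping hard-edged disks of radius
0.55–0.70 µm (area ≈ 1.2 µm², the endosome scale), marker contrast
200 over background 10, protein background 50 multiplied by the
enrichment factor (default 10) inside a chosen fraction of compartments,
a Gaussian PSF blur (σ = 1 px) and additive Gaussian read noise
(σ = 2 intensity units; Poisson shot noise optional). Intensities are
clamped at zero after noise. `generate_fret_fixture()` realizes an exact
known YFP/CFP ratio inside a rectangular cell with a border background
region.

These fixtures validate the *algorithmic* claims: segmentation counts,
null geometry, threshold behavior, fraction recovery, ratio arithmetic.
They do not emulate tubular recycling-endosome morphologies, compartments
touching or overlapping each other, intracellular background gradients,
out-of-focus light, or camera gain/offset. Passing the suite therefore
shows the method is implemented correctly and is well-calibrated under
its own assumptions — not that segmentation parameters tuned here are
optimal for any particular microscope.

## Numerical notes and edge cases

* A constant marker image under Otsu yields zero compartments (not an
  error); the report then carries `NA` percent positive — zero-compartment
  cells must be excluded from averages, not scored 0.
* Rasterized disk areas deviate from `pi * r^2` by construction; for
  radii ≥ 3 px the deviation stays within 15% of the requested pixel area
  (asserted in the tests). At the endosome defaults the realized area is
  113 px against a requested 120 px.
* Otsu's threshold is computed on a 256-level normalization of the
  smoothed ROI, making the segmentation invariant to positive rescaling
  of intensities.
* With `n = 1000` overlapping pseudo-disks in a 300 × 300 ROI the
  per-region means are positively correlated (disks share pixels), which
  makes the rank-sum p-values mildly conservative under the null — the
  calibration checks bound the effect (p-value distribution compatible
  with uniform at coarse KS tolerance) rather than pretend independence.
* All randomness (placement, noise) flows through explicit seeds; every
  report records its seed, and identical seeds give bit-identical
  fixtures, placements and output files.

## Validation problem sizes

The test suite and `scripts/acceptance.R` use: 20 runs × ~50 compartments
for the self-colocalization benchmark (protein = marker + 5% noise);
200 runs at 200 × 200 px / 30 compartments for the null calibration;
20 runs per enriched fraction in {0, 0.25, 0.5, 0.75, 1} at the default
image size for fraction recovery; oracle equivalence on images up to
64 × 64 px and rank-sum samples up to 5 + 5. These sizes make the whole
validation run in a few minutes on a single core while keeping every
estimate's Monte-Carlo error well below the asserted tolerances.

## Known limitations

Touching compartments are not split (no watershed), so crowded fields
undercount; the ROI is rectangular only; z-stacks and proprietary vendor
formats are out of scope; FRET bleed-through/cross-talk correction is not
applied; and no multiple-testing correction is made across compartment
classes — each image yields one real-vs-pseudo comparison.
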