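---
title: "Negative-contrast organelle reconstruction: models, parameters and validation"
author: "nciquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Negative-contrast organelle reconstruction: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Mast-cell secretory granules (SGs, roughly 0.3-1.0 um across) are hard to
outline with positively staining membrane markers: the concentrated
fluorophore on the granule surface scatters and diffracts, blurring the very
boundary one wants to trace, and no single marker labels every granule.
Negative contrast imaging (NCI) inverts the problem: soluble GFP expressed
in the cytoplasm fills everything *except* membrane-bounded organelles, so
every granule appears as a dark void in a bright field, with a boundary
defined by the exclusion itself rather than by marker accumulation.

`nciquant` turns confocal z-stacks of such cells into a quantitative
organelle inventory:

1. **Restoration** — Richardson-Lucy (RL) deconvolution under a parametric
   point spread function (PSF).
2. **Segmentation** — void detection and sub-pixel contour extraction by a
   relative-intensity rule, slice by slice.
3. **Reconstruction** — serial-section linking of contours into 3D
   organelles and lamination volumetry.
4. **Quantification** — size distributions, cell-volume/granule-count
   correlation, marker colocalization, and granule-granule fusion detection
   in time-lapse series.
5. **Phantoms** — a synthetic-data generator with analytic ground truth,
   used for every validation claim the package makes.

## The contour rule

For a negatively stained region, set the intensity at its centre to 0% and
the surrounding cytoplasm to 100%; the organelle boundary is drawn where
the relative intensity reaches a fraction $f \in [0.90, 0.95]$ (default
$f = 0.925$, the midpoint of the band, exposed as `contourFraction`). On an
analytic radial profile $I(r) = C\,(1 - e^{-(r/r_0)^2})$ the extracted
contour radius has the closed form $r = r_0\sqrt{-\ln(1-f)}$, which the
test suite verifies to within half a lateral pixel on rasterized profiles.

Three reference choices make the rule operational on real stacks, and all
three were genuinely open design decisions:

* **Periphery (100%) reference.** Local, not global: the median intensity
  in an annulus 0.2-0.4 um outside the preliminary void support. This
  keeps the rule self-calibrating under depth attenuation and local
  shading. When the annulus is unusable (fewer than 8 pixels, or
  overlapping another void) the global cytoplasm median — a robust,
  void-excluding iterated median (`estimateCytoplasmLevel`) — is the
  fallback. The single-seed `extractContour` uses the supplied global
  level directly, which is what the closed-form oracle assumes.
* **Centre (0%) reference.** The darkest core of the *3D* negatively
  stained region, not the per-slice minimum. A void's top and bottom cap
  slices have shallow per-slice minima (axial blur); referencing them to
  their own slice would misplace their boundaries. The pipeline labels the
  3D dark support (voxels below `minContrast` = 60% of cytoplasm) and
  shares each component's minimum across its slices.
* **Grey-level vs binarized tracing.** Whether the rule should be applied
  to raw, deconvolved, or black-and-white-converted images is not fixed by
  the procedure it mirrors, which interposed an ImageJ black-and-white
  conversion between deconvolution and contour tracing. `nciquant` follows
  that order by default (`binarizeContours = TRUE`): the slice is
  binarized at the midpoint between the region's core (0%) and the local
  periphery (100%) — the half-depth criterion — and the contour is then
  traced on the binary image by marching squares at the $f$ level.
  On a binary image every fraction in the 90-95% band yields the same
  interface, so the extractor is idempotent under re-running on its own
  binarization, and the boundary lands at the half-maximum edge crossing,
  which is the unbiased edge estimator for a symmetrically blurred step.
  Tracing the grey-level iso-curve at $f$ directly
  (`binarizeContours = FALSE`) is retained for low-contrast structures;
  on restored but still slightly blurred data it places the boundary on
  the outer shoulder of the edge and overestimates diameters by roughly
  20% on 1.0-um voids, which is why it is not the default.

Seeds (one per void per slice) are regional minima of the lightly smoothed
slice (Gaussian, 0.75 px) that are darker than 60% of the cytoplasm;
minima closer than 0.25 um merge. Plateau interiors (all eight neighbours
equal) are not minima. Seeds are confined to the cell interior eroded by
0.4 um: the blurred rim and the cap slices of the cell itself are not
organelle territory. When several seeds share one dark region, the region
is split along its intensity ridge by seeded region growing
(`EBImage::propagate`) and each seed's contour is its share's boundary —
the source procedure does not specify how clustered granules were
separated, so this is the package's choice.

## Restoration

The commercial blind deconvolution used upstream of the original
reconstructions is proprietary and its settings unreported; equivalence
cannot be established. `nciquant` substitutes non-blind Richardson-Lucy
with a user-supplied parametric PSF: blind deconvolution is ill-posed, and
for phantoms the PSF is known exactly. Defaults: Gaussian PSF with lateral
FWHM 0.25 um and axial FWHM 0.6 um (typical for a 1.4-NA oil objective at
GFP wavelengths — the source reports no PSF, so these are stated
assumptions), 30 iterations, mirror padding by one kernel extent,
FFT convolutions. RL conserves total intensity to ~1% and its residual
decreases monotonically on noiseless data (both tested). All channels with
signal are restored, since marker quantification is as blur-sensitive as
the GFP channel. Deconvolution is optional (`deconvolve = FALSE`): the
contour rule is relative and partially self-calibrating, but restored
stacks recover diameters better, and the bead benchmark quantifies the
difference.

## Reconstruction and morphometry

Contours in adjacent slices belong to one organelle iff their overlap area
is at least half the smaller area (`linkOverlap = 0.5`; "at the same
position" is otherwise unquantified). Matching is greedy by largest
overlap, then smallest centroid distance, one-to-one per slice pair;
linking is symmetric under slice-order reversal (tested). The primary
volume is the **lamination** (slab) volume $V = \Delta z \sum_i A_i$ —
the serial-section convention — with the voxel-count volume recorded
alongside for QC. The slab model has a known positive bias for curved
solids: for an $r = 0.5$ um sphere sampled at $\Delta z = 0.2$ um through
its centre the slab volume is 0.5341 um^3 against the analytic
0.5236 um^3 (+2.0%); the bias falls below 1% by $\Delta z = 0.02$ um
(both asserted in tests). The exact end-cap treatment of the commercial
reconstruction software is unpublished; the plain slab model is adopted
and its bias quantified rather than hidden.

Equivalent spherical diameter is $(6V/\pi)^{1/3}$; elongation is z-extent
over the area-weighted mean lateral equivalent diameter. Classification:
centroid in the nucleus mask → `nuclear`; thin tubes (lateral diameter
< 0.4 um with elongation > 2, along z or in-plane) → `mitochondrion-like`;
equivalent diameter in [0.3, 1.5] um → `SG`; otherwise `unclassified`.
Whether an elongated structure is one granule or a fused chain is left to
the user — elongation is reported, not interpreted. Objects touching the
first or last slice (or the lateral border) are flagged `truncated` and
excluded from size statistics by default, because their volumes are
underestimates.

The nucleus is segmented as the largest connected dim region (< 75% of
cytoplasm) of at least 30 um^3 in the eroded cell interior, then opened
morphologically (erode 0.45 um, dilate 0.5 um) so that granule-sized voids
whose dark regions touch the nucleus are shed back into the cytoplasmic
pool. Nuclear substructures with partial negative staining are segmented
but always class-labelled `nuclear`, never counted as SGs.

## Quantification

* **Marker colocalization**: an object is marker-positive iff its mean
  interior marker intensity exceeds the background mean by 3 background
  SDs (no criterion is given upstream; 3 sigma is the package's choice).
  Interior means are taken over a core eroded 0.15 um inward to limit
  partial-volume dilution at the boundary.
* **Cell-volume vs granule-count correlation**: Pearson (the association
  is presented as linear upstream) with Spearman alongside, least-squares
  slope, and a seeded 1,000-resample percentile bootstrap CI.
* **Size distributions** stratify cells at 1,500 um^3 (small) and
  2,500 um^3 (large).
* **Tracking**: greedy nearest-centroid matching with a 1.0-um-per-frame
  gate (suited to the 1-3 min frame intervals of the fusion experiments).
* **Fusion detection**: two coexisting tracks, at least one ending at
  frame $t$, with a track at $t+1$ inside the union of the parent extents
  and volume conservation ratio $V_c/(V_{p1}+V_{p2})$ in [0.6, 1.4].
  When exactly one parent is marker-positive the marker dilution ratio
  (child per-volume marker over marked-parent per-volume marker) is
  reported — 0.5 for an equal-volume marked+unmarked fusion — together
  with the approach axis.

## The phantom generator

The generator emulates what the method needs to be tested against, with
analytic ground truth:

* a bright, roughly uniform cytoplasmic field (default 1,000 photons per
  voxel — a bright, 2-frame-averaged acquisition) with dark excluded
  objects (spheres, z-cylinders, strings of touching spheres, ellipsoids),
  voxelized with 8x-per-axis supersampling of boundary voxels so planted
  volumes are unbiased;
* an ellipsoidal cell with a nucleus at 50% of the cytoplasmic level
  containing darker substructures (penetration fraction 0.3);
* confocal acquisition: Gaussian PSF blur (unit-sum kernel), Poisson shot
  noise, Gaussian read noise (SD 2), optional depth attenuation in the
  medium (default 0 — penetration is reported as good), and excitation
  shadowing by object material accumulated along z (default 0.3 per um for
  polystyrene-like beads, 0.1 per um for organelles), which is the
  generator's emulation of the reported obscuring of contours around
  large beads;
* scheduled granule-granule fusion that conserves combined volume, pools
  marker content (diluting per-volume fluorescence), elongates the child
  (axis ratio 1.6) along the approach axis, and holds parents at a 0.4-um
  clearance until the fusion frame so the two voids remain separable.

Bead fields default to 0.1-um z-steps and 40 x 40 nm pixels; cell
phantoms to 0.2-um z-steps. What the phantoms do **not** emulate:
refractive lensing and aberration by high-index objects (only their
integrated shadowing), fluorophore photophysics and bleaching, cell motion
between slices, and vectorial PSF structure. Passing the in-silico
benchmarks therefore demonstrates the correctness of the computational
chain under stated optics, not instrument-level fidelity on any particular
microscope.

## Validation scales

The published live-cell figures (a 3,338-um^3 cell, 1,014 granules) come
from unreleased microscope data and are used only as magnitude context.
The package validates itself on phantoms at these problem sizes, chosen so
a full run of the suite is comfortable on one CPU:

* bead benchmark: 12 beads of 1.0 um in one field (~11 x 9 x 2.8 um at
  40-nm pixels), full pipeline with RL 30; plus 6 beads each of 0.2, 0.5,
  0.75, 1.0, 1.5 um for the validity window;
* counting: one 1,200-um^3 cell with 50 granules at 0.1-um lateral
  sampling, noiseless, no deconvolution;
* correlation: seven cells of 350-950 um^3 with planted count
  proportional to volume;
* fusion: four frames of a 4.4 x 2.6 x 2.6 um field with two 0.8-um
  granules.

The mean recovered bead diameter must fall in the published
98.7 +/- 5.0% band; the 0.5-1.0-um window must show a mean absolute
diameter error of at most 10% with strictly worse errors at 0.2 and
1.5 um; counting must be exact; the fusion dilution ratio must be
0.5 +/- 0.1. `scripts/acceptance.R` recomputes the headline diameter
figure from scratch at any seed.

## Numerical and I/O choices

* All arrays are (z, y, x), 1-based in R, with physical micrometre
  coordinates measured from the stack corner; voxel centres sit at
  $(i-\tfrac12)\,d$.
* Every stochastic step runs under an explicit seed with the caller's RNG
  state restored; identical (configuration, seed) yields byte-identical
  object-table CSVs (tested).
* Stacks are written as plain multi-page TIFF with a JSON sidecar carrying
  the calibration (voxel size, channel names, intensity scale), because
  the TIFF writer available cannot embed custom tags. 32-bit pages
  round-trip intensities to within one step of the 2^32-sample grid; a
  half-step offset at write time compensates the writer's truncation so
  repeated write/read cycles do not drift. 16-bit export is available for
  viewers.
* Contours can be dumped as GeoJSON-style polygons for inspection;
  organelle inventories are fixed-header CSVs ordered by id.

## Known limitations

* The large-bead (> 1.0 um) accuracy degradation is reproduced through
  the shadowing term only; refractive lensing, likely the dominant
  physical cause, is not modelled, so the in-silico degradation at 1.5 um
  is milder than the reported in-vitro one.
* The binarized contour path assumes high-contrast (near-fully excluding)
  voids; partially excluding structures are better served by the
  grey-level path.
* Touching granules are separated by a ridge split only within a slice;
  granules stacked along z that touch merge into one elongated object, as
  they do in the serial-section procedure being mirrored.
* RL with a mismatched PSF degrades gracefully but is not blind; measured
  PSFs can be supplied via `measuredPSF()`.
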