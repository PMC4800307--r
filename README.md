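# nciquant

Quantitative 3D reconstruction of secretory granules from
**negative contrast imaging** (NCI) of live mast cells.

## The problem

Mast cells store inflammatory mediators in hundreds of secretory granules
(SGs) of roughly 0.3–1.0 µm diameter. Positively staining SG markers
(e.g. NPY– or CD63–fluorescent-protein fusions) accumulate on the granule
membrane, where concentrated fluorophore scatters and diffracts light and
blurs the boundary; and no marker labels every granule. NCI sidesteps
both problems: a cell abundantly expressing soluble cytoplasmic GFP is
bright everywhere *except* inside membrane-bounded organelles, so every
granule appears as a sharply outlined dark void — no marker required.

`nciquant` is an R implementation of the full analysis chain for such
data: synthetic phantom generation with analytic ground truth, image
restoration, void segmentation, serial-section 3D reconstruction, and
population/fusion quantification.

## The method

For each z-slice, a void boundary is the iso-intensity curve at relative
level

&nbsp;&nbsp;&nbsp;&nbsp;*L* = *I*<sub>centre</sub> + *f* · (*I*<sub>periphery</sub> − *I*<sub>centre</sub>),&nbsp;&nbsp;*f* ∈ [0.90, 0.95] (default 0.925),

where the centre (0%) is the darkest core of the 3D negatively stained
region and the periphery (100%) is the local cytoplasm, measured in an
annulus 0.2–0.4 µm outside the void. By default the slice is first
converted black-and-white at the half-depth level (an ImageJ-style
binarization, applied after Richardson–Lucy deconvolution) and the
contour is traced sub-pixel by marching squares. Contours in adjacent
slices that overlap by ≥ 50% of the smaller area are linked into one
organelle; its **lamination volume** is

&nbsp;&nbsp;&nbsp;&nbsp;*V* = Δ*z* · Σ<sub>i</sub> *A*<sub>i</sub>,

the serial-section slab model, and its equivalent spherical diameter is
(6*V*/π)<sup>1/3</sup>. Organelles are classified (SG /
mitochondrion-like / nuclear / unclassified), marker colocalization uses
a 3σ-above-background criterion, and time-lapse series are tracked to
detect SG–SG fusion events, whose per-volume marker fluorescence dilutes
by the volume ratio (0.5 for an equal-volume marked+unmarked fusion).

Everything is validated against a phantom generator that plants spheres,
cylinders, strings of granules, cells with nuclei, and scheduled fusion
events with exact analytic volumes, then simulates confocal acquisition
(Gaussian PSF, Poisson + Gaussian noise, depth/object shadowing).

## Worked example

Simulate a field of twelve 1.0-µm beads (the in-silico analogue of a
polystyrene-bead accuracy experiment), run the full pipeline, and look at
the recovered diameters:

```r
library(nciquant)

spec  <- beadFieldSpec(n = 12, diameter = 1.0, seed = 1)
scene <- makeBeadPhantom(spec)
rec   <- runPipeline(scene, nciConfig())   # optics + RL(30) + contours
head(rec@table[, c("id", "class", "volumeLamination", "equivDiameter")])
```

```
  id class volumeLamination equivDiameter
1  1    SG        0.5562660      1.020378
2  2    SG        0.5710758      1.029355
3  3    SG        0.5721038      1.029972
...
```

Each bead (true volume π/6 ≈ 0.524 µm³, diameter 1.0 µm) is recovered
with an equivalent diameter near 1.02–1.03 µm. The benchmark wrapper
aggregates this over bead sizes:

```r
runBenchmark(sizes = c(0.5, 0.75, 1.0), n = 6, seed = 3)
```

```
  diameter n nDetected meanRecoveryPct sdRecoveryPct meanAbsErrorPct
1     0.50 6         6        96.72412     0.2404873        3.275878
2     0.75 6         6       101.35405     0.5879892        1.354049
3     1.00 6         6       102.64020     0.3917569        2.640203
```

Mean recovery stays within a few percent of truth across the 0.5–1.0 µm
window in which the method is validated; 0.2-µm beads vanish into the
diffraction limit and oversized beads degrade through shadowing.

A cell phantom works the same way and returns a full
`CellReconstruction` (cell volume, nucleus, organelle inventory, stage
log); `writeObjectsTable()` exports the inventory as CSV, and
`sizeDistribution()`, `cellSgCorrelation()`, `trackObjects()` +
`detectFusionEvents()` cover the population and time-lapse analyses. A
thin command-line front end lives at `inst/cli/nci.R`
(`simulate | restore | run | benchmark`).

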