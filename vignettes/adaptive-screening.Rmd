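---
title: "Adaptive screening: methods and design notes"
author: "AdaptiveScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AdaptiveScreen)
```

## The screening model

Automated microscopes spend most of their time capturing regions that
contain nothing of interest. Adaptive (feedback) screening replaces the
exhaustive high-resolution scan with a three-step loop:

1. **First scan** — a low-resolution *search mosaic* of juxtaposed
   fields covering the entire sample, captured as fast as possible.
2. **Analysis** — an image-analysis routine locates the coordinates of
   the objects of interest on the stitched mosaic.
3. **Second scan** — only the identified objects are re-acquired at
   high resolution, with their own objective, zoom, z-stack and
   time-lapse settings.

`AdaptiveScreen` implements this loop end to end in a vendor-neutral
way: settings, scan jobs, coordinate lists and templates are a
versioned JSON/CSV dialect rather than any instrument's proprietary
format, and a *virtual microscope* stands in for the hardware so the
whole workflow can be exercised, tested and benchmarked without a
stage. The package is organised around a few S4 classes
(`MosaicFrame`, `AcquisitionSettings`, `TileGrid`, `DetectedObject`,
`SecondScanPlan`, `VirtualSlide`, `RunManifest`) with plain-function
operations between them.

## Coordinate geometry

Mosaic pixels are mapped to physical stage micrometres by an affine
`MosaicFrame`: pixel indices are 0-based, refer to pixel centres, and
may be fractional (centroids are sub-pixel); tiles and masks use
half-open pixel extents so sub-pixel arithmetic is consistent. The
`yAxisSign` field absorbs the vendor disagreement about whether image
rows grow with or against stage Y instead of hard-coding either
convention. `pixelToStage()` and `stageToPixel()` are exact inverses
(the tests require < 1e-9 µm round-trip error).

Changing objectives shifts the optical centre; this *paracentricity*
offset is modelled as a per-objective translation relative to one
declared reference objective (offset (0, 0)). The correction that
re-centres a point measured under objective A for capture under
objective B is simply `point + (offset_B − offset_A)`; corrections
therefore compose additively and invert exactly. A rotational or
scale component is deliberately not modelled: a translation is the
minimal model consistent with a predefined per-objective "correction",
and nothing in the workflow needs more. Parfocality (z) is out of
scope for the same reason.

## Planning the scans

`planSearchMosaic()` lays a grid of fields over the sample bounds with
step `fov × (1 − overlap)`. The first tile is centred at
`min + fov/2` and the last row/column is shifted inward to
`max − fov/2`, so the grid never overhangs the bounds by more than
half a field and layouts are deterministic; a sample smaller than one
field gets a single centred tile. Every point of the bounds lies in at
least one tile (the tests verify this at 1 µm pitch).

For the second scan, `planObjectAcquisition()` applies the
small/large-object rule: an object whose bounding box plus margin fits
the second-scan field in both axes becomes a single field centred on
its centroid; anything larger is covered by a tile grid planned like a
search mosaic over the padded box. A padded box *exactly* equal to the
field resolves to the single field — equality is assigned to the
cheaper plan. Tiles are visited in row-major serpentine order, which
keeps simulated stage travel short and makes stitching deterministic.

### NoIR: pruning non-informative regions

Large irregular objects waste fields on the empty corners of their
bounding boxes. `applyNoir()` re-examines one object's pixel mask and
disables every tile that does not intersect the mask dilated by a
margin. Three numerical choices matter:

* **Dilation is morphological in the mask's own raster**: a Euclidean
  disc of radius `margin / pixelSize` pixels (offsets with
  `hypot(di, dj) ≤ r`). This makes the operation exactly reproducible
  by a brute-force rasterization oracle, which the test suite runs on
  hundreds of random masks.
* **Closed rectangles; grazing contact counts as intersection.** The
  rule is deliberately conservative: a tile touching a single boundary
  line of the dilated mask stays enabled, so no object pixel is ever
  dropped from coverage.
* **The NoIR margin defaults to 0 µm** and is a template parameter;
  there is no canonical value for how much context a second scan
  should keep.

An empty mask disables every tile and signals a warning rather than an
error. Enabled sets are always subsets of the input enabled set, and
the enabled count is non-decreasing in the margin.

The conservatism has a quantifiable cost. For a disk inscribed in an
n × n grid the skipped fraction (`estimateSavings()`) tends to
1 − π/4 ≈ 0.215 as the grid refines, but every tile the disk boundary
crosses stays enabled, so the measured savings sit below the limit by
about (2n + 1)/n² — ≈ 0.03 at n = 64, halving as n doubles. A
centre-in-mask rule would converge much faster but would drop object
pixels at the boundary, which the coverage guarantee forbids; we keep
the conservative rule and accept the slower convergence.

`mergeNearbyObjects()` merges objects whose bounding boxes come within
a separation threshold (Euclidean gap between boxes), transitively and
repeatedly until a fixed point, so the operation is idempotent and
second-scan plans never overlap. Merged objects take the union box and
mask and an area-weighted centroid.

## Detection macros

The built-in macros keep the tunable surface to the minimal triple —
threshold, smoothing, size filter (`DetectionParams`):

* Gaussian smoothing (`smoothingSigma` pixels, 0 = off),
* a global threshold, either fixed or Otsu (Otsu is the default mode;
  no algorithm is canonical here so both are stated explicitly),
* hole filling, morphological closing of radius 1 px,
* 8-connected component labelling (diagonal contact joins regions),
* an area window in µm² applied after conversion by `pixelSize²`.

The area window doubles as the guard for Otsu's degenerate case: on a
featureless image Otsu places the threshold inside the noise
distribution and the above-threshold pixels percolate into one huge
component, which a finite `maxArea` removes, so an all-background
mosaic yields an empty object list rather than a spurious detection.
With a fixed threshold above the noise floor the empty result is
immediate.

Objects are reported largest-first with sub-pixel centroids in stage
micrometres. Objects touching the mosaic border are kept and flagged —
a rare event at the border must not be silently lost.

The rare-event macro (`detectRareEvents()`) segments nuclei with the
same pipeline, then measures every marker channel over the nucleus
mask dilated by 2 px. The dilation captures the cytoplasmic rim:
cytokeratin is cytoplasmic, and a nucleus-only mask would under-read
it. Classification is a hard gate: every positive rule must reach its
threshold (`≥`), every negative rule must stay strictly below (`<`) —
the boundary behaviour is part of the contract. The canonical
configuration is the CTC gate: nucleated, CK-positive, CD45-negative.
Greyscale dilation of the label image assigns contested rim pixels to
the larger label; with the generator's minimum cell separation rims
never touch, and on real data the effect is confined to abutting
cells.

External routines participate through the macro contract: they receive
the mosaic TIFF path, the frame JSON and an output path, and must
write the coordinate CSV (`object_id,x_um,y_um,bbox_w_um,bbox_h_um,
label,score`; µm, period decimals, UTF-8, LF). Out-of-bounds records
are rejected with a report; a nonzero exit or missing CSV is a
macro-contract error. Manual selections enter the same way and get
rectangular masks.

## The virtual microscope

`generateSlide()` draws a ground-truth scene from a
`SyntheticSampleSpec`; `acquire()` renders what the instrument would
capture for any plan item at any settings. Design choices:

* **The scene is analytic**, a sum of compactly supported smooth
  profiles (cosine edge ramps) over a uniform background — not a
  stored raster. Any field of view and pixel size can be rendered
  consistently, which is what lets the second scan genuinely see more
  detail than the first, and lets tests compare a stitched mosaic
  against a direct render of the same region.
* **Noise is additive Gaussian read noise only.** SNR is defined as
  (object mean − background)/noise sd. Poisson noise is omitted so
  that stated SNRs are exact and tests are deterministic; each
  acquisition item's noise stream is seeded by (slide seed, item id),
  so re-acquiring the same field reproduces the same image.
* **Placement is rejection sampling** (≤ 1000 attempts per object,
  then a placement error) with a spatial hash for neighbour queries;
  objects never overlap and keep a minimum separation.
* Only one z-plane and time point are rendered even when settings
  request stacks or lapses; those parameters ride along as plan
  metadata (declared limitation).
* `acquire()` displaces the optical centre by the objective's
  paracentricity offset, so plans corrected with
  `applyParacentricity()` come out centred — the correction is
  exercised physically, not just arithmetically.

Two reference scenes define the study conditions. The TMA scene
defaults to 77 differently sized tissue pieces (200–600 µm, ellipses
and Fourier-modulated blobs) on a 10 × 10 mm area. The CTC scene
defaults to 10,000 cells with event fraction 0.0025 — 1 in 400 — at
SNR (0.60 − 0.05)/0.11 = 5, with events CK-high/CD45-low and all
other cells the reverse; the slide carries exactly
`round(nCells × eventFraction)` events. Cell radii (nucleus ≈ 5 µm,
cytoplasm ≈ 8 µm) and the 6 µm minimum separation are typical of
enriched-sample slides where cells settle individually.

What the simulator does *not* emulate bounds what passing tests can
show: real point-spread functions, uneven illumination, staining
variability, overlapping or touching cells, autofocus failures and
stage positioning error are all absent. Perfect recall/precision on
the synthetic slides demonstrates that the pipeline is correct and
loses nothing by construction — not that any particular assay achieves
it; on real data the detection parameters are the user's to tune.

## The workflow engine

`runFirstScan()` → `runAnalysis()` → `runSecondScan()` (or `runAll()`,
the "play" mode) chain over a `RunManifest` that enforces step order
and records artifacts, timing and the savings fraction. Stitching uses
nominal stage positions only — the virtual stage is exact and a search
mosaic is a locator, not a quantitative image — and overlap strips are
averaged unweighted so pixel-level tests can be exact. The savings
report is `1 − enabled fields / fields of a full mosaic` over the
searched area at the second-scan field of view, recomputable from the
emitted scan job.

All serialization is canonical: sorted JSON keys, 9-significant-digit
numbers, LF endings. Two runs with the same template and seed produce
byte-identical coordinate and scan-job files, which the tests assert
literally. The interactive "revision of identified areas" between
analysis and the second scan becomes, in this offline setting, an
edit of the coordinate CSV re-imported as a manual selection (the
command-line `scan2 --coords` path).

A thin command-line wrapper (`inst/scripts/adaptivescreen`, verbs
`simulate`/`plan`/`scan1`/`analyze`/`scan2`/`play`) drives the same
functions; every verb recomputes deterministically from (template,
seed), so stepwise use and one-click play write identical artifacts.

## Problem sizes used by the checks

The shipped tests and the acceptance script use: 200 random masks on
grids up to 16 × 16 for the NoIR oracle; a 64 × 64 grid (512 µm at
1 µm raster) for the inscribed-disk savings; 100 random
bounds/FOV/overlap draws for coverage; 100 random documents per
serializer; 20 slides of 10,000 cells for rare-event recovery; one
77-piece TMA run; and two repeated small runs for determinism. These
sizes make every property observable at full strength while keeping a
complete run in the minutes range on one core.

## Known limitations

* Stage paths are serpentine, not travelling-salesman optimal; focus
  maps and per-tile exposure are out of scope.
* The settings dialect is an explicit stand-in: real vendor metadata
  files are not parsed.
* Grey-dilation rim measurement is approximate for touching cells (see
  above).
* Savings convergence for boundary-heavy objects is first-order in the
  tile count, the price of never dropping an object pixel.
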