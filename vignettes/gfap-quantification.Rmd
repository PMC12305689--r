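---
title: "Quantifying the spatial GFAP response to focal proton irradiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the spatial GFAP response to focal proton irradiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfaptile)
```

## The measurement problem

Months after a focused proton beam is delivered to one hemisphere of a
mouse brain, reactive astrocytes accumulate in and around the irradiated
tissue. Their hallmark is upregulated glial fibrillary acidic protein
(GFAP), so the areal density of GFAP-positive staining in a brain slice is
a spatial readout of astrogliosis, and — because thin slices cross-cut the
thin astrocyte processes — area fraction is the robust statistic, not cell
counts. `gfaptile` implements the complete analysis chain for this
readout:

1. **Segmentation** of the GFAP channel: rolling-ball background
   subtraction (ball radius 3.25 µm), linear conversion to an 8-bit
   scale, Otsu thresholding of the 256-bin histogram, connected-component
   labelling, and removal of segments outside 7–1000 µm² (bounds
   inclusive; sub-resolution specks and large vessel-like structures are
   discarded, erythrocyte and autofluorescence confounders deliberately
   are not).
2. **Tiling**: the slice is divided into 250 µm × 250 µm tiles anchored at
   the image origin; each tile's GFAP+ fraction is the summed retained
   segment area divided by the tile area.
3. **Dose co-registration**: a planning-grid dose raster is mapped into
   slice pixel coordinates by a least-squares affine transform fitted to
   landmarks (or a known transform) and resampled bilinearly; pixels
   outside the grid footprint receive 0 Gy.
4. **Mirrored ROIs**: a square region of interest (default 2.4 mm) centred
   on the beam axis in the irradiated (right) hemisphere, and its exact
   reflection about the midline in the contralateral hemisphere.
5. **Statistics**: per-slice mean ROI fractions, per-dose-level mean ± SD,
   and an ordinary least-squares regression of mean right-ROI fraction on
   prescription dose with a two-sided Wald *t*-test of the slope
   (significance level 0.05). Beam-axis depth profiles and transverse
   band profiles (cerebral cortex vs central brain) compare the spatial
   GFAP response with the dose distribution.

## The synthetic phantom

Real slice images for this assay are not publicly archived, so the package
ships a first-class generator that emulates the statistical structure the
analysis relies on. It is the basis of every end-to-end test.

The GFAP channel is a Boolean object model: branched curvilinear objects
(2–4 polyline branches of 8–25 µm with an angular kink, dilated to 1–3 px)
stand in for GFAP-stained astrocyte fragments. The expected covered
fraction at a tile is

```
density(tile) = baseline(band) + slope × mean local dose(tile)
```

with a lower baseline in the lateral "cortex" shells than in the central
band. To realise a target coverage *v* despite object overlap, objects are
placed with area intensity `-log(1 - v)` per tile (the exact Boolean-model
correction); objects are added sequentially until their summed individual
areas reach the target, with the final object accepted with probability
proportional to the remaining deficit so the expected placed area is
unbiased. Punctate bright discs emulate erythrocyte/autofluorescence
confounders (they are *not* part of the ground-truth mask), a smooth
background gradient and Gaussian noise complete the channel, and a DAPI
channel with nuclear blobs is generated for realism. All randomness flows
from a single integer seed; identical configurations give bit-identical
rasters.

The dose field is an analytic stand-in for a Monte Carlo proton
simulation: the depth profile has an entrance plateau (default 30% of the
peak) rising through a proximal Gaussian shoulder to a single Bragg-peak
maximum and falling distally below 1% of the maximum within ~3.1
`sigma_distal`; the lateral profile is the collimator top-hat convolved
with a Gaussian penumbra. Values are evaluated on the planning grid and
rescaled so that the grid maximum equals the prescription exactly — that
keeps "doubling the prescription doubles every value" true while being
robust to the grid sampling the sharp peak slightly off-centre. The beam
enters the right image edge and travels toward the midline, so the left
hemisphere receives essentially 0 Gy.

### What the phantom does and does not show

The phantom reproduces the features the pipeline's statistics depend on:
filamentous morphology at realistic process calibre relative to the
rolling-ball radius, dose-proportional density on top of band-structured
baselines, hemispheric asymmetry with a sham-symmetric null, and
confounders that survive the area filter. It does **not** model real
astrocyte arbors, 3-D tissue context, optical point-spread functions, or
anatomically curved region boundaries. Green tests therefore demonstrate
that the *pipeline* measures what it claims on data with known truth —
not that any particular biological effect size is correct.

## Default parameters and why

| Parameter | Default | Rationale |
|---|---|---|
| pixel size | 2 µm/px | reduced-scale canvas (4 × 6 mm at 2000 × 3000 px) that runs in seconds; the study value (0.65 µm) is a free parameter |
| rolling-ball radius | 3.25 µm | study protocol; ≥ 1 px required at any resolution |
| area filter | 7–1000 µm², inclusive | study protocol; bounds converted via pixel_size², never to rounded pixel counts |
| connectivity | 8-neighbour | keeps 1-px-wide filaments connected; 4-neighbour available |
| tile size | 250 µm | study protocol; must be an integer number of pixels |
| ROI size | 2.4 mm | study protocol ("approximately 2.4 mm") |
| baselines (central/cortex) | 0.02 / 0.008 | sham GFAP+ fractions of a few percent, cortex visibly sparser |
| dose-response slope | 0.003 Gy⁻¹ | sized so the expected right-ROI fraction roughly doubles between 45 and 85 Gy while peak coverage stays below ~0.3 |
| confounders | 10 mm⁻², discs 1.5–4 µm | sparse bright punctae, a small additive bias by design |
| noise SD | 100 (16-bit-scale units) | well below object amplitude (~4000) so thresholding is stable |

Dose levels (0/45/65/85 Gy, three slices per level) mirror the study's
cohort design; sham slices are included in the regression by default (a
flag excludes them).

## Numerical choices

* **Coordinates** are (row, col), 0-based, with pixel/cell centres at
  integer positions — stated once in `affine2d()` and used everywhere.
* **8-bit conversion** rounds half away from zero, matching the common
  imaging convention, so `{100, 600, 1100}` maps to `{0, 128, 255}`.
* **Otsu ties** are broken toward the lower threshold. With empty
  histogram bins between modes the maximiser is a plateau; any
  deterministic rule picks one end, which is why the complement-image
  invariant is equality of between-class variance rather than of the
  threshold itself.
* **Rolling ball** is implemented as grayscale opening with a non-flat
  spherical-cap structuring element (heights √(r²−d²)), with the
  neighbourhood clipped at image borders so constant images map exactly
  to zero.
* **Registration** is a 6-parameter affine rather than a deformable
  chain: the quantities consumed downstream (tile means, ROI means,
  250 µm profiles) tolerate the study's stated 0.5–1.5 mm registration
  uncertainty, and an affine is fully testable through round trips.
  Bilinear interpolation is used for the "upscaling" step; out-of-footprint
  dose is 0 Gy rather than extrapolated.
* **Tile membership** of an ROI is by tile centre, and border-truncated
  tiles are excluded from ROI means and profiles by default (their
  denominators differ).
* **Degenerate fits** (zero residual variance) return p = 1 for a zero
  slope and p = 0 otherwise, instead of NaN.

## Problem sizes used by the tests

Replicated end-to-end runs use a 750 × 1125 px phantom at 2 µm/px
(1.5 × 2.25 mm) with a 1 mm beam and 1 mm ROIs — a geometry-preserving
reduction of the default canvas chosen so that a 12-slice pipeline run
takes a few seconds and replicate sets complete in minutes. Sham-symmetry
checks use the full 4 × 6 mm canvas, averaging beam-axis profiles over
three sham slices (the study's slices-per-animal) and smoothing at 750 µm
before comparing mirrored positions. The dose-response recovery check
compares the fitted slope with `slope × mean relative ROI dose` and allows
up to 30% attenuation: segmentation loses interiors of merged
high-coverage clusters to the 1000 µm² cap and flattens dense object hubs
into the background estimate, which attenuates measured slopes by ~20–30%
— the same morphology-dependent bias the real protocol carries.

## Worked example

```{r example, eval = FALSE}
library(gfaptile)

cfg <- pipeline_config(
  phantom = phantom_config(seed = 1, image_shape = c(750L, 1125L),
                           pixel_size = 2, beam_diameter = 1000),
  doses = c(0, 45, 65, 85), slices_per_level = 3,
  roi_size = 1000, seed = 1, log_level = "quiet")
res <- run_pipeline(cfg, out_dir = "gfap-results")
res$hemispheres
res$fit_right
plot(res$fit_right)
```

The result bundle carries per-slice segment sets, tile maps, resampled
dose rasters, ROI means, and beam-axis/band profiles; `out_dir` receives
the CSV/JSON exports with a provenance record (config hash, seed,
package version).

## Known limitations

* Cell counts, single-cell morphology and co-staining-based confounder
  rejection are out of scope by design.
* The beam axis must be aligned with the image grid; rotated acquisitions
  should be rotated before analysis rather than tiled obliquely.
* Anatomical bands are axis-aligned rectangles supplied by configuration,
  not atlas regions; boundary tiles mix band baselines.
* Mixed-effects modelling of slice-within-animal correlation is not
  implemented; the regression treats slices as independent points, with
  per-animal aggregation available by averaging beforehand.
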