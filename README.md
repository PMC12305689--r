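# gfaptile

Tile-based quantification of the reactive-astrocyte (GFAP) response to
focal proton irradiation in brain slice images.

## The problem

After partial-brain proton irradiation, reactive astrocytes upregulate
glial fibrillary acidic protein (GFAP). Because thin histological slices
cross-cut the filamentous astrocyte processes, counting cells is
unreliable; the robust spatial readout is the **GFAP-positive area
fraction** — the fraction of each 250 µm × 250 µm tile covered by
segmented GFAP signal. `gfaptile` implements the full analysis for this
readout, for radiobiologists and image analysts who need to relate a
histological marker to a planned dose distribution:

* **Segmentation** of the GFAP channel exactly as the established
  protocol prescribes: rolling-ball background subtraction (radius
  3.25 µm), 8-bit conversion, Otsu thresholding, and removal of connected
  components outside 7–1000 µm² (bounds inclusive).
* **Tile fraction maps** on a 250 µm lattice: `fraction = Σ segment area
  / tile area`.
* **Dose co-registration**: least-squares affine mapping of a
  planning-grid dose raster into slice pixels, bilinear resampling, and
  isodose region extraction (e.g. the 80% isodose used for slice
  selection).
* **Mirrored hemisphere ROIs**: a ~2.4 mm square centred on the beam axis
  in the irradiated hemisphere and its exact reflection about the
  midline.
* **Statistics**: ordinary least-squares regression of mean right-ROI
  fraction on prescription dose *D* with a two-sided Wald *t*-test of the
  slope,

  `fraction = a + b·D`,  `t = b / SE(b)` on *n* − 2 df, α = 0.05,

  per-dose-level mean ± SD summaries, and dose/GFAP profiles along the
  beam axis and transverse to it (cerebral cortex vs central brain
  bands).
* **A synthetic phantom** (two imaging channels, matched dose grid,
  ground-truth masks) that emulates the study geometry — collimated beam
  with entrance plateau, Bragg peak, distal falloff and lateral penumbra,
  dose-proportional filament density, band-structured baselines,
  punctate confounders — so the entire pipeline is testable without
  animal data.

## Worked example

```r
library(gfaptile)

cfg <- pipeline_config(
  phantom = phantom_config(seed = 1, image_shape = c(750L, 1125L),
                           pixel_size = 2, beam_diameter = 1000),
  doses = c(0, 45, 65, 85), slices_per_level = 3,
  roi_size = 1000, seed = 1, log_level = "quiet")
res <- run_pipeline(cfg)
print(res)
```

```
<gfaptile_result> 12 slices, dose levels: 0/45/65/85 Gy
Mean ROI GFAP+ fraction by dose level (right / left hemisphere)
 dose n right_mean right_sd left_mean   left_sd
    0 3    0.01473 0.000382   0.01457 0.0004040
   45 3    0.07248 0.001014   0.01447 0.0004414
   65 3    0.09304 0.003262   0.01457 0.0003314
   85 3    0.10319 0.003104   0.01435 0.0002768
paired right-left difference: mean 0.05637 over 12 slices

Right-ROI fit:
Linear dose-response fit (GFAP+ fraction vs prescription dose)
  slope     0.00107408 +/- 5.64e-05 per Gy
  intercept 0.018498 +/- 0.00328
  Wald test (t, df = 10): p = 3.482e-09 -> slope significantly different from 0 at alpha = 0.05
  r = 0.9865, n = 12

Left-ROI fit:
Linear dose-response fit (GFAP+ fraction vs prescription dose)
  slope     -1.92714e-06 +/- 3.1e-06 per Gy
  intercept 0.0145856 +/- 0.00018
  Wald test (t, df = 10): p = 0.5477 -> slope not significantly different from 0 at alpha = 0.05
  r = -0.1931, n = 12
```

Reading the numbers: the irradiated-hemisphere ROI climbs from ~1.5%
GFAP+ area (sham) to ~10% at 85 Gy and the Wald test rejects a zero slope
(p ≈ 3×10⁻⁹), while the mirrored contralateral ROI stays at the sham
level at every dose (p ≈ 0.55) — the phantom-scale analogue of a
significant, approximately linear dose response confined to the
irradiated hemisphere. With `out_dir =` the run also writes per-slice
tile maps, profiles, the per-slice summary and a JSON report with
provenance (config hash, seed, package version). Lower-level entry
points (`segment_gfap()`, `compute_tile_fractions()`,
`fit_affine_from_landmarks()`, `resample_dose()`, `beam_axis_profile()`,
`fit_dose_response()`, …) expose each stage separately; a thin
command-line wrapper lives at `inst/scripts/run_gfaptile.R`. The methods
vignette (`vignettes/gfap-quantification.Rmd`) documents the model,
parameter defaults and numerical choices.

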