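# Reduced-scale phantom configurations used across the suite.
#
# "small": 750 x 1125 px at 2 um/px (1.5 x 2.25 mm), 1 mm beam; the scale
# used for replicated pipeline runs.
# "tiny": 400 x 600 px, for fast unit tests of plumbing.

small_phantom_config <- function(seed = 1L, dose = 45, ...) {
  phantom_config(seed = seed, image_shape = c(750L, 1125L), pixel_size = 2,
                 prescription_dose = dose, beam_diameter = 1000, ...)
}

tiny_phantom_config <- function(seed = 1L, dose = 45, ...) {
  # 375 x 625 px at 2 um/px: an exact 3 x 5 lattice of 250 um tiles
  phantom_config(seed = seed, image_shape = c(375L, 625L), pixel_size = 2,
                 prescription_dose = dose, beam_diameter = 600, ...)
}

small_rois <- function(cfg, roi_size = 1000) {
  define_mirrored_rois(cfg$image_shape, cfg$beam_entry_row, cfg$midline_col,
                       phantom_peak_col(cfg), roi_size, cfg$pixel_size)
}

small_pipeline_config <- function(seed = 1L, doses = c(0, 45, 65, 85),
                                  slices_per_level = 3L) {
  pipeline_config(phantom = small_phantom_config(), doses = doses,
                  slices_per_level = slices_per_level, roi_size = 1000,
                  seed = seed, log_level = "quiet")
}

# mean relative local dose (fraction of prescription) over the right-ROI
# pixels of a generated phantom; the implied dose-response slope of mean
# ROI fraction vs prescription is dose_response_slope times this factor
roi_mean_relative_dose <- function(ph, roi) {
  if (ph$config$prescription_dose <= 0) return(0)
  sel <- ph$dose_slice[(roi$row_min:roi$row_max) + 1L,
                       (roi$col_min:roi$col_max) + 1L]
  mean(sel) / ph$config$prescription_dose
}
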