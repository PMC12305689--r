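# build a segment_set directly from a logical mask (all pixels retained)
mask_segments <- function(mask, pixel_size = 1) {
  filter_segments(mask, segmentation_params(min_area = 1e-9, max_area = 1e12), pixel_size)
}

test_that("tile fractions handle empty and saturated tiles", {
  empty <- mask_segments(matrix(FALSE, 20, 30))
  m0 <- compute_tile_fractions(empty, 10)
  expect_true(all(m0$fractions == 0))
  expect_equal(dim(m0$fractions), c(2, 3))

  sat <- matrix(FALSE, 20, 20); sat[1:10, 1:10] <- TRUE
  m1 <- compute_tile_fractions(mask_segments(sat), 10)
  expect_equal(m1$fractions[1, 1], 1.0)
  expect_true(all(m1$full))
})

test_that("tile fractions equal nested-loop pixel counts, including partial tiles", {
  set.seed(17)
  mask <- matrix(runif(130 * 170) < 0.2, 130, 170)
  seg <- mask_segments(mask, 2)
  map <- compute_tile_fractions(seg, 100)   # 50 px tiles; 130/50, 170/50 leave partials
  oracle <- tile_fractions_nested(seg$label_map, 50, 2)
  expect_equal(map$fractions, oracle$fractions, tolerance = 1e-12)
  expect_identical(map$full, oracle$full)
  expect_false(all(map$full))
})

test_that("summed tile areas conserve the total retained segment area", {
  set.seed(19)
  mask <- matrix(runif(96 * 96) < 0.3, 96, 96)
  seg <- mask_segments(mask, 0.65)
  map <- compute_tile_fractions(seg, 0.65 * 32)   # 32 px tiles, all full
  total_from_tiles <- sum(map$fractions * map$tile_size^2)
  expect_equal(total_from_tiles, sum(mask) * 0.65^2, tolerance = 1e-9)
})

test_that("tile size constraints are enforced", {
  seg <- mask_segments(matrix(FALSE, 50, 50), 2)
  expect_error(compute_tile_fractions(seg, 15), "at least 10")
  expect_error(compute_tile_fractions(seg, 101), "integer number of pixels")
  expect_warning(compute_tile_fractions(seg, 200), "larger than the image")
})

test_that("mirrored ROIs reflect exactly and the reflection is an involution", {
  rois <- define_mirrored_rois(c(2000, 3000), 1000, 1500, 2200,
                               roi_size = 2400, pixel_size = 2)
  r <- rois$right; l <- rois$left
  expect_equal(r$row_max - r$row_min + 1L, 1200L)   # 2.4 mm at 2 um
  expect_equal(r$col_max - r$col_min + 1L, 1200L)
  expect_identical(l$row_min, r$row_min)
  # reflection about the mirror axis
  expect_identical(l$col_min, 2L * 1500L - r$col_max)
  expect_identical(l$col_max, 2L * 1500L - r$col_min)
  # reflecting the left ROI again returns the right ROI
  expect_identical(2L * 1500L - l$col_max, r$col_min)
  expect_identical(2L * 1500L - l$col_min, r$col_max)
  # offset +d on the right maps to -d on the left
  d_right <- r$col_min - 1500L
  d_left <- 1500L - l$col_max
  expect_identical(d_right, d_left)

  expect_error(define_mirrored_rois(c(2000, 3000), 1000, 1500, 1550,
                                    roi_size = 2400, pixel_size = 2),
               "crosses")
  expect_error(define_mirrored_rois(c(2000, 3000), 100, 1500, 2100,
                                    roi_size = 2400, pixel_size = 2),
               "fit")
})

test_that("ROI means follow constant fields, two-tile averages and the enumeration oracle", {
  uni <- matrix(FALSE, 40, 40); uni[seq(1, 40, 2), ] <- TRUE   # fraction 0.5 everywhere
  map_u <- compute_tile_fractions(mask_segments(uni), 10)
  roi <- roi_spec(0, 39, 0, 39, side = "right", mirror_axis_col = NA)
  expect_equal(mean_roi_fraction(map_u, roi), 0.5, tolerance = 1e-12)

  two <- matrix(FALSE, 10, 20)
  two[1, 1:10] <- TRUE                      # tile 1: 10/100 = 0.1
  two[1:3, 11:20] <- TRUE                   # tile 2: 30/100 = 0.3
  map_t <- compute_tile_fractions(mask_segments(two), 10)
  roi_t <- roi_spec(0, 9, 0, 19, side = "right", mirror_axis_col = NA)
  expect_equal(mean_roi_fraction(map_t, roi_t), 0.2, tolerance = 1e-12)

  set.seed(29)
  mask <- matrix(runif(80 * 80) < 0.25, 80, 80)
  map_r <- compute_tile_fractions(mask_segments(mask), 16)
  roi_r <- roi_spec(11, 62, 19, 73, side = "right", mirror_axis_col = NA)
  # oracle: enumerate tile centres directly
  centres <- (0:4) * 16 + 7.5
  vals <- c()
  for (i in 1:5) for (j in 1:5) {
    if (centres[i] >= 11 && centres[i] <= 62 && centres[j] >= 19 && centres[j] <= 73)
      vals <- c(vals, map_r$fractions[i, j])
  }
  expect_equal(mean_roi_fraction(map_r, roi_r), mean(vals), tolerance = 1e-12)

  empty_roi <- roi_spec(0, 2, 0, 2, side = "right", mirror_axis_col = NA)
  expect_error(mean_roi_fraction(map_r, empty_roi), "no tile centres")
})

test_that("ROI means are exactly mirror-consistent on symmetric maps", {
  set.seed(33)
  half <- matrix(runif(60 * 40) < 0.3, 60, 40)
  mask <- cbind(half, half[, 40:1])   # symmetric under col' = 79 - col
  map <- compute_tile_fractions(mask_segments(mask), 10)
  # tile-aligned ROIs that are mirror images under the same reflection
  right <- roi_spec(10, 49, 50, 69, side = "right", mirror_axis_col = NA)
  left <- roi_spec(10, 49, 10, 29, side = "left", mirror_axis_col = NA)
  expect_identical(mean_roi_fraction(map, right), mean_roi_fraction(map, left))
})

test_that("beam-axis profiles are flat on uniform maps and peak with the dose", {
  uni <- matrix(FALSE, 60, 100); uni[seq(1, 60, 2), ] <- TRUE
  map <- compute_tile_fractions(mask_segments(uni), 10)
  dose <- matrix(0, 60, 100); dose[, 41:50] <- 30   # single interior maximum
  roi <- roi_spec(10, 49, 61, 99, side = "right", mirror_axis_col = 50)
  pr <- beam_axis_profile(map, dose, roi)
  expect_true(all(abs(pr$gfap_mean - 0.5) < 1e-12))
  expect_equal(nrow(pr), 10L)               # full slice along the beam
  # oracle: argmax of the direct tile means of the dose
  expect_equal(which.max(pr$dose_mean_Gy), 5L)
  expect_error(beam_axis_profile(map, dose,
                                 roi_spec(0, 1, 0, 99, "right", NA)),
               "transverse")
})

test_that("transverse band profiles match direct per-band means and reject overlap", {
  set.seed(37)
  mask <- matrix(runif(60 * 120) < 0.3, 60, 120)
  map <- compute_tile_fractions(mask_segments(mask), 10)
  dose <- matrix(runif(60 * 120, 0, 20), 60, 120)
  cortex <- roi_spec(0, 59, 100, 119, side = "band", mirror_axis_col = NA)
  central <- roi_spec(0, 59, 40, 79, side = "band", mirror_axis_col = NA)
  pr <- transverse_band_profiles(map, dose, cortex, central)
  # oracle: direct means over tile columns 11..12 (cortex) and 5..8 (central)
  dm <- tile_mean_map(dose, map)
  expect_equal(pr$cortex$gfap_mean, rowMeans(map$fractions[, 11:12]), tolerance = 1e-12)
  expect_equal(pr$central$gfap_mean, rowMeans(map$fractions[, 5:8]), tolerance = 1e-12)
  expect_equal(pr$central$dose_mean_Gy, rowMeans(dm[, 5:8]), tolerance = 1e-12)
  # two disjoint bands with identical content give identical profiles
  mask2 <- mask; mask2[, 101:120] <- mask2[, 1:20]
  dose2 <- dose; dose2[, 101:120] <- dose2[, 1:20]
  map2 <- compute_tile_fractions(mask_segments(mask2), 10)
  pr3 <- transverse_band_profiles(map2, dose2,
                                  roi_spec(0, 59, 100, 119, "band", NA),
                                  roi_spec(0, 59, 0, 19, "band", NA))
  expect_equal(pr3$cortex$gfap_mean, pr3$central$gfap_mean, tolerance = 1e-12)
  expect_equal(pr3$cortex$dose_mean_Gy, pr3$central$dose_mean_Gy, tolerance = 1e-12)
  expect_error(transverse_band_profiles(map, dose, cortex,
                                        roi_spec(0, 59, 110, 119, "band", NA)),
               "overlap")
})
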