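test_that("rolling-ball subtraction removes flat and offset backgrounds exactly", {
  img <- slice_image(matrix(137.5, 40, 50), 0.65)
  out <- subtract_background(img, 3.25)
  expect_true(all(out$values == 0))

  set.seed(42)
  base <- matrix(runif(30 * 30, 0, 500), 30, 30)
  a <- subtract_background(slice_image(base, 0.65), 3.25)
  b <- subtract_background(slice_image(base + 250, 0.65), 3.25)
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("rolling-ball subtraction matches the direct ball-opening oracle and keeps spikes", {
  set.seed(7)
  x <- matrix(runif(21 * 21, 0, 100), 21, 21)
  x[11, 11] <- x[11, 11] + 5000          # 1-px spike of height ~5000
  img <- slice_image(x, 1)
  out <- subtract_background(img, 4)     # radius 4 px >> 1 px
  oracle_bg <- ball_opening_direct(x, 4L)
  expect_equal(out$values, pmax(x - oracle_bg, 0), tolerance = 1e-10)
  h <- 5000
  expect_gte(out$values[11, 11], 0.9 * h)
})

test_that("rolling-ball radius below one pixel is rejected", {
  img <- slice_image(matrix(1:20, 4, 5) * 1.0, 2)
  expect_error(subtract_background(img, 1.9), "one pixel")
})

test_that("8-bit conversion is a min-max rescale with round-half-away-from-zero", {
  img <- slice_image(matrix(c(0, 1000, 0, 1000), 2, 2), 1)
  expect_setequal(unique(as.vector(to_8bit(img)$values)), c(0, 255))

  img2 <- slice_image(matrix(c(100, 600, 1100, 100, 600, 1100), 2, 3), 1)
  out2 <- to_8bit(img2)$values
  expect_equal(sort(unique(as.vector(out2))), c(0, 128, 255))

  set.seed(1)
  v <- matrix(as.numeric(sample(0:255, 100, replace = TRUE)), 10, 10)
  v[1] <- 0; v[100] <- 255   # pin the range
  expect_equal(to_8bit(slice_image(v, 1))$values, v)

  expect_warning(out3 <- to_8bit(slice_image(matrix(5, 3, 3), 1)), "constant")
  expect_true(all(out3$values == 0))
})

test_that("Otsu threshold separates a perfectly bimodal image and rejects constants", {
  v <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  res <- otsu_threshold(slice_image(v, 1))
  expect_true(res$threshold >= 10 && res$threshold < 200)
  expect_identical(res$mask, v > res$threshold)
  expect_identical(sum(res$mask), 50L)
  expect_error(otsu_threshold(slice_image(matrix(7, 5, 5), 1)), "constant")
})

test_that("Otsu threshold equals the brute-force search, with complement symmetry", {
  # between-class variance of the split at t, computed directly
  sb <- function(v, t) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) return(0)
    w0 <- length(lo) / length(v)
    w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  }
  set.seed(11)
  for (i in 1:10) {
    img <- random_8bit(24)
    t_pkg <- otsu_threshold(img)$threshold
    expect_identical(t_pkg, otsu_bruteforce(img$values))
    # intensity reversal maps the split at t to the split at 254 - t; with
    # empty bins between the modes the maximiser is a plateau, so the
    # invariant is equality of the between-class variance, not of t itself
    comp <- slice_image(255 - img$values, 1)
    t_comp <- otsu_threshold(comp)$threshold
    expect_identical(t_comp, otsu_bruteforce(comp$values))
    expect_equal(sb(img$values, 254L - t_comp), sb(img$values, t_pkg),
                 tolerance = 1e-12)
  }
})

test_that("area filter keeps the study bounds inclusively and in physical units", {
  # at 0.65 um px: 16 px = 6.76 um^2 (excluded), 17 px = 7.1825 um^2 (kept)
  m <- matrix(FALSE, 10, 40)
  m[5, 1:16] <- TRUE
  m[8, 21:37] <- TRUE
  seg <- filter_segments(m, segmentation_params(), 0.65)
  expect_length(seg$areas, 1L)
  expect_equal(seg$areas, 17 * 0.65^2)

  # at 1 um px the bounds are hit exactly: 7 and 1000 px kept, 6 and 1001 not
  m2 <- matrix(FALSE, 60, 300)
  m2[2, 1:6] <- TRUE
  m2[5, 1:7] <- TRUE
  m2[10:13, 1:250] <- TRUE              # 1000 px
  m2[20:23, 1:250] <- TRUE; m2[24, 1] <- TRUE  # 1001 px
  seg2 <- filter_segments(m2, segmentation_params(), 1)
  expect_setequal(seg2$areas, c(7, 1000))
})

test_that("component labelling matches a flood-fill oracle for both connectivities", {
  set.seed(23)
  for (i in 1:5) {
    m <- matrix(runif(48 * 48) < 0.35, 48, 48)
    for (conn in c(4L, 8L)) {
      seg <- filter_segments(m, segmentation_params(min_area = 1e-9, max_area = 1e9,
                                                    connectivity = conn), 1)
      expect_identical(seg$label_map, flood_fill_label(m, conn),
                       info = sprintf("iter %d conn %d", i, conn))
    }
  }
  # a diagonal pair is one component under 8- but two under 4-connectivity
  d <- matrix(FALSE, 4, 4); d[1, 1] <- TRUE; d[2, 2] <- TRUE
  p <- function(conn) segmentation_params(min_area = 1e-9, max_area = 1e9, connectivity = conn)
  expect_length(filter_segments(d, p(8L), 1)$areas, 1L)
  expect_length(filter_segments(d, p(4L), 1)$areas, 2L)
})

test_that("4-connectivity labelling agrees with EBImage::bwlabel", {
  skip_if_not_installed("EBImage")
  set.seed(31)
  m <- matrix(runif(64 * 64) < 0.3, 64, 64)
  seg <- filter_segments(m, segmentation_params(min_area = 1e-9, max_area = 1e9,
                                                connectivity = 4L), 1)
  ref <- EBImage::bwlabel(m * 1)
  expect_identical(max(seg$label_map), as.integer(max(ref)))
  # identical partitions: each package label maps to exactly one reference label
  agree <- tapply(ref[m], seg$label_map[m], function(v) length(unique(v)))
  expect_true(all(agree == 1L))
})

test_that("empty masks yield empty segment sets and filtering is monotone in min_area", {
  seg <- filter_segments(matrix(FALSE, 8, 8), segmentation_params(), 1)
  expect_length(seg$areas, 0L)
  expect_true(all(seg$label_map == 0L))

  set.seed(5)
  m <- matrix(runif(64 * 64) < 0.3, 64, 64)
  prev <- Inf
  for (ma in c(1, 4, 9, 25, 100)) {
    tot <- sum(filter_segments(m, segmentation_params(min_area = ma, max_area = 1e9), 1)$areas)
    expect_lte(tot, prev)
    prev <- tot
  }
})

test_that("the segmentation chain is deterministic and does not hallucinate area", {
  cfg <- tiny_phantom_config(seed = 4, dose = 45, noise_sd = 0,
                             baseline_density_central = 0,
                             baseline_density_cortex = 0, confounder_rate = 0,
                             background_level = 0, background_gradient = 0)
  ph <- generate_phantom(cfg)
  seg1 <- segment_gfap(ph$gfap)
  seg2 <- segment_gfap(ph$gfap)
  expect_identical(seg1$label_map, seg2$label_map)
  expect_identical(seg1$areas, seg2$areas)
  # every retained segment overlaps the ground truth (no confounders here)
  for (l in seq_along(seg1$areas)) {
    expect_gt(sum(ph$truth$gfap_mask[seg1$label_map == l]), 0)
  }
})

test_that("segmented area recovers the ground-truth area within the morphology band", {
  cfg <- small_phantom_config(seed = 9, dose = 45)
  ph <- generate_phantom(cfg)
  seg <- segment_gfap(ph$gfap)
  ratio <- sum(seg$areas) / (sum(ph$truth$gfap_mask) * cfg$pixel_size^2)
  expect_gte(ratio, 0.7)
  expect_lte(ratio, 1.1)
})
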