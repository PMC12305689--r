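#' Rolling-ball background subtraction
#'
#' Estimates the slowly varying background of a fluorescence image as the
#' grayscale opening with a ball-shaped (non-flat, spherical-cap)
#' structuring element and subtracts it. Structures narrower than the ball
#' survive the subtraction; smooth background (including any constant
#' offset) is removed exactly, so a constant image maps to zero.
#'
#' @param image a [slice_image].
#' @param radius ball radius in micrometres (default 3.25, the study value).
#' @return A [slice_image] with the background removed (clamped at 0).
#' @export
subtract_background <- function(image, radius = 3.25) {
  stopifnot(inherits(image, "slice_image"))
  if (radius <= 0) stop("'radius' must be positive")
  r_px <- radius / image$pixel_size
  if (r_px < 1)
    stop("rolling-ball radius is smaller than one pixel at this resolution")
  r <- max(1L, as.integer(round(r_px)))
  se <- ball_element(r)
  bg <- morph_dilate(morph_erode(image$values, se$offsets, se$heights),
                     se$offsets, se$heights)
  out <- image$values - bg
  out[out < 0] <- 0
  image$values <- out
  image
}

# Ball structuring element: offsets within the disc of radius r (pixels) and
# heights sqrt(r^2 - d^2) in intensity units.
ball_element <- function(r) {
  d <- expand.grid(dr = -r:r, dc = -r:r)
  keep <- d$dr^2 + d$dc^2 <= r^2
  d <- d[keep, , drop = FALSE]
  list(offsets = cbind(as.integer(d$dr), as.integer(d$dc)),
       heights = sqrt(r^2 - (d$dr^2 + d$dc^2)))
}

#' Convert an image to an 8-bit intensity scale
#'
#' Linear min-max rescale to the integer range 0..255, rounding half away
#' from zero. A constant image yields an all-zero result with a warning
#' (the thresholding stage then rejects it).
#'
#' @param image a [slice_image].
#' @return A [slice_image] whose values are integers in 0..255.
#' @export
to_8bit <- function(image) {
  stopifnot(inherits(image, "slice_image"))
  v <- image$values
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    warning("constant image: 8-bit conversion yields all zeros")
    image$values <- array(0, dim(v))
    return(image)
  }
  image$values <- floor(255 * (v - lo) / (hi - lo) + 0.5)
  image
}

#' Otsu threshold of an 8-bit image
#'
#' Finds the integer threshold t in 0..255 maximising the between-class
#' variance of the 256-bin histogram; the foreground mask is `values > t`.
#' Ties are broken toward the lower threshold.
#'
#' @param image a [slice_image] with integer values in 0..255 (as produced
#'   by [to_8bit()]).
#' @return A list with elements `threshold` (integer) and `mask` (logical
#'   matrix).
#' @export
otsu_threshold <- function(image) {
  stopifnot(inherits(image, "slice_image"))
  v <- image$values
  if (any(v < 0) || any(v > 255) || any(v != floor(v)))
    stop("otsu_threshold expects integer values in 0..255; run to_8bit() first")
  h <- tabulate(as.integer(v) + 1L, nbins = 256L)
  if (sum(h > 0) < 2L) stop("constant image: no valid Otsu threshold")
  n <- sum(h)
  p <- h / n
  lev <- 0:255
  w0 <- cumsum(p)                 # weight of class {<= t}
  s0 <- cumsum(p * lev)           # first moment of class {<= t}
  mu_t <- s0[256]
  sb <- (mu_t * w0 - s0)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf      # empty classes are not valid thresholds
  t <- which.max(sb) - 1L         # which.max takes the first (lowest) maximum
  list(threshold = t, mask = v > t)
}

#' Label and area-filter segmented components
#'
#' Labels connected components of a binary mask and removes components whose
#' physical area falls outside the retained band. The study bounds
#' (7 and 1000 um^2) are inclusive for retention: components of exactly
#' 7 or 1000 um^2 are kept. Areas are pixel counts times `pixel_size^2`,
#' so the bounds stay exact across resolutions.
#'
#' @param mask logical matrix of foreground pixels.
#' @param params a [segmentation_params].
#' @param pixel_size pixel edge in micrometres.
#' @return An object of class `segment_set` with fields `label_map`
#'   (integer matrix, 0 = background, labels 1..K consecutive), `areas`
#'   (numeric vector of retained areas in um^2, indexed by label),
#'   `params`, and `pixel_size`.
#' @export
filter_segments <- function(mask, params = segmentation_params(), pixel_size) {
  if (!is.logical(mask) || !is.matrix(mask)) stop("'mask' must be a logical matrix")
  stopifnot(inherits(params, "segmentation_params"))
  if (pixel_size <= 0) stop("'pixel_size' must be positive")
  lab <- label_components_cpp(mask, params$connectivity)
  nlab <- max(lab)
  px_area <- pixel_size^2
  if (nlab == 0L) {
    return(structure(list(label_map = lab, areas = numeric(0),
                          params = params, pixel_size = pixel_size),
                     class = "segment_set"))
  }
  counts <- tabulate(lab[lab > 0L], nbins = nlab)
  areas <- counts * px_area
  keep <- areas >= params$min_area & areas <= params$max_area
  remap <- integer(nlab)
  remap[keep] <- seq_len(sum(keep))
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  structure(list(label_map = out, areas = areas[keep], params = params,
                 pixel_size = pixel_size),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments, total area %.1f um^2 (bounds [%g, %g] um^2, %d-connectivity)\n",
              length(x$areas), sum(x$areas), x$params$min_area,
              x$params$max_area, x$params$connectivity))
  invisible(x)
}

#' Full GFAP segmentation chain
#'
#' Applies the study's preprocessing chain to a GFAP channel image:
#' rolling-ball background subtraction, 8-bit conversion, Otsu thresholding
#' over the whole slice, then connected-component area filtering.
#'
#' @param image a [slice_image] (GFAP channel).
#' @param params a [segmentation_params].
#' @return A `segment_set` with an additional `threshold` field recording
#'   the Otsu threshold used.
#' @export
segment_gfap <- function(image, params = segmentation_params()) {
  sub <- subtract_background(image, params$rolling_ball_radius)
  eight <- to_8bit(sub)
  th <- otsu_threshold(eight)
  seg <- filter_segments(th$mask, params, image$pixel_size)
  seg$threshold <- th$threshold
  seg
}

#' Per-segment summary table
#'
#' @param segments a `segment_set`.
#' @return A data frame with columns `label`, `area_um2`, `centroid_row`,
#'   `centroid_col` (0-based pixel coordinates).
#' @export
segment_table <- function(segments) {
  stopifnot(inherits(segments, "segment_set"))
  lab <- segments$label_map
  idx <- which(lab > 0L)
  if (length(idx) == 0L)
    return(data.frame(label = integer(0), area_um2 = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0)))
  l <- lab[idx]
  r <- (idx - 1L) %% nrow(lab)
  c <- (idx - 1L) %/% nrow(lab)
  data.frame(
    label = seq_along(segments$areas),
    area_um2 = segments$areas,
    centroid_row = as.numeric(tapply(r, l, mean)),
    centroid_col = as.numeric(tapply(c, l, mean)))
}
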