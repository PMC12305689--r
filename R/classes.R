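#' Single-channel slice image
#'
#' Container for a 2-D fluorescence intensity raster with its physical pixel
#' size and slice-level metadata. Intensities are non-negative and stored as
#' a numeric matrix; the pixel size is isotropic and given in micrometres
#' per pixel (the study images were scanned at 0.65 um/px).
#'
#' @param values numeric matrix of non-negative intensities.
#' @param pixel_size pixel edge length in micrometres (> 0).
#' @param channel channel label, `"GFAP"` or `"DAPI"`.
#' @param slice_id character identifier of the slice.
#' @param quality_score integer 1 (poor) to 5 (excellent); metadata only,
#'   not used by any computation.
#' @return An object of class `slice_image`.
#' @export
slice_image <- function(values, pixel_size, channel = c("GFAP", "DAPI"),
                        slice_id = "slice", quality_score = 5L) {
  channel <- match.arg(channel)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (anyNA(values) || any(values < 0))
    stop("slice intensities must be non-negative and non-missing")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number")
  quality_score <- as.integer(quality_score)
  if (is.na(quality_score) || quality_score < 1L || quality_score > 5L)
    stop("'quality_score' must be an integer in 1..5")
  structure(
    list(values = values, pixel_size = pixel_size, channel = channel,
         slice_id = as.character(slice_id), quality_score = quality_score),
    class = "slice_image")
}

#' @export
print.slice_image <- function(x, ...) {
  cat(sprintf("<slice_image> %s [%s], %d x %d px @ %.3g um/px (%.2f x %.2f mm), quality %d\n",
              x$slice_id, x$channel, nrow(x$values), ncol(x$values),
              x$pixel_size,
              nrow(x$values) * x$pixel_size / 1000,
              ncol(x$values) * x$pixel_size / 1000, x$quality_score))
  invisible(x)
}

#' Dose grid
#'
#' A 2-D raster of absorbed dose in Gy on a regular planning grid, together
#' with the grid spacing, the in-grid beam axis direction and the
#' prescription dose. The grid maximum may exceed the prescription by at
#' most 5% (tolerance for penumbra/normalisation effects).
#'
#' @param values numeric matrix of doses in Gy (>= 0).
#' @param spacing grid cell edge in micrometres.
#' @param beam_direction unit 2-vector (d_row, d_col) of beam travel in grid
#'   coordinates; must be axis-aligned.
#' @param prescription_dose prescription dose in Gy.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, spacing, beam_direction = c(0, -1),
                      prescription_dose) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (anyNA(values) || any(values < 0)) stop("doses must be >= 0")
  if (spacing <= 0) stop("'spacing' must be positive")
  if (prescription_dose < 0) stop("'prescription_dose' must be >= 0 (0 = sham)")
  if (max(values) > prescription_dose * 1.05)
    stop("grid maximum exceeds prescription dose by more than 5%")
  bd <- as.numeric(beam_direction)
  if (length(bd) != 2L || sum(bd != 0) != 1L || any(abs(bd[bd != 0]) != 1))
    stop("'beam_direction' must be an axis-aligned unit vector")
  structure(
    list(values = values, spacing = spacing, beam_direction = bd,
         prescription_dose = prescription_dose),
    class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d x %d cells @ %g um, prescription %g Gy, max %.2f Gy, beam (%g,%g)\n",
              nrow(x$values), ncol(x$values), x$spacing, x$prescription_dose,
              max(x$values), x$beam_direction[1], x$beam_direction[2]))
  invisible(x)
}

#' 2-D affine transform
#'
#' A 2x3 matrix mapping dose-grid coordinates (row, col) to slice pixel
#' coordinates. Coordinates are 0-based with pixel/cell centres at integer
#' positions; this convention is used throughout the package.
#'
#' @param matrix a 2x3 numeric matrix `[A | t]` so that
#'   `dst = A %*% src + t`.
#' @return An object of class `affine2d`.
#' @export
affine2d <- function(matrix) {
  m <- base::matrix(as.numeric(matrix), 2L, 3L)
  det <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (!is.finite(det) || abs(det) < .Machine$double.eps * 100)
    stop("linear part of the affine transform is singular")
  structure(list(matrix = m, det = det), class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("<affine2d> dst = A src + t, det(A) =", format(x$det), "\n")
  print(x$matrix)
  invisible(x)
}

#' Segmentation parameters
#'
#' Parameters of the GFAP segmentation chain. Defaults follow the study
#' protocol: rolling-ball radius 3.25 um, retained segment areas between
#' 7 and 1000 um^2 (bounds inclusive), 8-neighbour connectivity.
#'
#' @param rolling_ball_radius rolling-ball radius in micrometres.
#' @param min_area minimum retained segment area in um^2 (inclusive).
#' @param max_area maximum retained segment area in um^2 (inclusive).
#' @param connectivity 4 or 8 neighbour connectivity for component labelling.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(rolling_ball_radius = 3.25, min_area = 7,
                                max_area = 1000, connectivity = 8L) {
  if (rolling_ball_radius <= 0) stop("'rolling_ball_radius' must be positive")
  if (!(min_area > 0 && min_area < max_area))
    stop("need 0 < min_area < max_area")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("'connectivity' must be 4 or 8")
  structure(
    list(rolling_ball_radius = rolling_ball_radius, min_area = min_area,
         max_area = max_area, connectivity = connectivity),
    class = "segmentation_params")
}

#' Rectangular region of interest
#'
#' An axis-aligned rectangle in 0-based slice pixel coordinates (bounds
#' inclusive), tagged with the hemisphere it belongs to and the mirror-axis
#' column about which left/right ROIs correspond.
#'
#' @param row_min,row_max,col_min,col_max inclusive pixel bounds (0-based).
#' @param side `"right"`, `"left"`, or `"band"` for anatomical bands.
#' @param mirror_axis_col pixel column of the hemisphere mirror axis
#'   (may be `NA` for bands).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(row_min, row_max, col_min, col_max,
                     side = c("right", "left", "band"), mirror_axis_col = NA) {
  side <- match.arg(side)
  if (row_min > row_max || col_min > col_max)
    stop("ROI bounds must satisfy min <= max")
  structure(
    list(row_min = row_min, row_max = row_max, col_min = col_min,
         col_max = col_max, side = side,
         mirror_axis_col = mirror_axis_col),
    class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec:%s> rows [%d, %d], cols [%d, %d]\n", x$side,
              x$row_min, x$row_max, x$col_min, x$col_max))
  invisible(x)
}

roi_overlaps <- function(a, b) {
  a$row_min <= b$row_max && b$row_min <= a$row_max &&
    a$col_min <= b$col_max && b$col_min <= a$col_max
}
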