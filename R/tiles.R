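# Tile lattice helpers. The lattice is anchored at pixel (0,0); tile (i,j)
# covers pixel rows [i*tpx, (i+1)*tpx - 1]. Tiles truncated by the image
# border are "partial" and flagged.

tile_sums <- function(values, tpx) {
  nr <- nrow(values); nc <- ncol(values)
  row_tile <- (0:(nr - 1L)) %/% tpx
  col_tile <- (0:(nc - 1L)) %/% tpx
  s <- rowsum(values, row_tile, reorder = TRUE)
  s <- t(rowsum(t(s), col_tile, reorder = TRUE))
  dimnames(s) <- NULL
  counts <- outer(tabulate(row_tile + 1L, max(row_tile) + 1L),
                  tabulate(col_tile + 1L, max(col_tile) + 1L))
  list(sums = s, counts = counts)
}

#' Tile-based GFAP+ area fraction map
#'
#' Divides the slice into a regular lattice of square tiles (default
#' 250 um) anchored at the image origin, and computes for each tile the
#' fraction of its area covered by retained segments: summed segment area
#' divided by tile area. Edge tiles truncated by the image border use their
#' actual covered area as denominator and are flagged as partial.
#'
#' @param segments a `segment_set` (see [filter_segments()]).
#' @param tile_size tile edge in micrometres; must be at least 10 pixels
#'   and an integer number of pixels.
#' @return An object of class `tile_fraction_map` with fields `fractions`
#'   (tiles-by-tiles matrix in `[0,1]`), `full` (logical matrix, TRUE for
#'   complete tiles), `counts` (pixels per tile), `tile_size`, `tile_px`,
#'   `pixel_size`, and `origin` (pixel coordinates of tile (0,0), always
#'   `c(0,0)` here).
#' @export
compute_tile_fractions <- function(segments, tile_size = 250) {
  stopifnot(inherits(segments, "segment_set"))
  px <- segments$pixel_size
  if (tile_size < 10 * px)
    stop("'tile_size' must be at least 10 pixels across")
  tpx_f <- tile_size / px
  tpx <- as.integer(round(tpx_f))
  if (abs(tpx_f - tpx) > 1e-8)
    stop("'tile_size' must be an integer number of pixels")
  lab <- segments$label_map
  if (tpx >= nrow(lab) && tpx >= ncol(lab))
    warning("tile larger than the image: single-tile map")
  ts <- tile_sums((lab > 0L) * 1, tpx)
  structure(
    list(fractions = ts$sums / ts$counts,
         full = ts$counts == tpx * tpx,
         counts = ts$counts,
         tile_size = tile_size, tile_px = tpx, pixel_size = px,
         origin = c(0, 0)),
    class = "tile_fraction_map")
}

#' @export
print.tile_fraction_map <- function(x, ...) {
  cat(sprintf("<tile_fraction_map> %d x %d tiles of %g um (%d px), fractions %.4f - %.4f\n",
              nrow(x$fractions), ncol(x$fractions), x$tile_size, x$tile_px,
              min(x$fractions), max(x$fractions)))
  invisible(x)
}

#' Mean of any raster on the tile lattice of a fraction map
#'
#' Used to put the resampled dose on the same lattice as the GFAP
#' fractions.
#'
#' @param raster numeric matrix at slice resolution (same shape as the
#'   segmented slice).
#' @param map a `tile_fraction_map` providing the lattice.
#' @return Matrix of per-tile means with the map's tile dimensions.
#' @export
tile_mean_map <- function(raster, map) {
  stopifnot(inherits(map, "tile_fraction_map"))
  ts <- tile_sums(raster, map$tile_px)
  if (!all(dim(ts$sums) == dim(map$fractions)))
    stop("raster does not match the tile lattice of the map")
  ts$sums / ts$counts
}

# 0-based pixel coordinates of tile centres along one axis.
tile_centres_px <- function(n_tiles, tpx) (seq_len(n_tiles) - 1L) * tpx + (tpx - 1) / 2

#' Mirrored hemisphere regions of interest
#'
#' Defines a square ROI in the right (irradiated) hemisphere, centred on
#' the beam axis at a given depth, and its exact mirror image about the
#' hemisphere midline in the left hemisphere (the study used ~2.4 mm
#' squares). An ROI that would cross the mirror axis or leave the image is
#' an error.
#'
#' @param image_shape integer 2-vector (rows, cols) of the slice in pixels.
#' @param beam_axis_row 0-based row of the beam central axis.
#' @param mirror_axis_col 0-based column of the hemisphere mirror axis.
#' @param centre_col 0-based column of the ROI centre (e.g. the
#'   Bragg-peak depth).
#' @param roi_size ROI edge length in micrometres (default 2400).
#' @param pixel_size pixel edge in micrometres.
#' @return List with [roi_spec] elements `right` and `left`.
#' @export
define_mirrored_rois <- function(image_shape, beam_axis_row, mirror_axis_col,
                                 centre_col, roi_size = 2400, pixel_size) {
  nr <- image_shape[1]; nc <- image_shape[2]
  hpx <- as.integer(round(roi_size / pixel_size))
  if (hpx < 1L) stop("'roi_size' is below one pixel")
  row_min <- as.integer(beam_axis_row) - hpx %/% 2L
  row_max <- row_min + hpx - 1L
  col_min <- as.integer(centre_col) - hpx %/% 2L
  col_max <- col_min + hpx - 1L
  if (row_min < 0L || row_max > nr - 1L || col_min < 0L || col_max > nc - 1L)
    stop("ROI does not fit inside the image")
  m <- as.integer(mirror_axis_col)
  if (col_min <= m && col_max >= m)
    stop("ROI crosses the hemisphere mirror axis")
  side <- if (col_min > m) "right" else "left"
  l_min <- 2L * m - col_max
  l_max <- 2L * m - col_min
  if (l_min < 0L || l_max > nc - 1L)
    stop("mirrored ROI does not fit inside the image")
  a <- roi_spec(row_min, row_max, col_min, col_max, side = side,
                mirror_axis_col = m)
  b <- roi_spec(row_min, row_max, l_min, l_max,
                side = if (side == "right") "left" else "right",
                mirror_axis_col = m)
  if (side == "right") list(right = a, left = b) else list(right = b, left = a)
}

# Tile indices (rows, cols) whose centres fall inside an ROI; full tiles
# only unless include_partial.
roi_tile_sel <- function(map, roi, include_partial = FALSE) {
  cr <- tile_centres_px(nrow(map$fractions), map$tile_px)
  cc <- tile_centres_px(ncol(map$fractions), map$tile_px)
  rows <- which(cr >= roi$row_min & cr <= roi$row_max)
  cols <- which(cc >= roi$col_min & cc <= roi$col_max)
  ok <- matrix(FALSE, nrow(map$fractions), ncol(map$fractions))
  ok[rows, cols] <- TRUE
  if (!include_partial) ok <- ok & map$full
  list(rows = rows, cols = cols, sel = ok)
}

#' Mean GFAP+ fraction over an ROI
#'
#' Unweighted mean over all complete tiles whose centres fall inside the
#' ROI rectangle (membership by tile centre; partial edge tiles excluded
#' by default).
#'
#' @param map a `tile_fraction_map`.
#' @param roi a [roi_spec].
#' @param include_partial include border-truncated tiles.
#' @return The mean fraction (scalar).
#' @export
mean_roi_fraction <- function(map, roi, include_partial = FALSE) {
  stopifnot(inherits(map, "tile_fraction_map"), inherits(roi, "roi_spec"))
  s <- roi_tile_sel(map, roi, include_partial)
  if (!any(s$sel)) stop("no tile centres fall inside the ROI")
  mean(map$fractions[s$sel])
}

new_profile <- function(position_um, gfap_mean, dose_mean, axis, band) {
  structure(
    data.frame(position_um = position_um, gfap_mean = gfap_mean,
               dose_mean_Gy = dose_mean),
    axis = axis, band = band, class = c("gfap_profile", "data.frame"))
}

#' @export
print.gfap_profile <- function(x, ...) {
  cat(sprintf("<gfap_profile> axis %s, band %s, %d positions\n",
              attr(x, "axis"), attr(x, "band"), nrow(x)))
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Dose and GFAP profile along the beam axis
#'
#' For each tile position along the beam direction, averages the GFAP
#' fraction and the dose over all complete tiles lying within the ROI's
#' transverse extent (tile-centre membership). The profile spans the full
#' slice along the beam, not only the ROI depth range. The beam axis is
#' assumed aligned with the tile grid; `axis = "col"` means the beam
#' travels along image columns.
#'
#' @param map a `tile_fraction_map`.
#' @param dose_raster dose matrix at slice resolution (Gy).
#' @param roi [roi_spec] whose transverse extent defines the averaging
#'   band.
#' @param axis `"col"` (beam along columns, the phantom geometry) or
#'   `"row"`.
#' @return A `gfap_profile` data frame (position in um along the beam
#'   axis, mean GFAP fraction, mean dose in Gy).
#' @export
beam_axis_profile <- function(map, dose_raster, roi, axis = c("col", "row")) {
  stopifnot(inherits(map, "tile_fraction_map"), inherits(roi, "roi_spec"))
  axis <- match.arg(axis)
  dm <- tile_mean_map(dose_raster, map)
  fr <- map$fractions
  if (axis == "row") {
    fr <- t(fr); dm <- t(dm); full <- t(map$full)
    cr <- tile_centres_px(nrow(map$fractions), map$tile_px)
    trans <- which(cr >= roi$col_min & cr <= roi$col_max)
    centres <- tile_centres_px(ncol(map$fractions), map$tile_px)
  } else {
    full <- map$full
    cr <- tile_centres_px(nrow(map$fractions), map$tile_px)
    trans <- which(cr >= roi$row_min & cr <= roi$row_max)
    centres <- tile_centres_px(ncol(map$fractions), map$tile_px)
  }
  if (length(trans) == 0L) stop("empty transverse extent: no tile centres inside the ROI width")
  g <- d <- rep(NA_real_, ncol(fr))
  for (j in seq_len(ncol(fr))) {
    ok <- full[trans, j]
    if (any(ok)) {
      g[j] <- mean(fr[trans, j][ok])
      d[j] <- mean(dm[trans, j][ok])
    }
  }
  keep <- !is.na(g)
  new_profile(centres[keep] * map$pixel_size, g[keep], d[keep],
              axis = "along-beam", band = "ROI")
}

#' Transverse dose and GFAP profiles in anatomical bands
#'
#' Averages tile values along the beam direction separately within two
#' non-overlapping bands (cerebral cortex and central brain), yielding
#' profiles versus the transverse (anterior-posterior) position.
#'
#' @param map a `tile_fraction_map`.
#' @param dose_raster dose matrix at slice resolution (Gy).
#' @param cortex_band,central_band [roi_spec] rectangles (must not
#'   overlap).
#' @param axis beam axis: `"col"` (default) or `"row"`.
#' @return List of two `gfap_profile`s, `cortex` and `central`.
#' @export
transverse_band_profiles <- function(map, dose_raster, cortex_band,
                                     central_band, axis = c("col", "row")) {
  axis <- match.arg(axis)
  if (roi_overlaps(cortex_band, central_band))
    stop("cortex and central bands overlap")
  band_profile <- function(band, label) {
    s <- roi_tile_sel(map, band, include_partial = FALSE)
    if (!any(s$sel)) stop(sprintf("no complete tiles inside the %s band", label))
    dm <- tile_mean_map(dose_raster, map)
    if (axis == "col") {
      # beam along columns: transverse position is the tile row
      centres <- tile_centres_px(nrow(map$fractions), map$tile_px)
      n <- nrow(map$fractions)
      g <- d <- rep(NA_real_, n)
      for (i in seq_len(n)) {
        ok <- s$sel[i, ]
        if (any(ok)) { g[i] <- mean(map$fractions[i, ok]); d[i] <- mean(dm[i, ok]) }
      }
    } else {
      centres <- tile_centres_px(ncol(map$fractions), map$tile_px)
      n <- ncol(map$fractions)
      g <- d <- rep(NA_real_, n)
      for (i in seq_len(n)) {
        ok <- s$sel[, i]
        if (any(ok)) { g[i] <- mean(map$fractions[ok, i]); d[i] <- mean(dm[ok, i]) }
      }
    }
    keep <- !is.na(g)
    new_profile(centres[keep] * map$pixel_size, g[keep], d[keep],
                axis = "transverse", band = label)
  }
  list(cortex = band_profile(cortex_band, "cortex"),
       central = band_profile(central_band, "central"))
}
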