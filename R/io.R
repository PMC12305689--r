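# TIFF + JSON sidecar I/O. Intensity channels are stored as 16-bit TIFF
# with the physical scale recorded in the sidecar; dose grids are stored as
# 32-bit float TIFF normalised to the prescription dose, with the 2x3
# grid-to-slice affine (row-major) in the sidecar.

#' Write a slice image as 16-bit TIFF with a JSON sidecar
#'
#' @param image a [slice_image].
#' @param tif_path output TIFF path.
#' @param json_path sidecar path (default `<tif_path>.json`).
#' @param scale intensity mapped to the 16-bit maximum.
#' @return `tif_path`, invisibly.
#' @export
write_slice_tiff <- function(image, tif_path,
                             json_path = paste0(tif_path, ".json"),
                             scale = 65535) {
  stopifnot(inherits(image, "slice_image"))
  v <- pmin(image$values / scale, 1)
  tiff::writeTIFF(v, tif_path, bits.per.sample = 16L)
  meta <- list(pixel_size_um = image$pixel_size, channel = image$channel,
               slice_id = image$slice_id, quality_score = image$quality_score,
               intensity_scale = scale)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(tif_path)
}

#' Read a slice image written by [write_slice_tiff()]
#'
#' @param tif_path TIFF path.
#' @param json_path sidecar path.
#' @return A [slice_image].
#' @export
read_slice_tiff <- function(tif_path, json_path = paste0(tif_path, ".json")) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  v <- tiff::readTIFF(tif_path)
  slice_image(round(v * meta$intensity_scale), meta$pixel_size_um,
              meta$channel, meta$slice_id, meta$quality_score)
}

#' Write a dose grid and its transform
#'
#' @param dose a [dose_grid].
#' @param transform [affine2d] mapping grid coordinates to slice pixels.
#' @param tif_path output TIFF path (32-bit float, dose normalised to the
#'   prescription).
#' @param json_path sidecar path.
#' @return `tif_path`, invisibly.
#' @export
write_dose_tiff <- function(dose, transform, tif_path,
                            json_path = paste0(tif_path, ".json")) {
  stopifnot(inherits(dose, "dose_grid"), inherits(transform, "affine2d"))
  scale <- if (dose$prescription_dose > 0) dose$prescription_dose else 1
  tiff::writeTIFF(pmin(dose$values / scale, 1), tif_path, bits.per.sample = 32L)
  meta <- list(prescription_dose_Gy = dose$prescription_dose,
               spacing_um = dose$spacing,
               beam_direction = dose$beam_direction,
               dose_scale_Gy = scale,
               transform_row_major = as.vector(t(transform$matrix)))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(tif_path)
}

#' Read a dose grid written by [write_dose_tiff()]
#'
#' @param tif_path TIFF path.
#' @param json_path sidecar path.
#' @return List with elements `dose` ([dose_grid]) and `transform`
#'   ([affine2d]).
#' @export
read_dose_tiff <- function(tif_path, json_path = paste0(tif_path, ".json")) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  v <- tiff::readTIFF(tif_path) * meta$dose_scale_Gy
  list(dose = dose_grid(v, meta$spacing_um, meta$beam_direction,
                        meta$prescription_dose_Gy),
       transform = affine2d(matrix(meta$transform_row_major, 2L, 3L,
                                   byrow = TRUE)))
}

#' Export a tile fraction map (with dose) as CSV
#'
#' @param map a `tile_fraction_map`.
#' @param dose_means optional matrix of per-tile mean doses (Gy) on the
#'   same lattice.
#' @param path output CSV path.
#' @return The exported data frame, invisibly.
#' @export
write_tile_map_csv <- function(map, dose_means = NULL, path) {
  stopifnot(inherits(map, "tile_fraction_map"))
  nt <- dim(map$fractions)
  df <- data.frame(
    tile_row = rep(0:(nt[1] - 1L), times = nt[2]),
    tile_col = rep(0:(nt[2] - 1L), each = nt[1]),
    fraction = as.vector(map$fractions),
    mean_dose_Gy = if (is.null(dose_means)) NA_real_ else as.vector(dose_means),
    full_tile = as.vector(map$full))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Export one or more profiles as CSV
#'
#' @param profiles a `gfap_profile` or a list of them.
#' @param path output CSV path.
#' @return The exported data frame, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  if (inherits(profiles, "gfap_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(position_um = p$position_um, gfap_mean = p$gfap_mean,
               dose_mean_Gy = p$dose_mean_Gy,
               axis = attr(p, "axis"), band = attr(p, "band"))
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
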