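#' Phantom configuration
#'
#' Parameters of the synthetic two-channel slice phantom. The phantom
#' emulates the study inputs: a GFAP channel containing branched
#' filamentous bright objects whose local areal density is
#' `baseline(band) + dose_response_slope * local_dose`, punctate
#' erythrocyte/autofluorescence-like confounders, smooth background
#' gradients and additive Gaussian noise; a DAPI channel with nuclear
#' blobs; and a collimated proton beam dose field (entrance plateau,
#' Bragg peak, distal falloff, lateral penumbra) delivered to the right
#' hemisphere, with the left hemisphere receiving ~0 Gy.
#'
#' The default canvas is a reduced-scale brain slice of 2000 x 3000 px at
#' 2 um/px (4 x 6 mm) so that the full pipeline runs in seconds; the
#' pixel size is a free parameter, never hard-coded downstream.
#'
#' @param seed integer seed driving the single pseudo-random stream.
#' @param image_shape integer 2-vector (rows, cols) in pixels.
#' @param pixel_size pixel edge in micrometres.
#' @param prescription_dose prescription dose in Gy (0 for sham).
#' @param baseline_density_central expected GFAP+ area fraction at 0 Gy in
#'   the central brain band.
#' @param baseline_density_cortex same for the cortex bands (lateral image
#'   edges); lower than central in healthy tissue.
#' @param dose_response_slope added expected fraction per Gy of local dose.
#' @param confounder_rate punctate confounders per mm^2.
#' @param noise_sd additive Gaussian noise SD in intensity units.
#' @param midline_col 0-based pixel column of the hemisphere mirror axis.
#' @param beam_entry_row 0-based pixel row of the beam central axis.
#' @param beam_direction axis-aligned unit vector of beam travel in
#'   (row, col) pixel coordinates; `c(0, -1)` means the beam enters at the
#'   right image edge and travels toward the midline.
#' @param beam_diameter collimated beam diameter in micrometres.
#' @param peak_depth Bragg-peak depth from the entry edge in micrometres.
#' @param entrance_fraction entrance plateau dose as a fraction of the peak.
#' @param sigma_proximal Gaussian width (um) of the proximal peak shoulder.
#' @param sigma_distal Gaussian width (um) of the distal falloff.
#' @param penumbra_sigma lateral penumbra width (um).
#' @param cortex_band_frac fraction of image columns at each lateral edge
#'   assigned the cortex baseline.
#' @param dose_grid_spacing planning-grid cell size in micrometres.
#' @param background_level,background_gradient constant and peak-to-peak
#'   amplitude of the smooth background, intensity units.
#' @param object_intensity,confounder_intensity mean stamp amplitudes.
#' @param nuclei_rate DAPI nuclei per mm^2.
#' @param tile_size tile edge (um) on which the ground-truth density field
#'   is defined; matches the analysis tile size.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(seed = 1L,
                           image_shape = c(2000L, 3000L),
                           pixel_size = 2,
                           prescription_dose = 45,
                           baseline_density_central = 0.02,
                           baseline_density_cortex = 0.008,
                           dose_response_slope = 0.003,
                           confounder_rate = 10,
                           noise_sd = 100,
                           midline_col = NULL,
                           beam_entry_row = NULL,
                           beam_direction = c(0, -1),
                           beam_diameter = NULL,
                           peak_depth = NULL,
                           entrance_fraction = 0.3,
                           sigma_proximal = NULL,
                           sigma_distal = NULL,
                           penumbra_sigma = NULL,
                           cortex_band_frac = 0.15,
                           dose_grid_spacing = 50,
                           background_level = 500,
                           background_gradient = 300,
                           object_intensity = 4000,
                           confounder_intensity = 6000,
                           nuclei_rate = 400,
                           tile_size = 250) {
  shape <- as.integer(image_shape)
  if (length(shape) != 2L || any(shape <= 0L)) stop("'image_shape' must be two positive integers")
  if (pixel_size <= 0) stop("'pixel_size' must be positive")
  if (prescription_dose < 0) stop("'prescription_dose' must be >= 0")
  if (is.null(midline_col)) midline_col <- shape[2] %/% 2L
  if (midline_col <= 0 || midline_col >= shape[2] - 1L)
    stop("'midline_col' must lie inside the image")
  if (is.null(beam_entry_row)) beam_entry_row <- shape[1] %/% 2L
  if (beam_entry_row < 0 || beam_entry_row > shape[1] - 1L)
    stop("'beam_entry_row' must lie inside the image")
  hemi_um <- (shape[2] - midline_col) * pixel_size
  if (is.null(beam_diameter)) beam_diameter <- 0.6 * shape[1] * pixel_size
  if (is.null(peak_depth)) peak_depth <- 0.5 * hemi_um
  if (is.null(sigma_proximal)) sigma_proximal <- 0.6 * peak_depth
  if (is.null(sigma_distal)) sigma_distal <- max(100, 0.15 * peak_depth)
  if (is.null(penumbra_sigma)) penumbra_sigma <- max(80, 0.06 * beam_diameter)
  for (nm in c("baseline_density_central", "baseline_density_cortex")) {
    v <- get(nm)
    if (v < 0 || v >= 1) stop(sprintf("'%s' must be in [0, 1)", nm))
  }
  if (dose_response_slope < 0) stop("'dose_response_slope' must be >= 0")
  dmax <- max(baseline_density_central, baseline_density_cortex) +
    dose_response_slope * prescription_dose
  if (dmax >= 1)
    stop(sprintf("configuration error: expected density %.3f at maximum dose is not < 1", dmax))
  if (confounder_rate < 0 || noise_sd < 0) stop("rates and noise must be >= 0")
  structure(
    list(seed = as.integer(seed), image_shape = shape, pixel_size = pixel_size,
         prescription_dose = prescription_dose,
         baseline_density_central = baseline_density_central,
         baseline_density_cortex = baseline_density_cortex,
         dose_response_slope = dose_response_slope,
         confounder_rate = confounder_rate, noise_sd = noise_sd,
         midline_col = as.integer(midline_col),
         beam_entry_row = as.integer(beam_entry_row),
         beam_direction = as.numeric(beam_direction),
         beam_diameter = beam_diameter, peak_depth = peak_depth,
         entrance_fraction = entrance_fraction,
         sigma_proximal = sigma_proximal, sigma_distal = sigma_distal,
         penumbra_sigma = penumbra_sigma,
         cortex_band_frac = cortex_band_frac,
         dose_grid_spacing = dose_grid_spacing,
         background_level = background_level,
         background_gradient = background_gradient,
         object_intensity = object_intensity,
         confounder_intensity = confounder_intensity,
         nuclei_rate = nuclei_rate, tile_size = tile_size),
    class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("<phantom_config> %d x %d px @ %g um/px, %g Gy, baselines %.3f/%.3f (central/cortex), slope %.4f /Gy, seed %d\n",
              x$image_shape[1], x$image_shape[2], x$pixel_size,
              x$prescription_dose, x$baseline_density_central,
              x$baseline_density_cortex, x$dose_response_slope, x$seed))
  invisible(x)
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Analytic collimated proton beam dose field
#'
#' Parametric stand-in for a Monte Carlo proton dose calculation: the depth
#' profile is an entrance plateau rising through a proximal Gaussian
#' shoulder to a single Bragg-peak maximum, followed by a sharp Gaussian
#' distal falloff (below 1% of the maximum within ~3.1 `sigma_distal`);
#' the lateral profile is a top-hat of the collimator diameter convolved
#' with a Gaussian penumbra. Values are evaluated on the grid and rescaled
#' so the grid maximum equals the prescription exactly, which keeps
#' prescription scaling linear.
#'
#' @param prescription prescription dose in Gy (> 0).
#' @param geometry list with elements `axis_row` and `entry_col` (um, grid
#'   coordinates), `peak_depth`, `entrance_fraction`, `sigma_proximal`,
#'   `sigma_distal`, `beam_diameter`, `penumbra_sigma` (um), and
#'   `beam_direction` (`c(0, -1)` or `c(0, 1)`; the beam must travel along
#'   the column axis — rotate the image otherwise).
#' @param grid_shape integer 2-vector (rows, cols) of the dose grid.
#' @param spacing grid cell size in micrometres.
#' @return A [dose_grid].
#' @export
simulate_dose <- function(prescription, geometry, grid_shape, spacing) {
  if (prescription <= 0) stop("'prescription' must be positive")
  g <- geometry
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  if (nr <= 0L || nc <= 0L) stop("'grid_shape' must be positive")
  bd <- as.numeric(g$beam_direction)
  if (!(length(bd) == 2L && bd[1] == 0 && abs(bd[2]) == 1))
    stop("beam must travel along the column axis; rotate the image first")
  row_um <- (0:(nr - 1L)) * spacing
  col_um <- (0:(nc - 1L)) * spacing
  depth <- if (bd[2] < 0) g$entry_col - col_um else col_um - g$entry_col
  peak_col_um <- g$entry_col + bd[2] * g$peak_depth
  if (peak_col_um < 0 || peak_col_um > (nc - 1L) * spacing)
    stop("grid too small to contain the Bragg peak")
  z0 <- g$peak_depth
  e <- g$entrance_fraction
  dz <- ifelse(depth < 0, 0,
               ifelse(depth <= z0,
                      e + (1 - e) * exp(-(depth - z0)^2 / (2 * g$sigma_proximal^2)),
                      exp(-(depth - z0)^2 / (2 * g$sigma_distal^2))))
  y <- row_um - g$axis_row
  R <- g$beam_diameter / 2
  s <- g$penumbra_sigma * sqrt(2)
  ly <- 0.5 * (erf((R - y) / s) + erf((R + y) / s))
  values <- outer(ly, dz)
  m <- max(values)
  if (m <= 0) stop("degenerate beam geometry: zero dose everywhere")
  values <- values * (prescription / m)
  dose_grid(values, spacing, bd, prescription)
}

# Branched curvilinear object: 3-5 polyline branches from a common centre,
# each with an angular kink, dilated to 1-3 px width. Returns unique linear
# pixel indices on an nr x nc canvas.
draw_astrocyte <- function(nr, nc, r0, c0, pixel_size) {
  nb <- sample(2:4, 1L)
  rr <- r0; cc <- c0
  for (b in seq_len(nb)) {
    th <- runif(1, 0, 2 * pi)
    L <- max(2L, as.integer(round(runif(1, 8, 25) / pixel_size)))
    n1 <- as.integer(ceiling(L / 2)); n2 <- L - n1
    t1 <- seq_len(n1)
    rr <- c(rr, r0 + t1 * sin(th)); cc <- c(cc, c0 + t1 * cos(th))
    if (n2 > 0L) {
      th2 <- th + runif(1, -0.7, 0.7)
      re <- r0 + n1 * sin(th); ce <- c0 + n1 * cos(th)
      t2 <- seq_len(n2)
      rr <- c(rr, re + t2 * sin(th2)); cc <- c(cc, ce + t2 * cos(th2))
    }
  }
  # processes 1-3 px wide: at the phantom resolution these stay narrower
  # than the rolling-ball diameter, as real GFAP-stained processes are at
  # the study resolution, so the background estimate does not absorb them
  w <- sample(1:3, 1L, prob = c(0.55, 0.30, 0.15))
  off <- switch(w,
                cbind(0L, 0L),
                cbind(c(0L, 1L, 0L, 1L), c(0L, 0L, 1L, 1L)),
                cbind(c(0L, -1L, 1L, 0L, 0L), c(0L, 0L, 0L, -1L, 1L)))
  pr <- rep(as.integer(round(rr)), times = nrow(off)) + rep(off[, 1], each = length(rr))
  pc <- rep(as.integer(round(cc)), times = nrow(off)) + rep(off[, 2], each = length(rr))
  ok <- pr >= 1L & pr <= nr & pc >= 1L & pc <= nc
  unique((pc[ok] - 1L) * nr + pr[ok])
}

# Stamp circular discs (confounders, nuclei) at given 1-based centres.
stamp_discs <- function(canvas, centres_r, centres_c, radius_px, amps) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  templ <- lapply(seq_len(max(radius_px)), function(r) {
    d <- expand.grid(dr = -r:r, dc = -r:r)
    d[d$dr^2 + d$dc^2 <= r^2, , drop = FALSE]
  })
  for (i in seq_along(centres_r)) {
    d <- templ[[radius_px[i]]]
    pr <- as.integer(round(centres_r[i])) + d$dr
    pc <- as.integer(round(centres_c[i])) + d$dc
    ok <- pr >= 1L & pr <= nr & pc >= 1L & pc <= nc
    idx <- (pc[ok] - 1L) * nr + pr[ok]
    canvas[idx] <- pmax(canvas[idx], amps[i])
  }
  canvas
}

# Anatomical band membership of 0-based columns: TRUE where cortex baseline
# applies (lateral shells of the slice).
cortex_columns <- function(ncol_px, cortex_band_frac) {
  w <- as.integer(round(cortex_band_frac * ncol_px))
  cols <- 0:(ncol_px - 1L)
  cols < w | cols >= ncol_px - w
}

#' Anatomical band rectangles of a phantom
#'
#' Returns the entry-side cortex band and the central-brain band (around
#' the Bragg-peak depth) as [roi_spec] rectangles for transverse profile
#' extraction. Bands span all rows and do not overlap.
#'
#' @param config a [phantom_config].
#' @return List with elements `cortex` and `central`.
#' @export
phantom_bands <- function(config) {
  nc <- config$image_shape[2]; nr <- config$image_shape[1]
  w <- as.integer(round(config$cortex_band_frac * nc))
  peak_col <- phantom_peak_col(config)
  hw <- as.integer(round(0.1 * nc))
  list(
    cortex = roi_spec(0L, nr - 1L, nc - w, nc - 1L, side = "band",
                      mirror_axis_col = config$midline_col),
    central = roi_spec(0L, nr - 1L, max(0L, peak_col - hw),
                       min(nc - 1L, peak_col + hw), side = "band",
                       mirror_axis_col = config$midline_col))
}

#' 0-based column of the Bragg-peak depth in slice coordinates
#'
#' @param config a [phantom_config].
#' @return Integer column index.
#' @export
phantom_peak_col <- function(config) {
  nc <- config$image_shape[2]
  entry_col_um <- (nc - 1L) * config$pixel_size
  dir <- config$beam_direction[2]
  if (dir > 0) entry_col_um <- 0
  as.integer(round((entry_col_um + dir * config$peak_depth) / config$pixel_size))
}

phantom_geometry <- function(config) {
  nc <- config$image_shape[2]
  list(axis_row = config$beam_entry_row * config$pixel_size,
       entry_col = if (config$beam_direction[2] < 0) (nc - 1L) * config$pixel_size else 0,
       peak_depth = config$peak_depth,
       entrance_fraction = config$entrance_fraction,
       sigma_proximal = config$sigma_proximal,
       sigma_distal = config$sigma_distal,
       beam_diameter = config$beam_diameter,
       penumbra_sigma = config$penumbra_sigma,
       beam_direction = config$beam_direction)
}

#' Generate a synthetic two-channel slice phantom
#'
#' Produces a GFAP channel, a DAPI channel, the matched planning dose grid
#' with its grid-to-slice affine transform, and the ground truth (true
#' GFAP mask, expected per-tile density field, object count). The expected
#' GFAP+ area fraction at each location is
#' `baseline(band) + dose_response_slope * local_dose`; coverage is
#' realised through a Boolean object model with intensity
#' `-log(1 - target)` so that overlaps do not bias the expected fraction.
#' Identical configurations (including the seed) give bit-identical
#' outputs.
#'
#' @param config a [phantom_config].
#' @return A list with elements `gfap`, `dapi` ([slice_image]s), `dose`
#'   ([dose_grid] on the planning grid), `transform` ([affine2d] mapping
#'   grid to slice pixels), `dose_slice` (dose resampled to slice pixels),
#'   `truth` (list: `gfap_mask`, `local_density_field`, `object_count`),
#'   and `config`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  px <- config$pixel_size
  npx <- nr * nc

  # planning dose grid covering the slice, plus the known affine
  gsp <- config$dose_grid_spacing
  gnr <- as.integer(ceiling((nr - 1L) * px / gsp)) + 1L
  gnc <- as.integer(ceiling((nc - 1L) * px / gsp)) + 1L
  transform <- affine2d(rbind(c(gsp / px, 0, 0), c(0, gsp / px, 0)))
  if (config$prescription_dose > 0) {
    dose <- simulate_dose(config$prescription_dose, phantom_geometry(config),
                          c(gnr, gnc), gsp)
  } else {
    dose <- dose_grid(matrix(0, gnr, gnc), gsp, config$beam_direction, 0)
  }
  dose_slice <- resample_dose(dose, transform, c(nr, nc), px)

  # expected density per pixel: band baseline + slope * local dose
  base_col <- ifelse(cortex_columns(nc, config$cortex_band_frac),
                     config$baseline_density_cortex,
                     config$baseline_density_central)
  dens <- matrix(base_col, nr, nc, byrow = TRUE) +
    config$dose_response_slope * dose_slice

  # per-tile target density and Boolean-model placement intensity
  tpx <- as.integer(round(config$tile_size / px))
  row_tile <- (0:(nr - 1L)) %/% tpx
  col_tile <- (0:(nc - 1L)) %/% tpx
  ntr <- max(row_tile) + 1L; ntc <- max(col_tile) + 1L
  sums <- rowsum(dens, row_tile, reorder = TRUE)
  sums <- t(rowsum(t(sums), col_tile, reorder = TRUE))
  cnt_r <- tabulate(row_tile + 1L, ntr)
  cnt_c <- tabulate(col_tile + 1L, ntc)
  counts <- outer(cnt_r, cnt_c)
  vt <- pmin(sums / counts, 0.95)

  mask <- matrix(FALSE, nr, nc)
  sig <- matrix(0, nr, nc)
  n_obj <- 0L
  for (tj in seq_len(ntc)) {
    c_lo <- (tj - 1L) * tpx + 1L; c_hi <- min(nc, tj * tpx)
    for (ti in seq_len(ntr)) {
      target <- -log(1 - vt[ti, tj]) * counts[ti, tj]
      if (target <= 0) next
      r_lo <- (ti - 1L) * tpx + 1L; r_hi <- min(nr, ti * tpx)
      acc <- 0
      repeat {
        r0 <- runif(1, r_lo, r_hi); c0 <- runif(1, c_lo, c_hi)
        idx <- draw_astrocyte(nr, nc, r0, c0, px)
        a <- length(idx)
        if (a == 0L) next
        amp <- config$object_intensity * runif(1, 0.7, 1.3)
        if (acc + a >= target) {
          # thin the final object so the expected placed area is unbiased
          if (runif(1) < (target - acc) / a) {
            mask[idx] <- TRUE
            sig[idx] <- pmax(sig[idx], amp)
            n_obj <- n_obj + 1L
          }
          break
        }
        mask[idx] <- TRUE
        sig[idx] <- pmax(sig[idx], amp)
        n_obj <- n_obj + 1L
        acc <- acc + a
      }
    }
  }

  # punctate confounders (erythrocyte / autofluorescence-like), not part of
  # the true GFAP mask
  area_mm2 <- npx * px^2 / 1e6
  n_conf <- rpois(1, config$confounder_rate * area_mm2)
  if (n_conf > 0) {
    sig <- stamp_discs(sig, runif(n_conf, 1, nr), runif(n_conf, 1, nc),
                       pmax(1L, as.integer(round(runif(n_conf, 1.5, 4) / px))),
                       config$confounder_intensity * runif(n_conf, 0.8, 1.2))
  }

  # smooth background + noise
  bg <- config$background_level + config$background_gradient *
    (0.5 * matrix(rep(0:(nc - 1L) / max(1L, nc - 1L), each = nr), nr, nc) +
     0.5 * matrix(sin(pi * (0:(nr - 1L)) / max(1L, nr - 1L)), nr, nc))
  gfap_vals <- bg + sig
  if (config$noise_sd > 0)
    gfap_vals <- gfap_vals + rnorm(npx, 0, config$noise_sd)
  gfap_vals[gfap_vals < 0] <- 0

  # DAPI channel: nuclei blobs, analysis-neutral plumbing
  n_nuc <- rpois(1, config$nuclei_rate * area_mm2)
  dapi_sig <- matrix(0, nr, nc)
  if (n_nuc > 0) {
    dapi_sig <- stamp_discs(dapi_sig, runif(n_nuc, 1, nr), runif(n_nuc, 1, nc),
                            pmax(1L, as.integer(round(runif(n_nuc, 2, 4) / px))),
                            3000 * runif(n_nuc, 0.8, 1.2))
  }
  dapi_vals <- 300 + dapi_sig
  if (config$noise_sd > 0)
    dapi_vals <- dapi_vals + rnorm(npx, 0, config$noise_sd)
  dapi_vals[dapi_vals < 0] <- 0

  sid <- sprintf("phantom_s%d_%gGy", config$seed, config$prescription_dose)
  list(
    gfap = slice_image(gfap_vals, px, "GFAP", sid),
    dapi = slice_image(dapi_vals, px, "DAPI", sid),
    dose = dose,
    transform = transform,
    dose_slice = dose_slice,
    truth = list(gfap_mask = mask,
                 local_density_field = pmin(pmax(sums / counts, 0), 1),
                 object_count = n_obj),
    config = config)
}
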