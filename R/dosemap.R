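#' Fit an affine transform from landmark pairs
#'
#' Least-squares 6-parameter affine mapping dose-grid coordinates to slice
#' pixel coordinates, a testable stand-in for contour-based slice-to-volume
#' registration. Requires at least three non-collinear point pairs.
#'
#' @param src_points n x 2 matrix of (row, col) grid coordinates.
#' @param dst_points n x 2 matrix of (row, col) slice pixel coordinates.
#' @return An [affine2d] with attributes `residuals` (n x 2 matrix) and
#'   `rmse` (root-mean-square residual over both coordinates).
#' @export
fit_affine_from_landmarks <- function(src_points, dst_points) {
  src <- as.matrix(src_points); dst <- as.matrix(dst_points)
  if (ncol(src) != 2L || ncol(dst) != 2L || nrow(src) != nrow(dst))
    stop("landmarks must be two n x 2 matrices with matching n")
  if (nrow(src) < 3L) stop("at least 3 landmark pairs are required")
  A <- cbind(src, 1)
  qrA <- qr(A)
  if (qrA$rank < 3L) stop("landmarks are collinear: affine transform is not identifiable")
  beta <- qr.coef(qrA, dst)          # 3 x 2: [a c; b d; tx ty]
  m <- rbind(c(beta[1, 1], beta[2, 1], beta[3, 1]),
             c(beta[1, 2], beta[2, 2], beta[3, 2]))
  tf <- affine2d(m)
  res <- dst - A %*% beta
  attr(tf, "residuals") <- res
  attr(tf, "rmse") <- sqrt(mean(res^2))
  tf
}

#' Apply an affine transform to points
#'
#' @param transform an [affine2d].
#' @param points n x 2 matrix of (row, col) coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
apply_affine <- function(transform, points) {
  stopifnot(inherits(transform, "affine2d"))
  p <- as.matrix(points)
  m <- transform$matrix
  sweep(p %*% t(m[, 1:2]), 2, m[, 3], "+")
}

#' Invert an affine transform
#'
#' @param transform an [affine2d].
#' @return The inverse [affine2d].
#' @export
invert_affine <- function(transform) {
  stopifnot(inherits(transform, "affine2d"))
  A <- transform$matrix[, 1:2]
  Ainv <- solve(A)
  affine2d(cbind(Ainv, -Ainv %*% transform$matrix[, 3]))
}

#' Resample a dose grid into slice pixel coordinates
#'
#' Pulls the dose raster through the (invertible) grid-to-slice affine with
#' bilinear interpolation, producing a dose raster at slice resolution.
#' Slice pixels that map outside the source grid receive 0 Gy (the
#' non-irradiated surroundings), matching the observation that the
#' unirradiated hemisphere behaves like sham tissue.
#'
#' @param dose a [dose_grid].
#' @param transform [affine2d] mapping grid (row, col) to slice pixels.
#' @param target_shape integer 2-vector (rows, cols) of the slice raster.
#' @param target_pixel_size slice pixel size in micrometres (attached as an
#'   attribute of the result).
#' @return Numeric matrix of doses (Gy) of dimension `target_shape`, with
#'   attribute `pixel_size`.
#' @export
resample_dose <- function(dose, transform, target_shape, target_pixel_size) {
  stopifnot(inherits(dose, "dose_grid"), inherits(transform, "affine2d"))
  nr <- as.integer(target_shape[1]); nc <- as.integer(target_shape[2])
  if (nr <= 0L || nc <= 0L) stop("'target_shape' must be positive")
  inv <- invert_affine(transform)$matrix
  v <- dose$values
  nrv <- nrow(v); ncv <- ncol(v)
  rows <- 0:(nr - 1L); cols <- 0:(nc - 1L)
  if (inv[1, 2] == 0 && inv[2, 1] == 0) {
    # axis-aligned transform: rows and columns resample separably
    gr <- inv[1, 1] * rows + inv[1, 3]
    gc <- inv[2, 2] * cols + inv[2, 3]
    rin <- gr >= 0 & gr <= nrv - 1L
    cin <- gc >= 0 & gc <= ncv - 1L
    r0 <- pmax(pmin(floor(gr), nrv - 2L), 0L); fr <- pmin(pmax(gr - r0, 0), 1)
    c0 <- pmax(pmin(floor(gc), ncv - 2L), 0L); fc <- pmin(pmax(gc - c0, 0), 1)
    res <- v[r0 + 1L, c0 + 1L, drop = FALSE] * outer(1 - fr, 1 - fc) +
      v[r0 + 2L, c0 + 1L, drop = FALSE] * outer(fr, 1 - fc) +
      v[r0 + 1L, c0 + 2L, drop = FALSE] * outer(1 - fr, fc) +
      v[r0 + 2L, c0 + 2L, drop = FALSE] * outer(fr, fc)
    if (!all(rin)) res[!rin, ] <- 0
    if (!all(cin)) res[, !cin] <- 0
  } else {
    gr <- as.vector(outer(inv[1, 1] * rows, inv[1, 2] * cols, "+")) + inv[1, 3]
    gc <- as.vector(outer(inv[2, 1] * rows, inv[2, 2] * cols, "+")) + inv[2, 3]
    r0 <- floor(gr); c0 <- floor(gc)
    out <- numeric(nr * nc)
    inside <- gr >= 0 & gr <= nrv - 1L & gc >= 0 & gc <= ncv - 1L
    if (any(inside)) {
      r0i <- pmin(r0[inside], nrv - 2L); r0i <- pmax(r0i, 0)
      c0i <- pmin(c0[inside], ncv - 2L); c0i <- pmax(c0i, 0)
      fri <- gr[inside] - r0i; fci <- gc[inside] - c0i
      i00 <- r0i + 1L + c0i * nrv
      out[inside] <-
        v[i00] * (1 - fri) * (1 - fci) +
        v[i00 + 1L] * fri * (1 - fci) +
        v[i00 + nrv] * (1 - fri) * fci +
        v[i00 + nrv + 1L] * fri * fci
    }
    res <- matrix(out, nr, nc)
  }
  attr(res, "pixel_size") <- target_pixel_size
  res
}

#' Isodose region mask
#'
#' Pixels receiving at least `level` times the maximum dose of the raster
#' (for example, the 80% isodose region used for slice selection).
#'
#' @param dose_raster numeric dose matrix (Gy).
#' @param level fraction of the maximum dose, in (0, 1).
#' @return Logical matrix; all `FALSE` for an all-zero raster.
#' @export
isodose_region <- function(dose_raster, level) {
  if (!(level > 0 && level < 1)) stop("'level' must be in (0, 1)")
  m <- max(dose_raster)
  if (m <= 0) return(array(FALSE, dim(dose_raster)))
  dose_raster >= level * m
}
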