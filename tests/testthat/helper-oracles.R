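# Independent reference implementations used as oracles. These are
# deliberately naive (loops, queues, closed forms) and share no code with
# the package internals.

# Exhaustive Otsu: try all 256 thresholds, maximise between-class variance
# computed directly from the two pixel populations; first (lowest) maximum.
otsu_bruteforce <- function(values) {
  v <- as.vector(values)
  best_t <- NA_integer_; best_sb <- -Inf
  for (t in 0:255) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    sb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb > best_sb + 1e-12) { best_sb <- sb; best_t <- t }
  }
  best_t
}

# Flood-fill connected-component labelling with an explicit queue, labels
# in column-major first-encounter order (the package convention).
flood_fill_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 4L) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  }
  nxt <- 0L
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (!mask[rr, cc] || lab[rr, cc] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(rr, cc)); lab[rr, cc] <- nxt
    while (length(queue) > 0L) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (o in offs) {
        q <- p + o
        if (q[1] < 1L || q[1] > nr || q[2] < 1L || q[2] > nc) next
        if (mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- nxt
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# Grayscale opening with a ball structuring element by direct min/max
# loops; for small images only.
ball_opening_direct <- function(x, r) {
  nr <- nrow(x); nc <- ncol(x)
  offs <- list(); h <- c()
  for (dr in -r:r) for (dc in -r:r) {
    if (dr^2 + dc^2 <= r^2) {
      offs[[length(offs) + 1L]] <- c(dr, dc)
      h <- c(h, sqrt(r^2 - dr^2 - dc^2))
    }
  }
  ero <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    m <- Inf
    for (k in seq_along(offs)) {
      p <- c(i, j) + offs[[k]]
      if (p[1] < 1 || p[1] > nr || p[2] < 1 || p[2] > nc) next
      m <- min(m, x[p[1], p[2]] - h[k])
    }
    ero[i, j] <- m
  }
  dil <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    m <- -Inf
    for (k in seq_along(offs)) {
      p <- c(i, j) + offs[[k]]
      if (p[1] < 1 || p[1] > nr || p[2] < 1 || p[2] > nc) next
      m <- max(m, ero[p[1], p[2]] + h[k])
    }
    dil[i, j] <- m
  }
  dil
}

# Closed-form OLS with Wald t-test, straight from the normal equations.
ols_closed_form <- function(x, y) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2); sxy <- sum((x - xb) * (y - yb))
  syy <- sum((y - yb)^2)
  slope <- sxy / sxx
  intercept <- yb - slope * xb
  sse <- sum((y - intercept - slope * x)^2)
  se <- sqrt(sse / (n - 2) / sxx)
  tstat <- slope / se
  list(slope = slope, intercept = intercept, se = se,
       p = 2 * pt(-abs(tstat), n - 2),
       r = sxy / sqrt(sxx * syy))
}

# Per-tile fraction of a label map by explicit nested loops.
tile_fractions_nested <- function(label_map, tpx, pixel_size) {
  nr <- nrow(label_map); nc <- ncol(label_map)
  ntr <- ceiling(nr / tpx); ntc <- ceiling(nc / tpx)
  fr <- matrix(0, ntr, ntc); full <- matrix(FALSE, ntr, ntc)
  for (i in seq_len(ntr)) for (j in seq_len(ntc)) {
    rows <- ((i - 1) * tpx + 1):min(i * tpx, nr)
    cols <- ((j - 1) * tpx + 1):min(j * tpx, nc)
    npx <- length(rows) * length(cols)
    cnt <- 0
    for (r in rows) for (c in cols) if (label_map[r, c] > 0) cnt <- cnt + 1
    fr[i, j] <- cnt * pixel_size^2 / (npx * pixel_size^2)
    full[i, j] <- npx == tpx * tpx
  }
  list(fractions = fr, full = full)
}

# Random 8-bit test image with a bimodal-ish histogram.
random_8bit <- function(n = 32) {
  n0 <- floor(0.8 * n * n); n1 <- n * n - n0
  v <- c(pmin(pmax(round(rnorm(n0, 40, 25)), 0), 255),
         pmin(pmax(round(rnorm(n1, 180, 30)), 0), 255))
  slice_image(matrix(as.numeric(sample(v)), n, n), 1)
}
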