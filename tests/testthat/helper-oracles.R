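# Independent oracles and small fixture builders, deliberately implemented
# differently from the package internals.

# Brute-force breadth-first flood fill over the wand's intensity window.
# Pure R, explicit queue, no shared code with the package's compiled kernel.
bfs_wand_oracle <- function(pixels, bit_depth, seed_xy, tolerance_fraction) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  r0 <- seed_xy[2] + 1L; c0 <- seed_xy[1] + 1L
  ref <- pixels[r0, c0]
  half <- tolerance_fraction * (2^bit_depth - 1)
  inwin <- abs(pixels - ref) <= half
  seen <- matrix(FALSE, nr, nc)
  seen[r0, c0] <- TRUE
  queue <- list(c(r0, c0))
  while (length(queue)) {
    rc <- queue[[1]]; queue <- queue[-1]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- rc[1] + dr; cc <- rc[2] + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (!seen[rr, cc] && inwin[rr, cc]) {
        seen[rr, cc] <- TRUE
        queue[[length(queue) + 1]] <- c(rr, cc)
      }
    }
  }
  seen
}

# Exhaustive Otsu: plain loop over candidate thresholds, class statistics
# computed directly from the pixel vector each time.
otsu_oracle <- function(pixels, bit_depth) {
  v <- as.vector(pixels)
  best_t <- NA_integer_; best_s <- -Inf
  for (t in 0:(2^bit_depth - 2)) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}

# Point-in-polygon oracle: mgcv::in.out for off-boundary points plus an
# explicit on-segment test (the package's convention counts boundary points
# as inside).
pip_oracle <- function(px, py, vx, vy) {
  n <- length(vx)
  bnd <- cbind(c(vx, vx[1]), c(vy, vy[1]))
  interior <- mgcv::in.out(bnd, cbind(px, py))
  on_edge <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    x1 <- vx[k]; y1 <- vy[k]
    x2 <- vx[if (k == n) 1 else k + 1]; y2 <- vy[if (k == n) 1 else k + 1]
    d <- abs((x2 - x1) * (py - y1) - (y2 - y1) * (px - x1))
    on <- d < 1e-9 &
      px >= min(x1, x2) - 1e-9 & px <= max(x1, x2) + 1e-9 &
      py >= min(y1, y2) - 1e-9 & py <= max(y1, y2) + 1e-9
    on_edge <- on_edge | on
  }
  interior | on_edge
}

# random small image_grid for the wand property tests
random_small_image <- function(seed, max_dim = 20, bit_depth = 8) {
  set.seed(seed)
  nr <- sample(3:max_dim, 1); nc <- sample(3:max_dim, 1)
  image_grid(matrix(sample(0:(2^bit_depth - 1), nr * nc, replace = TRUE), nr, nc),
             bit_depth = bit_depth)
}

mask_from <- function(m) region_mask(matrix(as.logical(m), nrow(m), ncol(m)))

# 4 x 3 16-bit grayscale PNG (synthetic format fixture, base64-inlined;
# pixel values by row: [0 7 300 1000; 65535 40000 12345 1; 256 511 32768 99])
g16_png_b64 <- paste0(
  "iVBORw0KGgoAAAANSUhEUgAAAAQAAAADEAAAAADBDy1ZAAAAI0lEQVR4nGNgYGBgZ9Rh",
  "fsH0//8cS33ev5IMjAyM/xsYGJIBWWsHK6992NUAAAAASUVORK5CYII=")
g16_png_values <- matrix(c(0, 7, 300, 1000,
                           65535, 40000, 12345, 1,
                           256, 511, 32768, 99), nrow = 3, byrow = TRUE)

write_g16_png <- function(path) {
  writeBin(jsonlite::base64_dec(g16_png_b64), path)
  path
}
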