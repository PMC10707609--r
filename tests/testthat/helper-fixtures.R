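# Shared fixtures: a compact render spec for speed, constructed masks, and
# an independent brute-force circle-fit oracle.

# Smaller canvas than the default render keeps the geometry (12 px/mm, same
# mm-frame scene) while quartering pixel count.
small_spec <- function(...) {
  eye_spec(image_height_px = 280L, image_width_px = 400L, px_per_mm = 12, ...)
}

# Disk-in-iris label mask: pupil disk (label 3) embedded in an iris field
# (label 2) so the pupil boundary touches iris, as in a real mask.
disk_mask <- function(h, w, center_row, center_col, radius, bg_label = 2L) {
  m <- matrix(bg_label, h, w)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  m[(rr - center_row)^2 + (cc - center_col)^2 <= radius^2] <- 3L
  m
}

# Exhaustive grid search minimizing the geometric sum of squared residuals;
# deliberately independent of the algebraic fit it checks.
brute_circle_fit <- function(x, y, center0, r0, half_width = 0.5, step = 0.05) {
  grid <- expand.grid(
    cx = seq(center0[1] - half_width, center0[1] + half_width, by = step),
    cy = seq(center0[2] - half_width, center0[2] + half_width, by = step),
    r = seq(r0 - half_width, r0 + half_width, by = step)
  )
  sse <- vapply(seq_len(nrow(grid)), function(i) {
    sum((sqrt((x - grid$cx[i])^2 + (y - grid$cy[i])^2) - grid$r[i])^2)
  }, numeric(1))
  unlist(grid[which.min(sse), ])
}

kasa_from_points <- function(x, y) mrdeye:::kasa_fit(x, y)

# Analytic points on an exact circle (no rasterization error).
circle_points <- function(cx, cy, r, n = 24) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  list(x = cx + r * cos(th), y = cy + r * sin(th))
}
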