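# Geometric fixtures built in code; used across test files.

disc_mask <- function(H, W, cr, cc, r) {
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((rows - cr)^2 + (cols - cc)^2 <= r^2) * 1
}

# Rasterised ellipse with semi-axes (a along rows, b along cols), rotated by
# `theta` radians (row/col frame, anticlockwise in (row, col) coordinates).
ellipse_mask <- function(H, W, cr, cc, a, b, theta = 0) {
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  dr <- rows - cr; dc <- cols - cc
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  ((u / a)^2 + (v / b)^2 <= 1) * 1
}

# Closed-form central chord of that ellipse along a unit direction `u`
# (row, col): independent oracle for the diameter algorithm.
ellipse_chord <- function(a, b, theta, u) {
  # direction expressed in the ellipse's own frame
  ur <- u[1] * cos(theta) + u[2] * sin(theta)
  uc <- -u[1] * sin(theta) + u[2] * cos(theta)
  2 / sqrt((ur / a)^2 + (uc / b)^2)
}

# Small stigma blob centred at (cr, cc), for steering the centroid axis.
blob_mask <- function(H, W, cr, cc, r = 4) disc_mask(H, W, cr, cc, r)

# A triangular stigma curve peaking at t_peak with S(0) = 0, sampled on a
# fixed grid; closed-form phase boundaries are exact by linear geometry.
triangle_curve <- function(t_peak = 10, t_end = 14, step = 0.1) {
  grid <- seq(0, t_end, by = step)
  S <- ifelse(grid <= t_peak, grid, t_peak - (grid - t_peak))
  structure(list(grid = grid, mean = S, ci_low = S, ci_high = S, span = NA),
            class = "smoothed_curve")
}
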