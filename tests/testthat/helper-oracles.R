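# Independent brute-force oracles, deliberately written without reusing the
# package's geometry helpers.

# Intersection of path p -> p+d with one segment, via a 2x2 linear solve.
oracle_seg_t <- function(p, d, a, b) {
  e <- b - a
  M <- cbind(d, -e)
  if (abs(det(M)) < 1e-14) return(-1)
  tu <- solve(M, a - p)
  if (tu[1] >= 0 && tu[1] <= 1 && tu[2] >= 0 && tu[2] <= 1) tu[1] else -1
}

# Exhaustive crossing list: every canonical segment tested against all of
# its periodic images; nearest image wins; sorted by (t, segment index).
oracle_crossings <- function(p, d, mesh) {
  box <- mesh$box
  ox <- if (box$boundary_x == "periodic") c(-box$width, 0, box$width) else 0
  oy <- if (box$boundary_y == "periodic") c(-box$height, 0, box$height) else 0
  segs <- mesh$segments
  res <- data.frame(segment = integer(), t = numeric())
  for (i in seq_len(nrow(segs))) {
    tmin <- Inf
    for (sx in ox) for (sy in oy) {
      a <- c(segs[i, 1] + sx, segs[i, 2] + sy)
      b <- c(segs[i, 3] + sx, segs[i, 4] + sy)
      t <- oracle_seg_t(p, d, a, b)
      if (t >= 0 && t < tmin) tmin <- t
    }
    if (is.finite(tmin))
      res <- rbind(res, data.frame(segment = i, t = tmin))
  }
  res[order(res$t, res$segment), , drop = FALSE]
}

# All item indices within `range` of point `p` (minimum image).
oracle_in_range <- function(p, positions, box, range) {
  dx <- positions[, 1] - p[1]
  dy <- positions[, 2] - p[2]
  if (box$boundary_x == "periodic") dx <- dx - round(dx / box$width) * box$width
  if (box$boundary_y == "periodic") dy <- dy - round(dy / box$height) * box$height
  which(dx^2 + dy^2 <= range^2)
}

# Shoelace area, independent of the package's helper.
oracle_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x); j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# A synthetic trajectory_set (for observable tests that need full control).
fake_traj <- function(frames_xy, times, box = sim_box(100, 100)) {
  # frames_xy: array [frames, 2, particles, reps]
  structure(list(traj = frames_xy, times = times, box = box),
            class = "trajectory_set")
}
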