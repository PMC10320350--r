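# The three fence models: hop probabilities, triangular fence potentials,
# and picket construction.

#' Scale a timestep-independent hop probability to a per-step probability
#'
#' With a fixed per-step hop probability the restriction a probabilistic
#' fence imposes depends on the timestep: a smaller timestep gives more
#' crossing attempts but smaller displacements, and the two effects combine
#' to a square-root scaling. The scaled probability (in fraction per
#' square-root nanosecond) removes that dependence; the per-step probability
#' is `p_hop_scaled * sqrt(dt)`.
#'
#' @param p_hop_scaled scaled hop probability, fraction·ns^(-1/2)
#'   (0.1677 %/sqrt(ns) is written 0.001677).
#' @param dt timestep in ns.
#' @return per-step probability in `[0, 1]`.
#' @examples
#' scale_hop_probability(0.001677, 2000)  # 0.075
#' @export
scale_hop_probability <- function(p_hop_scaled, dt) {
  stopifnot(is.numeric(p_hop_scaled), is.numeric(dt))
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (p_hop_scaled < 0) stop("p_hop_scaled must be non-negative", call. = FALSE)
  p <- p_hop_scaled * sqrt(dt)
  if (any(p > 1))
    stop(sprintf("scaled hop probability %.4g exceeds 1 at dt = %g ns", max(p), dt),
         call. = FALSE)
  p
}

#' Probabilistic fence crossing decision
#'
#' One independent uniform draw per crossed fence, in path order; the step
#' is accepted iff every draw is below the hop probability. Exactly one
#' draw per crossing is consumed from the RNG, so the random stream is
#' reproducible. An empty crossing list is accepted without consuming draws.
#'
#' @param crossings result of [path_fence_crossings()] (a data.frame), or an
#'   integer number of crossings.
#' @param p_hop per-step hop probability in `[0, 1]` (apply
#'   [scale_hop_probability()] first when using the scaled parameterization).
#' @return `TRUE` (step accepted) or `FALSE` (particle remains in place).
#' @export
crossing_decision <- function(crossings, p_hop) {
  stopifnot(p_hop >= 0, p_hop <= 1)
  n <- if (is.data.frame(crossings)) nrow(crossings) else as.integer(crossings)
  if (n == 0L) return(TRUE)
  draws <- runif(n)
  all(draws < p_hop)
}

# Perpendicular foot and distance from a point to a segment.
point_segment_foot <- function(p, ax, ay, bx, by) {
  ex <- bx - ax; ey <- by - ay
  L2 <- ex * ex + ey * ey
  t <- ((p[1] - ax) * ex + (p[2] - ay) * ey) / L2
  t <- min(1, max(0, t))
  q <- c(ax + t * ex, ay + t * ey)
  list(foot = q, dist = sqrt(sum((p - q)^2)))
}

#' Force field of triangular potential fences
#'
#' Every fence segment closer than the potential width `x0` contributes a
#' candidate force vector of magnitude `k_fence / x0` pointing from the
#' nearest point of the segment towards the particle (the triangular
#' potential has constant slope, so the force magnitude inside the range is
#' constant and symmetric on both sides of the fence). The returned force
#' has the direction of the vector sum of all candidates but the magnitude
#' of the strongest single candidate, so corners where several fences meet
#' do not produce forces beyond `k_fence / x0`.
#'
#' @param pos numeric length-2 particle position (nm), inside the box.
#' @param mesh a `fence_mesh`.
#' @param k_fence fence energy (aJ).
#' @param x0 potential width (nm).
#' @return numeric length-2 force vector (aJ/nm).
#' @export
fence_potential_force <- function(pos, mesh, k_fence, x0) {
  stopifnot(k_fence >= 0, x0 > 0)
  tl <- tiled_segments(mesh)
  segs <- tl$segments
  canon <- tl$canon
  nc <- nrow(mesh$segments)
  best_d <- rep(Inf, nc)
  best_v <- matrix(0, nc, 2)
  for (i in seq_len(nrow(segs))) {
    f <- point_segment_foot(pos, segs[i, 1], segs[i, 2], segs[i, 3], segs[i, 4])
    ci <- canon[i]
    if (f$dist < best_d[ci]) {
      best_d[ci] <- f$dist
      best_v[ci, ] <- pos - f$foot
    }
  }
  act <- which(best_d < x0 & best_d > 0)
  if (length(act) == 0L) return(c(0, 0))
  mag <- k_fence / x0
  cand <- best_v[act, , drop = FALSE] / best_d[act] * mag
  vsum <- colSums(cand)
  nv <- sqrt(sum(vsum^2))
  if (nv == 0) return(c(0, 0))
  vsum / nv * mag
}

#' Build a picket set on a fence mesh
#'
#' Pickets are immobile repulsive discs centred on the fence lines. Each
#' segment is subdivided deterministically: pickets sit at both endpoints
#' and the centre-to-centre spacing is as close as possible to
#' `2 * R + l_free`. Pickets meeting at shared vertices (and periodic
#' duplicates) are merged.
#'
#' @param mesh a `fence_mesh`; every segment must be longer than `2 * R`
#'   (but see `short_segments`).
#' @param R picket radius (nm).
#' @param l_free mean free space between adjacent pickets (nm).
#' @param short_segments what to do with segments shorter than a picket
#'   diameter: `"error"` (the strict contract), or `"endpoints"` — such
#'   segments contribute only their endpoint pickets, which random Voronoi
#'   meshes need since they always carry a few very short edges.
#' @return A `picket_set` with fields `centres` (matrix, nm) and `radius`.
#' @export
build_pickets <- function(mesh, R, l_free,
                          short_segments = c("error", "endpoints")) {
  stopifnot(R > 0, l_free >= 0)
  short_segments <- match.arg(short_segments)
  segs <- mesh$segments
  box <- mesh$box
  pitch <- 2 * R + l_free
  centres <- list()
  for (i in seq_len(nrow(segs))) {
    a <- segs[i, 1:2]; b <- segs[i, 3:4]
    len <- sqrt(sum((b - a)^2))
    if (len <= 2 * R && short_segments == "error")
      stop(sprintf("segment %d (%.3g nm) is shorter than a picket diameter", i, len),
           call. = FALSE)
    nint <- max(1L, round(len / pitch))
    ts <- seq(0, 1, length.out = nint + 1L)
    centres[[i]] <- cbind(a[1] + ts * (b[1] - a[1]), a[2] + ts * (b[2] - a[2]))
  }
  pts <- do.call(rbind, centres)
  # wrap into the box on periodic axes, then deduplicate shared vertices
  pts <- t(apply(pts, 1, wrap_point, box = box))
  key <- paste(round(pts[, 1] / 1e-9) , round(pts[, 2] / 1e-9))
  pts <- pts[!duplicated(key), , drop = FALSE]
  structure(list(centres = pts, radius = R), class = "picket_set")
}

#' @export
print.picket_set <- function(x, ...) {
  cat(sprintf("<picket_set> %d pickets of radius %g nm\n",
              nrow(x$centres), x$radius))
  invisible(x)
}

#' Write a picket set as columnar text (x y R per line)
#' @param pickets a `picket_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pickets <- function(pickets, path) {
  df <- data.frame(x = pickets$centres[, 1], y = pickets$centres[, 2],
                   R = pickets$radius)
  write.table(format(df, digits = 17), path, quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
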