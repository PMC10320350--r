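# Fence-crossing geometry for the probabilistic fence model: which fence
# segments does a straight displacement path cut, and where.

# Intersection parameter of path p -> p+d with segment a-b, or -1.
# Endpoint and vertex hits (t or u exactly 0/1) count as crossings;
# parallel/collinear paths do not cross.
path_segment_t <- function(px, py, dx, dy, ax, ay, bx, by) {
  ex <- bx - ax
  ey <- by - ay
  den <- dx * ey - dy * ex
  if (abs(den) < 1e-14) return(-1)
  t <- ((ax - px) * ey - (ay - py) * ex) / den
  u <- ((ax - px) * dy - (ay - py) * dx) / den
  if (t >= 0 && t <= 1 && u >= 0 && u <= 1) t else -1
}

#' Fence segments crossed by a displacement path
#'
#' Tests the straight path from `p_from` over `displacement` against every
#' fence segment of the mesh, including the periodic images of the segments,
#' and returns the crossings ordered by distance from the start. Each
#' canonical fence segment is counted at most once (the nearest image); a
#' path ending exactly on a segment counts as a crossing. Ties in distance
#' are broken by the lower segment index.
#'
#' @param p_from numeric length-2 start point (nm), inside the box.
#' @param displacement numeric length-2 displacement (nm).
#' @param mesh a `fence_mesh`.
#' @return data.frame with columns `segment` (canonical index into
#'   `mesh$segments`), `t` (fraction along the path), `x`, `y` (crossing
#'   point, nm); zero rows when nothing is crossed.
#' @export
path_fence_crossings <- function(p_from, displacement, mesh) {
  d <- as.numeric(displacement)
  stopifnot(all(is.finite(d)))
  tl <- tiled_segments(mesh)
  segs <- tl$segments
  canon <- tl$canon
  hits_t <- rep(Inf, nrow(mesh$segments))
  for (i in seq_len(nrow(segs))) {
    t <- path_segment_t(p_from[1], p_from[2], d[1], d[2],
                        segs[i, 1], segs[i, 2], segs[i, 3], segs[i, 4])
    if (t >= 0 && t < hits_t[canon[i]]) hits_t[canon[i]] <- t
  }
  idx <- which(is.finite(hits_t))
  if (length(idx) == 0L) {
    return(data.frame(segment = integer(), t = numeric(),
                      x = numeric(), y = numeric()))
  }
  ord <- idx[order(hits_t[idx], idx)]
  data.frame(segment = ord,
             t = hits_t[ord],
             x = p_from[1] + hits_t[ord] * d[1],
             y = p_from[2] + hits_t[ord] * d[2])
}
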