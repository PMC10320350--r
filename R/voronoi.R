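# Periodic Voronoi fence meshes.
#
# The diagram is built directly from its definition: the seed set is copied
# into the 8 surrounding box images (Moore neighbourhood) along periodic
# axes, and the cell of every central seed is the intersection of the
# half-planes bounded by the perpendicular bisectors to all other (tiled)
# seeds. Cells are convex, so Sutherland-Hodgman clipping against each
# bisector in order of seed distance, with an early exit once the remaining
# seeds are too far to cut the current polygon, is exact and fast.

# Clip convex polygon (n x 2 matrix) against half-plane {x : x.n <= c}.
clip_halfplane <- function(poly, nvec, cval) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  d <- poly %*% nvec - cval
  keep_all <- all(d <= 0)
  if (keep_all) return(poly)
  if (all(d > 0)) return(poly[0, , drop = FALSE])
  out <- matrix(0, n + 4L, 2L)
  m <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di <= 0) {
      m <- m + 1L; out[m, ] <- poly[i, ]
    }
    if ((di < 0 && dj > 0) || (di > 0 && dj <= 0)) {
      t <- di / (di - dj)
      m <- m + 1L; out[m, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(m), , drop = FALSE]
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Moore-neighbourhood tiling of a seed set along the periodic axes.
tile_seeds <- function(seeds, box) {
  per <- box_periodic(box)
  ox <- if (per[1]) c(0, -box$width, box$width) else 0
  oy <- if (per[2]) c(0, -box$height, box$height) else 0
  offs <- expand.grid(dx = ox, dy = oy)
  tiled <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k) {
    cbind(seeds[, 1] + offs$dx[k], seeds[, 2] + offs$dy[k])
  }))
  tiled
}

# Voronoi cell of tiled seed `idx` among all tiled seeds.
voronoi_cell <- function(idx, tiled) {
  s <- tiled[idx, ]
  span <- max(apply(tiled, 2, function(v) diff(range(v))))
  half <- span  # generous initial bound; shrinks by clipping
  poly <- cbind(s[1] + c(-half, half, half, -half),
                s[2] + c(-half, -half, half, half))
  d2 <- (tiled[, 1] - s[1])^2 + (tiled[, 2] - s[2])^2
  ord <- order(d2)
  rmax2 <- max((poly[, 1] - s[1])^2 + (poly[, 2] - s[2])^2)
  for (j in ord) {
    if (j == idx) next
    if (d2[j] > 4 * rmax2) break
    nvec <- c(tiled[j, 1] - s[1], tiled[j, 2] - s[2])
    mid <- (tiled[j, ] + s) / 2
    poly <- clip_halfplane(poly, nvec, sum(mid * nvec))
    if (nrow(poly) < 3L) break
    rmax2 <- max((poly[, 1] - s[1])^2 + (poly[, 2] - s[2])^2)
  }
  poly
}

# Canonicalize one edge: translate so its midpoint lies inside the box
# (periodic axes), snap to a 1e-6 nm grid, order endpoints lexicographically.
canonical_edge <- function(a, b, box) {
  ext <- box_extents(box)
  per <- box_periodic(box)
  mid <- (a + b) / 2
  for (k in 1:2) {
    if (per[k]) {
      shift <- floor(round(mid[k], 6) / ext[k]) * ext[k]
      a[k] <- a[k] - shift
      b[k] <- b[k] - shift
    }
  }
  a <- round(a, 6); b <- round(b, 6)
  if (a[1] > b[1] || (a[1] == b[1] && a[2] > b[2])) {
    tmp <- a; a <- b; b <- tmp
  }
  c(a, b)
}

# Build a fence mesh from an explicit seed set (no retry loop).
voronoi_from_seeds <- function(seeds, box, L_target = NA_real_) {
  seeds <- as.matrix(seeds)
  stopifnot(ncol(seeds) == 2L, nrow(seeds) >= 1L)
  tiled <- tile_seeds(seeds, box)
  n <- nrow(seeds)
  comps <- vector("list", n)
  edges <- list()
  for (i in seq_len(n)) {
    poly <- voronoi_cell(i, tiled)
    # clip to the box along repulsive axes (cells are unbounded there only
    # if the seed set does not span the box; the box wall is the fence)
    if (box$boundary_x == "repulsive") {
      poly <- clip_halfplane(poly, c(-1, 0), 0)
      poly <- clip_halfplane(poly, c(1, 0), box$width)
    }
    if (box$boundary_y == "repulsive") {
      poly <- clip_halfplane(poly, c(0, -1), 0)
      poly <- clip_halfplane(poly, c(0, 1), box$height)
    }
    comps[[i]] <- poly
    m <- nrow(poly)
    for (v in seq_len(m)) {
      w <- if (v == m) 1L else v + 1L
      edges[[length(edges) + 1L]] <- canonical_edge(poly[v, ], poly[w, ], box)
    }
  }
  segs <- unique(do.call(rbind, edges))
  # drop degenerate (zero-length) edges produced by clipping round-off
  len2 <- (segs[, 3] - segs[, 1])^2 + (segs[, 4] - segs[, 2])^2
  segs <- segs[len2 > 1e-10, , drop = FALSE]
  areas <- vapply(comps, polygon_area, numeric(1))
  mesh <- structure(list(
    seeds = seeds,
    segments = segs,
    compartments = comps,
    L_target = L_target,
    L_mesh = mean(sqrt(areas)),
    box = box
  ), class = "fence_mesh")
  mesh
}

#' Generate a periodic Voronoi fence mesh
#'
#' Places `round(width * height / L_target^2)` uniformly random seeds in the
#' box, copies them around the box in a Moore-neighbourhood manner to
#' enforce periodicity, computes the Voronoi diagram, and measures the
#' realized characteristic length (mean square root of compartment areas).
#' If that differs from `L_target` by more than 2%, the seeds are redrawn
#' with the point count alternating one more / one less around the analytic
#' count, up to `max_retries` attempts.
#'
#' @param L_target requested characteristic length (nm).
#' @param box a [sim_box()]; `L_target` must not exceed the smaller extent
#'   and the box must hold at least two seeds.
#' @param seed optional integer; seeds the RNG for a reproducible mesh.
#' @param max_retries retry cap for the 2% rule.
#' @return A `fence_mesh` with fields `seeds`, `segments` (one row per fence
#'   segment, `x1 y1 x2 y2` in nm), `compartments` (vertex rings), `L_target`,
#'   `L_mesh` and `box`, plus attributes `n_seeds` and `retries`.
#' @examples
#' m <- generate_periodic_voronoi(50, sim_box(100, 100), seed = 1)
#' characteristic_length(m)
#' @export
generate_periodic_voronoi <- function(L_target, box, seed = NULL,
                                      max_retries = 500L) {
  stopifnot(is.numeric(L_target), length(L_target) == 1L)
  if (L_target > min(box$width, box$height))
    stop("L_target exceeds the smaller box extent", call. = FALSE)
  n0 <- round(box$width * box$height / L_target^2)
  if (box$width * box$height / L_target^2 < 2)
    stop("box too small: fewer than two compartments at this L_target",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  # one point more or one point less per retry, in the direction that
  # corrects L_mesh (fewer points -> larger compartments), with fresh seed
  # positions every attempt; the count oscillates around the analytic value
  n <- n0
  last_L <- NA_real_
  for (attempt in seq_len(max_retries)) {
    seeds <- cbind(runif(n, 0, box$width), runif(n, 0, box$height))
    mesh <- voronoi_from_seeds(seeds, box, L_target = L_target)
    last_L <- mesh$L_mesh
    if (abs(mesh$L_mesh - L_target) / L_target <= 0.02) {
      attr(mesh, "n_seeds") <- n
      attr(mesh, "retries") <- attempt - 1L
      return(mesh)
    }
    n <- if (mesh$L_mesh < L_target) max(2L, n - 1L) else n + 1L
  }
  stop(sprintf(
    "mesh generation did not converge in %d attempts (last L_mesh = %.4g nm)",
    max_retries, last_L), call. = FALSE)
}

#' Characteristic length of a fence mesh
#'
#' The mean of the square roots of the compartment areas.
#'
#' @param mesh a `fence_mesh` with compartment polygons.
#' @return length in nm.
#' @export
characteristic_length <- function(mesh) {
  comps <- mesh$compartments
  if (is.null(comps) || length(comps) == 0L)
    stop("mesh has no compartment polygons", call. = FALSE)
  areas <- vapply(comps, polygon_area, numeric(1))
  if (any(areas <= 0))
    stop("mesh has a compartment with non-positive area", call. = FALSE)
  mean(sqrt(areas))
}

#' Build a fence mesh from explicit segments
#'
#' Accepts hand-drawn fence geometries (for example equally spaced barrier
#' lines) in the same representation the Voronoi generator produces.
#' Compartment polygons are not available for such meshes.
#'
#' @param segments numeric matrix with columns `x1 y1 x2 y2` (nm).
#' @param box a [sim_box()].
#' @param L_target optional nominal characteristic length.
#' @return A `fence_mesh`.
#' @export
manual_mesh <- function(segments, box, L_target = NA_real_) {
  segments <- matrix(as.numeric(segments), ncol = 4L)
  len2 <- (segments[, 3] - segments[, 1])^2 + (segments[, 4] - segments[, 2])^2
  if (any(len2 <= 0)) stop("degenerate segment (a == b)", call. = FALSE)
  structure(list(seeds = NULL, segments = segments, compartments = NULL,
                 L_target = L_target, L_mesh = NA_real_, box = box),
            class = "fence_mesh")
}

#' @export
print.fence_mesh <- function(x, ...) {
  cat(sprintf("<fence_mesh> %d segments, %s compartments, L_mesh = %s nm, box %g x %g nm\n",
              nrow(x$segments),
              if (is.null(x$compartments)) "no" else length(x$compartments),
              if (is.na(x$L_mesh)) "NA" else sprintf("%.3f", x$L_mesh),
              x$box$width, x$box$height))
  invisible(x)
}

# Segments tiled into the Moore neighbourhood along periodic axes, with the
# canonical segment index carried along. Used by crossing tests and fence
# potentials so that minimum-image geometry reduces to plain geometry.
tiled_segments <- function(mesh) {
  segs <- mesh$segments
  box <- mesh$box
  per <- box_periodic(box)
  ox <- if (per[1]) c(0, -box$width, box$width) else 0
  oy <- if (per[2]) c(0, -box$height, box$height) else 0
  offs <- expand.grid(dx = ox, dy = oy)
  m <- nrow(segs)
  out <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k) {
    cbind(segs[, 1] + offs$dx[k], segs[, 2] + offs$dy[k],
          segs[, 3] + offs$dx[k], segs[, 4] + offs$dy[k])
  }))
  list(segments = out, canon = rep.int(seq_len(m), nrow(offs)))
}

# Point-in-polygon (ray casting); boundary points count as inside.
point_in_polygon <- function(p, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-edge check
    ex <- xj - xi; ey <- yj - yi
    px <- p[1] - xi; py <- p[2] - yi
    cr <- ex * py - ey * px
    dt <- ex * px + ey * py
    if (abs(cr) < 1e-9 && dt >= -1e-9 && dt <= ex * ex + ey * ey + 1e-9)
      return(TRUE)
    if ((yi > p[2]) != (yj > p[2])) {
      xint <- xi + (p[2] - yi) / (yj - yi) * (xj - xi)
      if (p[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Locate the compartment containing a point
#'
#' @param p numeric length-2 point (nm).
#' @param mesh a `fence_mesh` with compartment polygons.
#' @return integer compartment index (first match), or `NA` if none.
#' @export
locate_compartment <- function(p, mesh) {
  if (is.null(mesh$compartments))
    stop("mesh has no compartment polygons", call. = FALSE)
  box <- mesh$box
  p <- wrap_point(as.numeric(p), box)
  per <- box_periodic(box)
  ox <- if (per[1]) c(0, -box$width, box$width) else 0
  oy <- if (per[2]) c(0, -box$height, box$height) else 0
  for (i in seq_along(mesh$compartments)) {
    poly <- mesh$compartments[[i]]
    for (dx in ox) for (dy in oy) {
      if (point_in_polygon(c(p[1] + dx, p[2] + dy), poly)) return(i)
    }
  }
  NA_integer_
}
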