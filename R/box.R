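#' Simulation box
#'
#' A rectangular 2D simulation region. Each axis is either `"periodic"`
#' (particles wrap, fences tile) or `"repulsive"` (particles are reflected
#' at the wall). Lengths are in nanometres.
#'
#' @param width,height box extents in nm; must be positive.
#' @param boundary_x,boundary_y boundary condition per axis.
#' @return An object of class `sim_box`.
#' @examples
#' sim_box(100, 100)
#' sim_box(100, 500, boundary_y = "repulsive")
#' @export
sim_box <- function(width, height,
                    boundary_x = c("periodic", "repulsive"),
                    boundary_y = c("periodic", "repulsive")) {
  boundary_x <- match.arg(boundary_x)
  boundary_y <- match.arg(boundary_y)
  stopifnot(is.numeric(width), length(width) == 1L, is.finite(width),
            is.numeric(height), length(height) == 1L, is.finite(height))
  if (width <= 0 || height <= 0)
    stop("box extents must be positive", call. = FALSE)
  structure(list(width = width, height = height,
                 boundary_x = boundary_x, boundary_y = boundary_y),
            class = "sim_box")
}

#' @export
print.sim_box <- function(x, ...) {
  cat(sprintf("<sim_box> %g x %g nm (x: %s, y: %s)\n",
              x$width, x$height, x$boundary_x, x$boundary_y))
  invisible(x)
}

box_extents <- function(box) c(box$width, box$height)

box_periodic <- function(box) {
  c(box$boundary_x == "periodic", box$boundary_y == "periodic")
}

#' Minimum-image displacement between two points
#'
#' Shortest displacement vector from `a` to `b`, wrapping across periodic
#' axes of the box. On a periodic axis the returned component has magnitude
#' at most half the axis extent; on a repulsive axis the plain difference
#' is returned.
#'
#' @param a,b numeric length-2 points (nm), inside the box.
#' @param box a [sim_box()].
#' @return numeric length-2 displacement (nm).
#' @examples
#' b <- sim_box(100, 100)
#' min_image_displacement(c(1, 1), c(99, 1), b)  # c(-2, 0)
#' @export
min_image_displacement <- function(a, b, box) {
  d <- as.numeric(b) - as.numeric(a)
  ext <- box_extents(box)
  per <- box_periodic(box)
  for (k in 1:2) {
    if (per[k]) d[k] <- d[k] - round(d[k] / ext[k]) * ext[k]
  }
  d
}

# Reduce a point into [0, width) x [0, height) along periodic axes.
wrap_point <- function(p, box) {
  ext <- box_extents(box)
  per <- box_periodic(box)
  for (k in 1:2) {
    if (per[k]) p[k] <- p[k] - floor(p[k] / ext[k]) * ext[k]
  }
  p
}
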