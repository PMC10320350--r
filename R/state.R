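#' System state at a time point
#'
#' Mobile particle positions plus the immobile environment (fence mesh and
#' pickets). Positions are wrapped into the box on periodic axes; the
#' accumulated periodic image counts are carried alongside so unwrapped
#' coordinates (needed for mean squared displacements) remain available.
#'
#' @param positions n x 2 matrix of particle positions (nm), inside the box.
#' @param radius particle radii (nm), scalar or length n.
#' @param D0 diffusion coefficients (nm^2/ns), scalar or length n.
#' @param box a [sim_box()].
#' @param mesh optional `fence_mesh`.
#' @param pickets optional `picket_set`.
#' @param time current time (ns).
#' @return An object of class `system_state`.
#' @export
system_state <- function(positions, radius, D0, box, mesh = NULL,
                         pickets = NULL, time = 0) {
  positions <- matrix(as.numeric(positions), ncol = 2L)
  n <- nrow(positions)
  radius <- rep_len(radius, n)
  D0 <- rep_len(D0, n)
  stopifnot(all(radius > 0), all(D0 > 0))
  if (any(positions[, 1] < 0 | positions[, 1] > box$width |
          positions[, 2] < 0 | positions[, 2] > box$height))
    stop("particle positions must lie inside the box", call. = FALSE)
  structure(list(positions = positions, radius = radius, D0 = D0,
                 box = box, mesh = mesh, pickets = pickets, time = time,
                 images = matrix(0L, n, 2L)),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("<system_state> %d particle(s), %s pickets, t = %g ns\n",
              nrow(x$positions),
              if (is.null(x$pickets)) "no" else nrow(x$pickets$centres),
              x$time))
  invisible(x)
}

# Draw non-overlapping uniform initial positions (rejection sampling).
# Overlap is checked against already placed particles and pickets using
# minimum-image distances; up to max_attempts redraws per particle.
init_positions <- function(n, radius, box, pickets = NULL,
                           max_attempts = 1e4) {
  radius <- rep_len(radius, n)
  pos <- matrix(NA_real_, n, 2L)
  redraws <- 0L
  for (i in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      p <- c(runif(1, 0, box$width), runif(1, 0, box$height))
      clash <- FALSE
      if (i > 1L) {
        for (j in seq_len(i - 1L)) {
          d <- min_image_displacement(pos[j, ], p, box)
          if (sum(d^2) < (radius[i] + radius[j])^2) { clash <- TRUE; break }
        }
      }
      if (!clash && !is.null(pickets) && nrow(pickets$centres) > 0L) {
        for (j in seq_len(nrow(pickets$centres))) {
          d <- min_image_displacement(pickets$centres[j, ], p, box)
          if (sum(d^2) < (radius[i] + pickets$radius)^2) { clash <- TRUE; break }
        }
      }
      if (!clash) { pos[i, ] <- p; ok <- TRUE; break }
      redraws <- redraws + 1L
    }
    if (!ok)
      stop(sprintf("could not place particle %d without overlap in %d attempts",
                   i, max_attempts), call. = FALSE)
  }
  attr(pos, "redraws") <- redraws
  pos
}
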