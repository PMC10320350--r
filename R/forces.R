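# Deterministic force terms of the propagator.

#' Linear pair-force magnitude between overlapping discs
#'
#' Zero outside contact; inside contact the magnitude grows linearly with
#' the overlap, `k_pair * (r_i + r_j - distance)`. The direction (pushing
#' the pair apart along the separation vector) is applied by the caller.
#'
#' @param centre_distance centre-to-centre distance (nm), positive.
#' @param r_i,r_j particle radii (nm).
#' @param k_pair linear force constant (aJ/nm^2).
#' @return force magnitude (aJ/nm).
#' @examples
#' pair_force_magnitude(0.6, 0.4, 0.4, 0.1)  # 0.02
#' @export
pair_force_magnitude <- function(centre_distance, r_i, r_j, k_pair) {
  if (any(centre_distance == 0))
    stop("coincident particles: pair force direction undefined", call. = FALSE)
  pmax(0, k_pair * (r_i + r_j - centre_distance))
}

#' Total deterministic force on one particle
#'
#' Sum of (a) linear repulsion from every overlapping mobile particle and
#' picket (minimum-image distances), (b) the fence potential force when the
#' fence model is `"potential"`, and (c) the drift term `gamma * v_drift`.
#' This is the reference implementation used for verification; the
#' simulation kernel computes the same quantity in compiled code.
#'
#' @param i particle index.
#' @param state a [system_state()].
#' @param params a [sim_params()].
#' @return numeric length-2 force vector (aJ/nm).
#' @export
total_force <- function(i, state, params) {
  pos <- state$positions
  p <- pos[i, ]
  f <- c(0, 0)
  n <- nrow(pos)
  for (j in seq_len(n)) {
    if (j == i) next
    d <- min_image_displacement(p, pos[j, ], state$box)
    dist <- sqrt(sum(d^2))
    rsum <- state$radius[i] + state$radius[j]
    if (dist < rsum) {
      mag <- pair_force_magnitude(dist, state$radius[i], state$radius[j],
                                  params$k_pair)
      f <- f - mag * d / dist
    }
  }
  if (!is.null(state$pickets) && nrow(state$pickets$centres) > 0L) {
    for (j in seq_len(nrow(state$pickets$centres))) {
      d <- min_image_displacement(p, state$pickets$centres[j, ], state$box)
      dist <- sqrt(sum(d^2))
      rsum <- state$radius[i] + state$pickets$radius
      if (dist < rsum) {
        mag <- pair_force_magnitude(dist, state$radius[i],
                                    state$pickets$radius, params$k_pair)
        f <- f - mag * d / dist
      }
    }
  }
  if (params$fence$model == "potential" && !is.null(state$mesh)) {
    f <- f + fence_potential_force(p, state$mesh,
                                   params$fence$k_fence, params$fence$x0)
  }
  gamma <- drag_coefficient(state$D0[i], params$T)
  f + gamma * params$v_drift
}
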