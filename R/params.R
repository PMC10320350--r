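# Simulation parameters. Internal unit system: nm, ns, aJ, K. In these
# units D0 = 0.8 um^2/s is 8e-4 nm^2/ns and the drag gamma = kB*T/D0 is
# about 5.177 aJ ns/nm^2 at 300 K.

#' Fence model parameter blocks
#'
#' Constructors for the fence-model configuration carried inside
#' [sim_params()]. Exactly one of `p_hop` / `p_hop_scaled` must be given
#' for a probabilistic fence; the scaled form is converted to a per-step
#' probability via [scale_hop_probability()] at simulation time.
#'
#' @param p_hop per-step hop probability in `[0, 1]`.
#' @param p_hop_scaled scaled hop probability (fraction per sqrt ns).
#' @param k_fence fence energy (aJ).
#' @param x0 potential width (nm).
#' @param R picket radius (nm).
#' @param l_free mean free space between adjacent pickets (nm).
#' @return A fence parameter list with a `model` field.
#' @export
probabilistic_fence <- function(p_hop = NULL, p_hop_scaled = NULL) {
  if (is.null(p_hop) == is.null(p_hop_scaled))
    stop("give exactly one of p_hop / p_hop_scaled", call. = FALSE)
  if (!is.null(p_hop) && (p_hop < 0 || p_hop > 1))
    stop("p_hop must be a probability in [0, 1]", call. = FALSE)
  if (!is.null(p_hop_scaled) && p_hop_scaled < 0)
    stop("p_hop_scaled must be non-negative", call. = FALSE)
  list(model = "probabilistic", p_hop = p_hop, p_hop_scaled = p_hop_scaled)
}

#' @rdname probabilistic_fence
#' @export
potential_fence <- function(k_fence, x0 = 2.5) {
  stopifnot(k_fence >= 0, x0 > 0)
  list(model = "potential", k_fence = k_fence, x0 = x0)
}

#' @rdname probabilistic_fence
#' @param short_segments policy for fence segments shorter than a picket
#'   diameter, see [build_pickets()].
#' @export
picket_fence <- function(R = 4, l_free = 0.8,
                         short_segments = c("error", "endpoints")) {
  stopifnot(R > 0, l_free >= 0)
  list(model = "picket", R = R, l_free = l_free,
       short_segments = match.arg(short_segments))
}

#' @rdname probabilistic_fence
#' @export
no_fence <- function() list(model = "none")

#' Simulation parameters
#'
#' Collects the propagator coefficients and run bookkeeping. Defaults are
#' the package's standard membrane setup: lipid-sized particles
#' (r = 0.4 nm) diffusing at 8e-4 nm^2/ns (0.8 um^2/s) at 300 K with a
#' linear pair repulsion of 0.1 aJ/nm^2 and samples recorded every 20 us.
#'
#' @param dt timestep (ns).
#' @param duration total simulated time per replication (ns); must be a
#'   multiple of `sample_interval`.
#' @param sample_interval observable recording cadence (ns); must be a
#'   multiple of `dt`.
#' @param n_particles number of mobile particles.
#' @param radius particle radius (nm), scalar or one per particle.
#' @param D0 free diffusion coefficient (nm^2/ns), scalar or per particle.
#' @param T temperature (K); the drag is `kB * T / D0`.
#' @param k_pair linear pair-force constant (aJ/nm^2).
#' @param v_drift drift velocity vector (nm/ns).
#' @param fence fence parameter block from [probabilistic_fence()],
#'   [potential_fence()], [picket_fence()] or [no_fence()].
#' @param seed master RNG seed; each replication derives a child seed.
#' @param replications number of independent runs.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(dt = 20,
                       duration = 2e6,
                       sample_interval = 2e4,
                       n_particles = 1L,
                       radius = 0.4,
                       D0 = 8e-4,
                       T = 300,
                       k_pair = 0.1,
                       v_drift = c(0, 0),
                       fence = no_fence(),
                       seed = NULL,
                       replications = 1L) {
  stopifnot(dt > 0, duration > 0, k_pair >= 0, T > 0, all(D0 > 0),
            all(radius > 0), length(v_drift) == 2L)
  if (sample_interval < dt) stop("sample_interval must be >= dt", call. = FALSE)
  if (abs(sample_interval / dt - round(sample_interval / dt)) > 1e-9)
    stop("sample_interval must be a multiple of dt", call. = FALSE)
  if (abs(duration / sample_interval - round(duration / sample_interval)) > 1e-9)
    stop("duration must be a multiple of sample_interval", call. = FALSE)
  structure(list(dt = dt, duration = duration,
                 sample_interval = sample_interval,
                 n_particles = as.integer(n_particles),
                 radius = radius, D0 = D0, T = T, k_pair = k_pair,
                 v_drift = as.numeric(v_drift), fence = fence,
                 seed = seed, replications = as.integer(replications)),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params> %d particle(s), dt = %g ns, duration = %g ns, fence = %s, %d rep(s)\n",
    x$n_particles, x$dt, x$duration, x$fence$model, x$replications))
  invisible(x)
}

# Drag coefficient gamma = kB * T / D0 (aJ ns / nm^2).
drag_coefficient <- function(D0, T) .kB_aJ * T / D0

# Per-step hop probability for a probabilistic fence block.
resolve_p_hop <- function(fence, dt) {
  if (!is.null(fence$p_hop_scaled))
    scale_hop_probability(fence$p_hop_scaled, dt)
  else fence$p_hop
}
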