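# R-level driver around the compiled propagator.

fence_model_code <- function(fence) {
  switch(fence$model, none = 0L, probabilistic = 1L, potential = 2L,
         picket = 3L,
         stop("unknown fence model: ", fence$model, call. = FALSE))
}

# Assemble the kernel arguments shared by langevin_step and simulate.
kernel_env <- function(state, params) {
  box <- state$box
  fence <- params$fence
  model <- fence_model_code(fence)
  if (model %in% c(1L, 2L)) {
    if (is.null(state$mesh)) stop("fence model needs a mesh", call. = FALSE)
    tl <- tiled_segments(state$mesh)
    segs <- tl$segments
    canon <- tl$canon - 1L
  } else {
    segs <- matrix(numeric(), 0L, 4L)
    canon <- integer()
  }
  if (!is.null(state$pickets) && nrow(state$pickets$centres) > 0L) {
    per <- box_periodic(box)
    ox <- if (per[1]) c(0, -box$width, box$width) else 0
    oy <- if (per[2]) c(0, -box$height, box$height) else 0
    offs <- expand.grid(dx = ox, dy = oy)
    pk <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k) {
      cbind(state$pickets$centres[, 1] + offs$dx[k],
            state$pickets$centres[, 2] + offs$dy[k])
    }))
    picket_r <- state$pickets$radius
  } else {
    pk <- matrix(numeric(), 0L, 2L)
    picket_r <- 0
  }
  p_hop <- if (model == 1L) resolve_p_hop(fence, params$dt) else 0
  list(model = model, segs = segs, canon = canon, pickets = pk,
       picket_r = picket_r, p_hop = p_hop,
       k_fence = if (model == 2L) fence$k_fence else 0,
       x0 = if (model == 2L) fence$x0 else 1)
}

#' Advance a system state by one (or more) propagator steps
#'
#' Runs the overdamped Langevin propagator: per particle a diffusion draw
#' `sqrt(2 D0 dt) * xi` plus the mobility-weighted deterministic forces,
#' followed by the probabilistic crossing test (if that fence model is
#' active) applied to the whole proposed displacement, then the boundary
#' conditions. Uses R's RNG, so wrap calls in `set.seed()` for
#' reproducibility.
#'
#' @param state a [system_state()].
#' @param params a [sim_params()].
#' @param nsteps number of timesteps to advance.
#' @param neighbor `"auto"` (brute force below 16 particles, voxel index
#'   otherwise), `"brute"` or `"voxel"`; both paths produce identical
#'   trajectories.
#' @return The advanced `system_state`; attribute `"counters"` carries the
#'   multi-crossing / reflection / rejected-step warning counters.
#' @export
langevin_step <- function(state, params, nsteps = 1L,
                          neighbor = c("auto", "brute", "voxel")) {
  neighbor <- match.arg(neighbor)
  ke <- kernel_env(state, params)
  box <- state$box
  res <- run_kernel(state$positions, state$radius, state$D0,
                    params$dt, as.integer(nsteps), as.integer(nsteps),
                    box$width, box$height,
                    box$boundary_x == "periodic", box$boundary_y == "periodic",
                    params$T, params$k_pair,
                    params$v_drift[1], params$v_drift[2],
                    ke$model, ke$p_hop, ke$k_fence, ke$x0,
                    ke$segs, ke$canon, ke$pickets, ke$picket_r,
                    match(neighbor, c("auto", "brute", "voxel")) - 1L,
                    state$images)
  state$positions <- res$final_positions
  state$images <- res$final_images
  state$time <- state$time + nsteps * params$dt
  attr(state, "counters") <- res$counters
  state
}

# Pure-R reference single step (independent oracle for the kernel).
# Consumes randomness in the same fixed order: all xi pairs in particle
# order, then crossing draws in particle order.
langevin_step_r <- function(state, params) {
  n <- nrow(state$positions)
  box <- state$box
  xi <- matrix(rnorm(2 * n), n, 2, byrow = TRUE)
  prop <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    gamma <- drag_coefficient(state$D0[i], params$T)
    f <- total_force(i, state, params)
    prop[i, ] <- sqrt(2 * state$D0[i] * params$dt) * xi[i, ] +
      params$dt / gamma * f
  }
  per <- box_periodic(box)
  ext <- box_extents(box)
  for (i in seq_len(n)) {
    accept <- TRUE
    if (params$fence$model == "probabilistic" && !is.null(state$mesh)) {
      cr <- path_fence_crossings(state$positions[i, ], prop[i, ], state$mesh)
      accept <- crossing_decision(cr, resolve_p_hop(params$fence, params$dt))
    }
    if (!accept) next
    p <- state$positions[i, ] + prop[i, ]
    for (k in 1:2) {
      if (per[k]) {
        while (p[k] < 0) { p[k] <- p[k] + ext[k]; state$images[i, k] <- state$images[i, k] - 1L }
        while (p[k] >= ext[k]) { p[k] <- p[k] - ext[k]; state$images[i, k] <- state$images[i, k] + 1L }
      } else {
        while (p[k] < 0 || p[k] > ext[k]) {
          p[k] <- if (p[k] < 0) -p[k] else 2 * ext[k] - p[k]
        }
      }
    }
    state$positions[i, ] <- p
  }
  state$time <- state$time + params$dt
  state
}

#' Run a membrane simulation
#'
#' Executes `params$replications` independent replications of the
#' overdamped Langevin propagator and records unwrapped particle positions
#' every `sample_interval`. Each replication derives its own child seed
#' from the master seed, so a run is bitwise reproducible and replications
#' are independent.
#'
#' @param params a [sim_params()].
#' @param box a [sim_box()] (default 100 x 100 nm periodic).
#' @param mesh optional `fence_mesh` (required by probabilistic and
#'   potential fences; used to build pickets for the picket model).
#' @param pickets optional pre-built `picket_set`; built from `mesh` and the
#'   fence parameters when the model is `"picket"` and this is `NULL`.
#' @param init `"uniform"` (random non-overlapping placement, redrawn per
#'   replication) or an n x 2 matrix of fixed start positions (nm).
#' @param neighbor neighbour-search path, see [langevin_step()].
#' @return A `trajectory_set`: unwrapped positions array
#'   `[frame, coordinate, particle, replication]`, sampling times, box,
#'   params and aggregated warning counters.
#' @examples
#' p <- sim_params(dt = 20, duration = 200, sample_interval = 20, seed = 1)
#' tr <- simulate_membrane(p)
#' dim(tr$traj)  # 11 frames x 2 x 1 particle x 1 replication
#' @export
simulate_membrane <- function(params, box = sim_box(100, 100), mesh = NULL,
                              pickets = NULL, init = "uniform",
                              neighbor = c("auto", "brute", "voxel")) {
  neighbor <- match.arg(neighbor)
  if (params$fence$model == "picket" && is.null(pickets)) {
    if (is.null(mesh)) stop("picket fences need a mesh", call. = FALSE)
    pickets <- build_pickets(mesh, params$fence$R, params$fence$l_free,
                             short_segments = params$fence$short_segments %||%
                               "error")
  }
  nsteps <- round(params$duration / params$dt)
  sample_every <- round(params$sample_interval / params$dt)
  if (nsteps %% sample_every != 0)
    stop("duration must be a multiple of sample_interval", call. = FALSE)
  nframes <- nsteps %/% sample_every + 1L
  n <- params$n_particles
  reps <- params$replications
  if (!is.null(params$seed)) set.seed(params$seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  traj <- array(NA_real_, c(nframes, 2L, n, reps))
  counters <- c(multi_cross = 0, reflections = 0, rejected = 0)
  redraws <- 0L
  radius <- rep_len(params$radius, n)
  D0 <- rep_len(params$D0, n)
  for (r in seq_len(reps)) {
    set.seed(child_seeds[r])
    if (is.matrix(init)) {
      pos0 <- init
    } else {
      pos0 <- init_positions(n, radius, box, pickets)
      redraws <- redraws + attr(pos0, "redraws")
    }
    st <- system_state(pos0, radius, D0, box, mesh = mesh, pickets = pickets)
    ke <- kernel_env(st, params)
    res <- run_kernel(st$positions, st$radius, st$D0,
                      params$dt, as.integer(nsteps), as.integer(sample_every),
                      box$width, box$height,
                      box$boundary_x == "periodic",
                      box$boundary_y == "periodic",
                      params$T, params$k_pair,
                      params$v_drift[1], params$v_drift[2],
                      ke$model, ke$p_hop, ke$k_fence, ke$x0,
                      ke$segs, ke$canon, ke$pickets, ke$picket_r,
                      match(neighbor, c("auto", "brute", "voxel")) - 1L,
                      st$images)
    traj[, , , r] <- res$traj
    counters <- counters + res$counters
  }
  structure(list(traj = traj,
                 times = seq(0, params$duration, by = params$sample_interval),
                 box = box, params = params, mesh = mesh, pickets = pickets,
                 counters = c(counters, init_redraws = redraws),
                 child_seeds = child_seeds),
            class = "trajectory_set")
}
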