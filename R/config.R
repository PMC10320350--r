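# Structured-text (YAML) run configuration. Keys mirror the standard model
# parameter names (radius, D0, T, k_pair, v_drift, L, k_fence, x0, P_hop,
# P_hop_scaled, R, l_free, dt, duration, ...). Values are either bare
# numbers in the package's internal units (nm, ns, aJ, K) or strings with
# a unit suffix ("0.8 um^2/s", "20 us"); a suffix of the wrong dimension
# is rejected naming the key.

.unit_tables <- list(
  length = c("nm" = 1, "um" = 1e3),
  time = c("ns" = 1, "us" = 1e3, "ms" = 1e6, "s" = 1e9),
  diffusivity = c("nm^2/ns" = 1, "um^2/s" = 1e-3),
  velocity = c("nm/ns" = 1, "um/s" = 1e-6),
  energy = c("aJ" = 1),
  spring = c("aJ/nm^2" = 1),
  temperature = c("K" = 1),
  probability = c(setNames(1, ""), "%" = 0.01),
  scaled_probability = c("1/sqrt(ns)" = 1, "%/sqrt(ns)" = 0.01)
)

parse_quantity <- function(value, dimension, key) {
  if (is.numeric(value)) return(as.numeric(value))
  if (!is.character(value) || length(value) != 1L)
    stop(sprintf("config key '%s': cannot parse value", key), call. = FALSE)
  m <- regmatches(value, regexec("^\\s*([-+0-9.eE]+)\\s*(.*)$", value))[[1]]
  if (length(m) != 3L || is.na(suppressWarnings(as.numeric(m[2]))))
    stop(sprintf("config key '%s': cannot parse value '%s'", key, value),
         call. = FALSE)
  num <- as.numeric(m[2])
  unit <- trimws(m[3])
  tab <- .unit_tables[[dimension]]
  if (!unit %in% names(tab))
    stop(sprintf("config key '%s': unit '%s' does not match dimension '%s'",
                 key, unit, dimension), call. = FALSE)
  num * unname(tab[unit])
}

check_keys <- function(block, allowed, section) {
  extra <- setdiff(names(block), allowed)
  if (length(extra) > 0L)
    stop(sprintf("unknown config key '%s' in section '%s'",
                 extra[[1]], section), call. = FALSE)
}

#' Standard membrane parameter defaults
#'
#' The package's baseline setup: a 100 x 100 nm periodic box, one particle
#' of radius 0.4 nm diffusing at 0.8 um^2/s at 300 K, characteristic length
#' 50 nm, picket radius 4 nm with 0.8 nm free space, potential width
#' 2.5 nm, timestep 20 ns.
#'
#' @return nested list mirroring the config file schema.
#' @export
default_config <- function() {
  list(
    box = list(width = 100, height = 100,
               boundary_x = "periodic", boundary_y = "periodic"),
    particles = list(n = 1L, radius = 0.4, D0 = 8e-4),
    fence = list(model = "none", L = 50, P_hop = NULL, P_hop_scaled = NULL,
                 k_fence = 0.0141, x0 = 2.5, R = 4, l_free = 0.8,
                 mesh_file = NULL, mesh_seed = NULL),
    simulation = list(dt = 20, duration = 2e6, sample_interval = 2e4,
                      T = 300, k_pair = 0.1, v_drift = c(0, 0),
                      seed = NULL, replications = 1L),
    experiment = list(scenario = NULL, output_dir = NULL)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, merges it over [default_config()], checks
#' every key and value, and returns resolved simulation objects.
#'
#' @param path YAML file path, or a list already parsed.
#' @return list with `params` (a [sim_params()]), `box` (a [sim_box()]),
#'   `fence_extra` (mesh construction settings: `L`, `mesh_file`,
#'   `mesh_seed`) and `experiment`.
#' @export
load_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  check_keys(cfg, c("box", "particles", "fence", "simulation", "experiment"),
             "top level")
  def <- default_config()
  check_keys(cfg$box %||% list(), names(def$box), "box")
  check_keys(cfg$particles %||% list(), names(def$particles), "particles")
  check_keys(cfg$fence %||% list(), names(def$fence), "fence")
  check_keys(cfg$simulation %||% list(), names(def$simulation), "simulation")
  check_keys(cfg$experiment %||% list(), names(def$experiment), "experiment")
  merged <- def
  for (sec in names(def))
    merged[[sec]] <- modifyList(def[[sec]], cfg[[sec]] %||% list())
  bx <- merged$box
  box <- sim_box(parse_quantity(bx$width, "length", "box.width"),
                 parse_quantity(bx$height, "length", "box.height"),
                 boundary_x = bx$boundary_x, boundary_y = bx$boundary_y)
  pt <- merged$particles
  fc <- merged$fence
  fence <- switch(
    fc$model,
    none = no_fence(),
    probabilistic = {
      if (!is.null(fc$P_hop) && !is.null(fc$P_hop_scaled))
        stop("give exactly one of P_hop / P_hop_scaled", call. = FALSE)
      if (!is.null(fc$P_hop)) {
        p <- parse_quantity(fc$P_hop, "probability", "fence.P_hop")
        if (p < 0 || p > 1)
          stop("fence.P_hop must be a probability in [0, 1]", call. = FALSE)
        probabilistic_fence(p_hop = p)
      } else if (!is.null(fc$P_hop_scaled)) {
        probabilistic_fence(p_hop_scaled = parse_quantity(
          fc$P_hop_scaled, "scaled_probability", "fence.P_hop_scaled"))
      } else stop("probabilistic fence needs P_hop or P_hop_scaled",
                  call. = FALSE)
    },
    potential = potential_fence(
      k_fence = parse_quantity(fc$k_fence, "energy", "fence.k_fence"),
      x0 = parse_quantity(fc$x0, "length", "fence.x0")),
    picket = picket_fence(
      R = parse_quantity(fc$R, "length", "fence.R"),
      l_free = parse_quantity(fc$l_free, "length", "fence.l_free")),
    stop("unknown fence model: ", fc$model, call. = FALSE))
  sm <- merged$simulation
  vd <- sm$v_drift
  if (length(vd) == 1L) vd <- list(vd, vd)
  params <- sim_params(
    dt = parse_quantity(sm$dt, "time", "simulation.dt"),
    duration = parse_quantity(sm$duration, "time", "simulation.duration"),
    sample_interval = parse_quantity(sm$sample_interval, "time",
                                     "simulation.sample_interval"),
    n_particles = pt$n,
    radius = parse_quantity(pt$radius, "length", "particles.radius"),
    D0 = parse_quantity(pt$D0, "diffusivity", "particles.D0"),
    T = parse_quantity(sm$T, "temperature", "simulation.T"),
    k_pair = parse_quantity(sm$k_pair, "spring", "simulation.k_pair"),
    v_drift = c(parse_quantity(vd[[1]], "velocity", "simulation.v_drift"),
                parse_quantity(vd[[2]], "velocity", "simulation.v_drift")),
    fence = fence,
    seed = sm$seed,
    replications = sm$replications)
  list(params = params, box = box,
       fence_extra = list(L = parse_quantity(fc$L, "length", "fence.L"),
                          mesh_file = fc$mesh_file,
                          mesh_seed = fc$mesh_seed),
       experiment = merged$experiment)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
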