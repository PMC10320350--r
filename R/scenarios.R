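# Scripted experiment scenarios at desk scale. Each scenario maps one of
# the package's standard study designs onto simulate_membrane() plus the
# observables, and (optionally) writes columnar output tables and a
# manifest. Desk-scale replication counts and durations keep a scenario in
# the minutes range; `full_scale = TRUE` switches to the full-scale study
# conditions.

#' Deterministic test fixtures
#'
#' * `"square4"` — four exact 50 x 50 nm compartments from regular seeds in
#'   a 100 x 100 nm periodic box.
#' * `"single_fence"` — one vertical fence at x = 50 nm in the same box.
#' * `"fig1_like"` — a random L = 50 nm periodic Voronoi mesh at a fixed
#'   embedded seed.
#'
#' @param name fixture name.
#' @return list with `mesh` and `params`.
#' @export
make_fixture <- function(name) {
  box <- sim_box(100, 100)
  mesh <- switch(
    name,
    square4 = voronoi_from_seeds(
      cbind(c(25, 25, 75, 75), c(25, 75, 25, 75)), box, L_target = 50),
    single_fence = manual_mesh(matrix(c(50, 0, 50, 100), 1), box),
    fig1_like = generate_periodic_voronoi(50, box, seed = 424242L),
    stop("unknown fixture: ", name, call. = FALSE))
  list(name = name, mesh = mesh,
       params = sim_params(seed = 424242L))
}

scenario_names <- c("free", "validate1d", "timestep_sweep", "crowding_sweep",
                    "drift", "relate_fences_export")

write_scenario_output <- function(tables, cfg_lines, output_dir, scenario,
                                  seed) {
  if (is.null(output_dir)) return(invisible(NULL))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    df <- tables[[nm]]
    if (is.data.frame(df) || is.matrix(df))
      write.table(as.data.frame(df), file.path(output_dir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg_path <- file.path(output_dir, "config.yaml")
  yaml::write_yaml(cfg_lines, cfg_path)
  manifest <- c(
    sprintf("scenario: %s", scenario),
    sprintf("seed: %s", format(seed)),
    sprintf("config_md5: %s", unname(tools::md5sum(cfg_path))),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("memfence"))))
  writeLines(manifest, file.path(output_dir, "manifest.txt"))
  invisible(NULL)
}

#' Run a scripted experiment scenario
#'
#' Scenarios:
#' * `"free"` — fence-free diffusion of replicated single particles;
#'   emits the MSD and effective diffusion tables.
#' * `"validate1d"` — single particle between vertical barriers every
#'   50 nm in a 2000 nm wide box (probabilistic fences), 1.58 ms;
#'   fits the 1D oracle permeability and emits profile and
#'   compartment-probability tables.
#' * `"timestep_sweep"` — probabilistic fences with the scaled hop
#'   probability across several timesteps; emits D_eff(t) per dt.
#' * `"crowding_sweep"` — D_eff(t) per particle count.
#' * `"drift"` — 100 x 500 nm box (periodic x, repulsive y), r = 2 nm
#'   particles drifting in +y among picket fences with 2 nm free space;
#'   emits g(dist) for the whole region and the upper/lower fifths.
#' * `"relate_fences_export"` — (P_hop, D_eff) and (k_fence, D_eff) curves
#'   on an L = 80 nm mesh in a 1000 x 1000 nm box, the inputs a parameter-
#'   relating fit would consume.
#'
#' @param scenario scenario name.
#' @param overrides named list of parameter overrides (`replications`,
#'   `duration`, `dt`, `n_particles`, `fence`, ...) applied over the
#'   scenario defaults.
#' @param output_dir optional directory for columnar output + manifest.
#' @param full_scale use full-scale replication counts and durations.
#' @param seed master seed.
#' @return list of result tables (invisible file output when `output_dir`
#'   is set).
#' @export
run_scenario <- function(scenario = scenario_names, overrides = list(),
                         output_dir = NULL, full_scale = FALSE, seed = 1L) {
  scenario <- match.arg(scenario)
  res <- switch(scenario,
    free = scenario_free(overrides, full_scale, seed),
    validate1d = scenario_validate1d(overrides, full_scale, seed),
    timestep_sweep = scenario_timestep_sweep(overrides, full_scale, seed),
    crowding_sweep = scenario_crowding_sweep(overrides, full_scale, seed),
    drift = scenario_drift(overrides, full_scale, seed),
    relate_fences_export = scenario_relate(overrides, full_scale, seed))
  write_scenario_output(res$tables, res$config, output_dir, scenario, seed)
  invisible(res$tables)
}

ov <- function(overrides, key, default) overrides[[key]] %||% default

scenario_free <- function(overrides, full_scale, seed) {
  reps <- ov(overrides, "replications", if (full_scale) 512L else 128L)
  params <- sim_params(dt = ov(overrides, "dt", 20),
                       duration = ov(overrides, "duration", 2e6),
                       sample_interval = ov(overrides, "sample_interval", 2e4),
                       n_particles = ov(overrides, "n_particles", 1L),
                       seed = seed, replications = reps)
  tr <- simulate_membrane(params, sim_box(100, 100))
  ms <- msd(tr)
  deff <- effective_diffusion(ms)
  fit <- fit_diffusion(tr)
  list(tables = list(msd = ms, deff = deff,
                     summary = data.frame(D_nm2_ns = fit$D, se = fit$se)),
       config = list(scenario = "free", replications = reps,
                     params = unclass(params)[c("dt", "duration",
                                                "sample_interval")]))
}

# Barrier mesh for the 1D validation: vertical fences every `spacing` nm.
barrier_mesh_1d <- function(width = 2000, height = 100, spacing = 50) {
  nb <- floor(width / spacing)
  xs <- (seq_len(nb) - 0.5) * spacing   # centred so x = width/2 lies
  box <- sim_box(width, height)         # between two barriers
  manual_mesh(cbind(xs, 0, xs, height), box, L_target = spacing)
}

scenario_validate1d <- function(overrides, full_scale, seed) {
  reps <- ov(overrides, "replications", if (full_scale) 1e5 else 1e4)
  dt <- ov(overrides, "dt", 2000)
  p_hop <- ov(overrides, "P_hop", 0.075)
  t_end <- ov(overrides, "duration", 1.58e6)
  spacing <- 50
  mesh <- barrier_mesh_1d(2000, 100, spacing)
  duration <- ceiling(t_end / dt) * dt
  params <- sim_params(dt = dt, duration = duration,
                       sample_interval = duration,
                       fence = probabilistic_fence(p_hop = p_hop),
                       seed = seed, replications = reps)
  start <- matrix(c(1000, 50), 1)       # centre between two barriers
  tr <- simulate_membrane(params, mesh$box, mesh = mesh, init = start)
  fin <- final_positions(tr, wrapped = TRUE)
  occ <- occupancy_profile(fin[, "x"], barrier_positions = mesh$segments[, 1],
                           bin_width = 2)
  centres <- (head(occ$bin_edges, -1) + tail(occ$bin_edges, -1)) / 2
  sys <- barrier_system_1d(D = params$D0, spacing = spacing, P = 0,
                           domain_half_width = 500, origin = 1000)
  fit <- fit_permeability(centres, occ$density, sys, t = duration)
  oracle_probs <- compartment_probs_1d(fit$profile)
  list(tables = list(
    occupancy = data.frame(x_nm = centres, density = occ$density),
    oracle_profile = data.frame(x_nm = fit$profile$x, pdf = fit$profile$pdf),
    compartments = data.frame(
      centre_nm = names(occ$compartment_probs),
      simulated = as.numeric(occ$compartment_probs)),
    fit = data.frame(P_nm_ns = fit$P, residual = fit$residual)),
    config = list(scenario = "validate1d", replications = reps, dt = dt,
                  P_hop = p_hop, t_ns = duration),
    fit = fit, occ = occ, oracle_probs = oracle_probs)
}

scenario_timestep_sweep <- function(overrides, full_scale, seed) {
  dts <- ov(overrides, "dts", if (full_scale) c(20, 200, 2000) else c(200, 2000))
  reps <- ov(overrides, "replications", if (full_scale) 512L else 256L)
  duration <- ov(overrides, "duration", 2e6)
  p_scaled <- ov(overrides, "P_hop_scaled", 0.001677)
  mesh <- make_fixture("fig1_like")$mesh
  out <- lapply(dts, function(dt) {
    params <- sim_params(dt = dt, duration = duration, sample_interval = 2e4,
                         fence = probabilistic_fence(p_hop_scaled = p_scaled),
                         seed = seed, replications = reps)
    tr <- simulate_membrane(params, mesh$box, mesh = mesh)
    deff <- effective_diffusion(msd(tr))
    cbind(dt_ns = dt, deff)
  })
  list(tables = list(deff_by_dt = do.call(rbind, out)),
       config = list(scenario = "timestep_sweep", dts = dts,
                     replications = reps, P_hop_scaled = p_scaled))
}

scenario_crowding_sweep <- function(overrides, full_scale, seed) {
  counts <- ov(overrides, "counts",
               if (full_scale) c(1, 500, 1000, 1500, 2000) else c(1, 500, 2000))
  duration <- ov(overrides, "duration", if (full_scale) 2e6 else 2e5)
  fence <- ov(overrides, "fence", no_fence())
  mesh <- if (fence$model == "none") NULL else make_fixture("fig1_like")$mesh
  dt <- ov(overrides, "dt", if (fence$model == "picket") 2 else 20)
  out <- lapply(counts, function(nn) {
    reps <- ov(overrides, "replications",
               max(2L, min(64L, ceiling(128 / nn))))
    params <- sim_params(dt = dt, duration = duration,
                         sample_interval = duration / 10,
                         n_particles = nn, fence = fence,
                         seed = seed + nn, replications = reps)
    tr <- simulate_membrane(params, sim_box(100, 100), mesh = mesh)
    deff <- effective_diffusion(msd(tr))
    cbind(n_particles = nn, deff)
  })
  list(tables = list(deff_by_count = do.call(rbind, out)),
       config = list(scenario = "crowding_sweep", counts = counts,
                     duration = duration, fence = fence$model))
}

scenario_drift <- function(overrides, full_scale, seed) {
  duration <- ov(overrides, "duration", if (full_scale) 5e8 else 5e6)
  n <- ov(overrides, "n_particles", if (full_scale) 500L else 100L)
  fence <- ov(overrides, "fence",
              picket_fence(R = 4, l_free = 2, short_segments = "endpoints"))
  dt <- ov(overrides, "dt", if (fence$model == "picket") 2 else 20)
  box <- sim_box(100, 500, boundary_y = "repulsive")
  mesh <- generate_periodic_voronoi(50, box, seed = seed)
  params <- sim_params(dt = dt, duration = duration,
                       sample_interval = duration / 10,
                       n_particles = n, radius = 2,
                       v_drift = ov(overrides, "v_drift", c(0, 1e-6)), # 1 um/s
                       fence = fence, seed = seed, replications = 1L)
  tr <- simulate_membrane(params, box,
                          mesh = if (fence$model == "none") NULL else mesh)
  frames <- seq(3L, length(tr$times))  # discard the transient
  tables <- list(
    g_all = radial_distribution(tr, dr = 0.5, region = "all", frames = frames),
    g_upper = radial_distribution(tr, dr = 0.5, region = "upper_fifth",
                                  frames = frames),
    g_lower = radial_distribution(tr, dr = 0.5, region = "lower_fifth",
                                  frames = frames))
  list(tables = tables,
       config = list(scenario = "drift", duration = duration, n = n,
                     fence = fence$model, dt = dt))
}

scenario_relate <- function(overrides, full_scale, seed) {
  p_hops <- ov(overrides, "p_hops", c(1e-4, 1e-3, 1e-2, 0.1, 0.5, 1))
  k_fences <- ov(overrides, "k_fences", c(0, 0.005, 0.0141, 0.03))
  reps <- ov(overrides, "replications", if (full_scale) 128L else 16L)
  duration <- ov(overrides, "duration", 2e7)
  box <- sim_box(1000, 1000)
  mesh <- generate_periodic_voronoi(80, box, seed = seed)
  run_one <- function(fence, dt) {
    params <- sim_params(dt = dt, duration = duration, sample_interval = 2e5,
                         fence = fence, seed = seed, replications = reps)
    tr <- simulate_membrane(params, box, mesh = mesh)
    deff <- effective_diffusion(msd(tr))
    tail(deff, 1L)$D
  }
  tab_p <- data.frame(P_hop = p_hops,
                      D_eff = vapply(p_hops, function(p)
                        run_one(probabilistic_fence(p_hop = p), 2000),
                        numeric(1)))
  tab_k <- data.frame(k_fence = k_fences,
                      D_eff = vapply(k_fences, function(k)
                        run_one(potential_fence(k_fence = k), 200),
                        numeric(1)))
  list(tables = list(deff_by_p_hop = tab_p, deff_by_k_fence = tab_k),
       config = list(scenario = "relate_fences_export", L = 80,
                     replications = reps, duration = duration))
}
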