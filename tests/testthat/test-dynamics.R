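test_that("pair force is linear in the overlap and zero outside contact", {
  expect_equal(pair_force_magnitude(2.0, 0.4, 0.4, 0.1), 0)
  expect_equal(pair_force_magnitude(0.6, 0.4, 0.4, 0.1), 0.02)
  # continuity at contact
  expect_lt(pair_force_magnitude(0.8 - 1e-12, 0.4, 0.4, 0.1), 1e-12)
  expect_error(pair_force_magnitude(0, 0.4, 0.4, 0.1), "coincident")
})

test_that("total force sums pair, fence and drift terms", {
  box <- sim_box(100, 100)
  params <- sim_params(v_drift = c(0, 1e-6))
  st <- system_state(matrix(c(50, 50), 1), 0.4, 8e-4, box)
  f <- total_force(1, st, params)
  gamma <- 1.380649e-5 * 300 / 8e-4       # kB T / D0
  expect_equal(f, c(0, gamma * 1e-6), tolerance = 1e-9)
  expect_equal(round(gamma, 3), 5.177)
  # isolated particle without drift
  expect_equal(total_force(1, st, sim_params()), c(0, 0))
  # Newton's third law for an overlapping pair
  st2 <- system_state(matrix(c(50, 50, 50.5, 50.2), 2, byrow = TRUE),
                      0.4, 8e-4, box)
  f1 <- total_force(1, st2, sim_params())
  f2 <- total_force(2, st2, sim_params())
  expect_equal(f1, -f2)
  expect_gt(sqrt(sum(f1^2)), 0)
})

test_that("the drift term contributes exactly dt * v_drift per step", {
  box <- sim_box(100, 100)
  params <- sim_params(dt = 20, v_drift = c(0, 1e-3),
                       duration = 20, sample_interval = 20)
  st <- system_state(matrix(c(50, 50), 1), 0.4, 8e-4, box)
  set.seed(123)
  st1 <- langevin_step(st, params)
  set.seed(123)
  xi <- rnorm(2)
  diffusion <- sqrt(2 * 8e-4 * 20) * xi
  drift <- 20 * c(0, 1e-3)
  expect_equal(st1$positions[1, ], c(50, 50) + diffusion + drift,
               tolerance = 1e-12)
})

test_that("free-diffusion step variance equals 2 D0 dt per axis", {
  params <- sim_params(dt = 20, duration = 2e6, sample_interval = 20,
                       seed = 77, replications = 1)
  tr <- simulate_membrane(params)
  steps_x <- diff(tr$traj[, 1, 1, 1])
  steps_y <- diff(tr$traj[, 2, 1, 1])
  n <- length(steps_x)
  tol <- 3 * sqrt(2 / n) * 2 * 8e-4 * 20     # 3 sigma of a sample variance
  expect_lt(abs(var(steps_x) - 2 * 8e-4 * 20), tol)
  expect_lt(abs(var(steps_y) - 2 * 8e-4 * 20), tol)
  expect_lt(abs(mean(steps_x)), 3 * sqrt(2 * 8e-4 * 20 / n))
})

test_that("a rejected crossing leaves the particle exactly in place", {
  box <- sim_box(100, 100)
  mesh <- make_fixture("single_fence")$mesh
  # strong drift pushes the particle against the impermeable fence
  params <- sim_params(dt = 2000, duration = 2e6, sample_interval = 2000,
                       v_drift = c(5e-4, 0),
                       fence = probabilistic_fence(p_hop = 0),
                       seed = 13, replications = 1)
  tr <- simulate_membrane(params, box, mesh = mesh,
                          init = matrix(c(45, 50), 1))
  xs <- tr$traj[, 1, 1, 1]
  expect_true(all(xs < 50))
  expect_gt(tr$counters[["rejected"]], 0)
  expect_gt(max(xs), 48)  # it does pile up against the fence
})

test_that("frame counts, determinism and replication independence hold", {
  params <- sim_params(dt = 20, duration = 200, sample_interval = 20,
                       seed = 4, replications = 2)
  tr <- simulate_membrane(params)
  expect_equal(dim(tr$traj), c(11L, 2L, 1L, 2L))
  expect_equal(tr$times, seq(0, 200, by = 20))
  tr2 <- simulate_membrane(params)
  expect_identical(tr$traj, tr2$traj)
  # different replications differ
  expect_false(identical(tr$traj[, , 1, 1], tr$traj[, , 1, 2]))
})

test_that("voxel and brute-force neighbour paths give bitwise-identical runs", {
  mesh <- make_fixture("fig1_like")$mesh
  params <- sim_params(dt = 20, duration = 2e4, sample_interval = 2e3,
                       n_particles = 24, radius = 0.4,
                       fence = probabilistic_fence(p_hop = 0.5),
                       seed = 15, replications = 2)
  trb <- simulate_membrane(params, mesh$box, mesh = mesh, neighbor = "brute")
  trv <- simulate_membrane(params, mesh$box, mesh = mesh, neighbor = "voxel")
  expect_identical(trb$traj, trv$traj)
})

test_that("kernel and pure-R propagator agree step by step", {
  mesh <- make_fixture("fig1_like")$mesh
  box <- mesh$box
  pk <- build_pickets(mesh, 4, 0.8, short_segments = "endpoints")
  for (fence in list(no_fence(), probabilistic_fence(p_hop = 0.4),
                     potential_fence(0.0141))) {
    params <- sim_params(dt = 2000, duration = 2000, sample_interval = 2000,
                         fence = fence, v_drift = c(1e-4, 0))
    st <- system_state(matrix(c(43, 55, 44, 55.3), 2, byrow = TRUE),
                       0.4, 8e-4, box, mesh = mesh,
                       pickets = if (fence$model == "none") pk else NULL)
    set.seed(21)
    a <- st
    for (k in 1:25) a <- langevin_step(a, params)
    set.seed(21)
    b <- st
    for (k in 1:25) b <- memfence:::langevin_step_r(b, params)
    expect_equal(a$positions, b$positions, tolerance = 1e-12)
  }
})

test_that("voxel index queries return supersets verified against brute force", {
  set.seed(31)
  for (k in 1:100) {
    box <- sim_box(runif(1, 40, 120), runif(1, 40, 120),
                   boundary_x = sample(c("periodic", "repulsive"), 1),
                   boundary_y = sample(c("periodic", "repulsive"), 1))
    n <- sample(2:40, 1)
    pos <- cbind(runif(n, 0, box$width), runif(n, 0, box$height))
    range <- runif(1, 1, 8)
    idx <- build_voxel_index(pos, box, voxel_size = range,
                             interaction_range = range)
    p <- c(runif(1, 0, box$width), runif(1, 0, box$height))
    got <- query_voxel_index(idx, p)
    want <- oracle_in_range(p, pos, box, range)
    expect_true(all(want %in% got))
  }
  # empty system
  box <- sim_box(100, 100)
  idx0 <- build_voxel_index(matrix(numeric(), 0, 2), box, 5)
  expect_length(query_voxel_index(idx0, c(10, 10)), 0L)
  # single item anywhere in its neighbourhood
  idx1 <- build_voxel_index(matrix(c(50, 50), 1), box, 5)
  expect_equal(query_voxel_index(idx1, c(52, 49)), 1L)
  expect_error(build_voxel_index(matrix(c(50, 50), 1), box, 2,
                                 interaction_range = 5), "at least")
})

test_that("oversized periodic steps raise the minimum-image guard", {
  params <- sim_params(dt = 20, duration = 20, sample_interval = 20,
                       v_drift = c(3, 0), seed = 1, replications = 1)
  expect_error(simulate_membrane(params), "step too large")
})

test_that("repulsive boundaries keep every recorded position inside the box", {
  box <- sim_box(100, 100, boundary_y = "repulsive")
  params <- sim_params(dt = 2000, duration = 2e6, sample_interval = 2e3,
                       v_drift = c(0, 5e-4), seed = 8, replications = 2)
  tr <- simulate_membrane(params, box)
  ys <- tr$traj[, 2, 1, ]
  expect_true(all(ys >= 0 & ys <= 100))
  expect_gt(tr$counters[["reflections"]], 0)
})

test_that("ensemble MSD of free diffusion follows 4 D0 t over two decades", {
  params <- sim_params(dt = 20, duration = 2e5, sample_interval = 2e3,
                       seed = 19, replications = 64)
  tr <- simulate_membrane(params)
  ms <- msd(tr)
  sel <- ms$lag_ns %in% c(2e3, 2e4, 2e5)
  expect_true(all(abs(ms$msd_nm2[sel] - 4 * 8e-4 * ms$lag_ns[sel]) <=
                    3 * ms$se[sel]))
})

test_that("crowding slows fence-free macroscopic diffusion", {
  res <- run_scenario("crowding_sweep",
                      overrides = list(counts = c(1, 500), duration = 1e5),
                      seed = 23)
  tab <- res$deff_by_count
  last <- tab[tab$lag_ns == max(tab$lag_ns), ]
  d1 <- last$D[last$n_particles == 1]
  se1 <- last$se[last$n_particles == 1]
  d500 <- last$D[last$n_particles == 500]
  expect_lt(d500, d1 + 3 * se1)
})
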