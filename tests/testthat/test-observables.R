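test_that("msd is zero for stationary particles and exact for pure drift", {
  times <- seq(0, 100, by = 10)
  nf <- length(times)
  still <- array(5, c(nf, 2, 3, 2))
  expect_true(all(msd(fake_traj(still, times))$msd_nm2 == 0))
  # pure drift v = (0.3, 0.4), |v| = 0.5: msd(t) = (0.5 t)^2
  v <- c(0.3, 0.4)
  drift <- array(0, c(nf, 2, 1, 2))
  drift[, 1, 1, ] <- v[1] * times
  drift[, 2, 1, ] <- v[2] * times
  ms <- msd(fake_traj(drift, times))
  expect_equal(ms$msd_nm2, (0.5 * ms$lag_ns)^2, tolerance = 1e-12)
})

test_that("msd is invariant under global translation and particle relabeling", {
  times <- seq(0, 200, by = 20)
  set.seed(5)
  arr <- array(cumsum(rnorm(length(times) * 2 * 4 * 3, sd = 0.3)),
               c(length(times), 2, 4, 3))
  base <- msd(fake_traj(arr, times))
  shifted <- arr + 1234.5
  expect_equal(msd(fake_traj(shifted, times))$msd_nm2, base$msd_nm2)
  relab <- arr[, , c(3, 1, 4, 2), ]
  expect_equal(msd(fake_traj(relab, times))$msd_nm2, base$msd_nm2)
})

test_that("msd rejects inconsistent lags", {
  times <- seq(0, 100, by = 10)
  tr <- fake_traj(array(0, c(11, 2, 1, 1)), times)
  expect_error(msd(tr, lags = 15), "multiples")
  expect_error(msd(tr, lags = 200), "exceeds")
})

test_that("effective diffusion inverts the MSD formula", {
  expect_equal(effective_diffusion(3200, 1e6, 2), 8e-4)
  expect_equal(effective_diffusion(0, 10), 0)
  expect_equal(effective_diffusion(c(10, 20), c(5, 5), n_dim = 1),
               c(1, 2))
  expect_error(effective_diffusion(10, 0), "positive")
})

test_that("effective diffusion recovers D0 from synthetic Brownian paths", {
  # synthetic paths generated directly from the increments definition,
  # independent of the simulator
  D0 <- 8e-4
  dt <- 1e3
  nf <- 101
  reps <- 128
  set.seed(71)
  arr <- array(0, c(nf, 2, 1, reps))
  for (r in seq_len(reps))
    arr[, , 1, r] <- apply(matrix(rnorm(2 * (nf - 1), sd = sqrt(2 * D0 * dt)),
                                  ncol = 2), 2, function(s) c(0, cumsum(s)))
  tr <- fake_traj(arr, seq(0, by = dt, length.out = nf))
  ms <- msd(tr)
  de <- effective_diffusion(ms)
  sel <- de$lag_ns %in% c(1e3, 1e4, 1e5)   # two decades of lag
  expect_true(all(abs(de$D[sel] - D0) <= 3 * de$se[sel]))
})

test_that("restricted diffusion has non-increasing D(t) beyond the microscopic regime", {
  mesh <- make_fixture("fig1_like")$mesh
  params <- sim_params(dt = 2000, duration = 2e6, sample_interval = 2e4,
                       fence = probabilistic_fence(p_hop = 0.02),
                       seed = 55, replications = 64)
  tr <- simulate_membrane(params, mesh$box, mesh = mesh)
  de <- effective_diffusion(msd(tr))
  early <- de$D[de$lag_ns == 4e4]
  late <- de$D[de$lag_ns == 2e6]
  expect_lt(late, early + 3 * sqrt(de$se[de$lag_ns == 4e4]^2 +
                                     de$se[de$lag_ns == 2e6]^2))
  expect_lt(late, 8e-4)   # macroscopic D below the free coefficient
})

test_that("radial distribution is 1 for uniform points in a periodic box", {
  box <- sim_box(100, 100)
  set.seed(41)
  frames <- replicate(60, cbind(runif(80, 0, 100), runif(80, 0, 100)),
                      simplify = FALSE)
  g <- radial_distribution(frames, box = box, dr = 1, r_max = 20)
  # uniform points: g equals (N-1)/N (the estimator normalizes by N/A but a
  # reference particle has N-1 potential neighbours)
  g_exp <- 79 / 80
  # counting error: each bin collects Poisson counts over refs x frames
  n_ref <- 80 * 60
  expected_counts <- (79 / 1e4) * pi *
    ((g$dist_nm + 0.5)^2 - (g$dist_nm - 0.5)^2) * n_ref
  se_g <- sqrt(expected_counts) / expected_counts * g_exp
  expect_true(all(abs(g$g - g_exp) <= 4 * se_g))
  expect_lt(abs(mean(g$g) - g_exp), 3 * mean(se_g) / sqrt(length(se_g)) + 0.01)
})

test_that("radial distribution vanishes below contact for hard discs", {
  box <- sim_box(100, 100)
  r <- 2
  set.seed(43)
  place <- function() {
    pos <- matrix(NA_real_, 40, 2)
    k <- 1
    while (k <= 40) {
      p <- runif(2, 0, 100)
      ok <- TRUE
      if (k > 1) {
        d <- sweep(pos[seq_len(k - 1), , drop = FALSE], 2, p)
        d <- d - round(d / 100) * 100
        ok <- all(rowSums(d^2) >= (2 * r)^2)
      }
      if (ok) { pos[k, ] <- p; k <- k + 1 }
    }
    pos
  }
  frames <- replicate(10, place(), simplify = FALSE)
  g <- radial_distribution(frames, box = box, dr = 0.5, r_max = 15)
  expect_true(all(g$g[g$dist_nm < 2 * r] == 0))
  expect_gt(mean(g$g[g$dist_nm > 2 * r + 1]), 0.5)
})

test_that("two fixed particles give a single rdf bin with the hand-computed value", {
  box <- sim_box(100, 100)
  frames <- list(rbind(c(40, 50), c(50, 50)))   # distance 10
  g <- radial_distribution(frames, box = box, dr = 1, r_max = 20)
  nz <- which(g$g > 0)
  expect_equal(g$dist_nm[nz], 10)
  rho <- 2 / 1e4
  A <- pi * (10.5^2 - 9.5^2)
  expect_equal(g$g[nz], 1 / (rho * A), tolerance = 1e-12)
})

test_that("whole-region rdf is the reference-count weighted sum of subregions", {
  box <- sim_box(100, 500, boundary_y = "repulsive")
  set.seed(47)
  # all particles inside the upper and lower fifths only
  ylow <- runif(30, 0, 100); yup <- runif(30, 400, 500)
  pos <- cbind(runif(60, 0, 100), c(ylow, yup))
  frames <- list(pos)
  g_all <- radial_distribution(frames, box = box, dr = 1, r_max = 20)
  g_up <- radial_distribution(frames, box = box, dr = 1, r_max = 20,
                              region = "upper_fifth")
  g_lo <- radial_distribution(frames, box = box, dr = 1, r_max = 20,
                              region = "lower_fifth")
  expect_equal(g_all$g, (30 * g_up$g + 30 * g_lo$g) / 60, tolerance = 1e-9)
})

test_that("occupancy profiles are normalized partitions", {
  b <- c(-75, -25, 25, 75)
  x <- c(rep(0, 90), rep(40, 8), rep(-60, 2))   # mostly central
  occ <- occupancy_profile(x, b, bin_width = 2)
  widths <- diff(occ$bin_edges)
  expect_equal(sum(occ$density * widths), 1, tolerance = 1e-9)
  expect_equal(sum(occ$compartment_probs), 1, tolerance = 1e-12)
  expect_equal(unname(occ$compartment_probs[["0"]]), 0.90)
  # all mass in one compartment
  occ1 <- occupancy_profile(rep(1, 50), b)
  expect_equal(max(occ1$compartment_probs), 1)
})
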