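test_that("characteristic length is the mean square root of compartment areas", {
  box <- sim_box(100, 100)
  fake_mesh <- function(comps) {
    structure(list(compartments = comps, box = box), class = "fence_mesh")
  }
  square <- function(w) cbind(c(0, w, w, 0), c(0, 0, w, w))
  rect <- function(w, h) cbind(c(0, w, w, 0), c(0, 0, h, h))
  expect_equal(characteristic_length(fake_mesh(list(square(50)))), 50)
  expect_equal(characteristic_length(fake_mesh(rep(list(square(50)), 4))), 50)
  # 1600 nm^2 and 3600 nm^2 -> (40 + 60) / 2
  expect_equal(characteristic_length(fake_mesh(list(rect(40, 40), rect(60, 60)))), 50)
  expect_error(characteristic_length(fake_mesh(list())), "no compartment")
})

test_that("minimum-image displacement wraps periodic axes only", {
  per <- sim_box(100, 100)
  expect_equal(min_image_displacement(c(1, 1), c(99, 1), per), c(-2, 0))
  expect_equal(min_image_displacement(c(5, 7), c(5, 7), per), c(0, 0))
  rep_x <- sim_box(100, 100, boundary_x = "repulsive")
  expect_equal(min_image_displacement(c(1, 1), c(99, 1), rep_x), c(98, 0))
  # components never exceed half the extent on periodic axes
  set.seed(1)
  for (k in 1:50) {
    a <- runif(2, 0, 100); b <- runif(2, 0, 100)
    d <- min_image_displacement(a, b, per)
    expect_true(all(abs(d) <= 50))
  }
})

test_that("periodic Voronoi generation honours the seed count and the 2% rule", {
  box <- sim_box(100, 100)
  expect_equal(round(100 * 100 / 50^2), 4)  # analytic initial count
  m <- generate_periodic_voronoi(50, box, seed = 1)
  expect_s3_class(m, "fence_mesh")
  expect_true(abs(m$L_mesh - 50) / 50 <= 0.02)
  # areas of the compartments tile the box
  areas <- vapply(m$compartments, oracle_area, numeric(1))
  expect_equal(sum(areas), 100 * 100, tolerance = 1e-9)
  # recomputing L from the compartments matches the stored value
  expect_equal(mean(sqrt(areas)), m$L_mesh, tolerance = 1e-12)
  # 2% rule over several distinct seeds
  for (s in 2:21) {
    mi <- generate_periodic_voronoi(50, box, seed = s)
    expect_true(abs(characteristic_length(mi) - 50) / 50 <= 0.02)
  }
  # preconditions
  expect_error(generate_periodic_voronoi(150, box), "exceeds")
  expect_error(generate_periodic_voronoi(80, sim_box(90, 90)), "fewer than two")
})

test_that("mesh generation is deterministic and periodic", {
  box <- sim_box(100, 100)
  m1 <- generate_periodic_voronoi(50, box, seed = 7)
  m2 <- generate_periodic_voronoi(50, box, seed = 7)
  expect_identical(m1$seeds, m2$seeds)
  expect_identical(m1$segments, m2$segments)
  # segments leaving one box edge continue at the opposite edge: the fence
  # trace on x = 0 matches the trace on x = width
  tl <- memfence:::tiled_segments(m1)$segments
  cross_at <- function(x0) {
    ys <- c()
    for (i in seq_len(nrow(tl))) {
      x1 <- tl[i, 1]; y1 <- tl[i, 2]; x2 <- tl[i, 3]; y2 <- tl[i, 4]
      if ((x1 - x0) * (x2 - x0) < 0) {
        ys <- c(ys, y1 + (x0 - x1) / (x2 - x1) * (y2 - y1))
      }
    }
    sort(ys[ys >= 0 & ys <= 100] %% 100)
  }
  expect_equal(cross_at(0), cross_at(100), tolerance = 1e-6)
})

test_that("translating the seed lattice leaves the compartment areas unchanged", {
  box <- sim_box(100, 100)
  set.seed(33)
  seeds <- cbind(runif(5, 0, 100), runif(5, 0, 100))
  m0 <- memfence:::voronoi_from_seeds(seeds, box)
  a0 <- sort(vapply(m0$compartments, oracle_area, numeric(1)))
  for (shift in list(c(100, 0), c(0, -100), c(37.5, 81.25))) {
    moved <- sweep(seeds, 2, shift, "+") %% 100
    mi <- memfence:::voronoi_from_seeds(moved, box)
    ai <- sort(vapply(mi$compartments, oracle_area, numeric(1)))
    expect_equal(ai, a0, tolerance = 1e-8)
  }
})

test_that("a large sparse box converges near the analytic seed count", {
  m <- generate_periodic_voronoi(80, sim_box(1000, 1000), seed = 3)
  expect_true(abs(attr(m, "n_seeds") - 156) <= 10)
  areas <- vapply(m$compartments, oracle_area, numeric(1))
  expect_equal(sum(areas), 1e6, tolerance = 1e-9)
  expect_true(abs(mean(sqrt(areas)) - 80) / 80 <= 0.02)
})

test_that("path_fence_crossings matches direct expectations", {
  box <- sim_box(100, 100)
  mesh <- manual_mesh(matrix(c(25, 0, 25, 100), 1), box)
  # axis-aligned crossing
  cr <- path_fence_crossings(c(24, 10), c(2, 0), mesh)
  expect_equal(nrow(cr), 1L)
  expect_equal(c(cr$x, cr$y), c(25, 10))
  # path inside one compartment
  expect_equal(nrow(path_fence_crossings(c(30, 10), c(2, 2), mesh)), 0L)
  # path ending exactly on the fence counts
  expect_equal(nrow(path_fence_crossings(c(24, 10), c(1, 0), mesh)), 1L)
  # two parallel fences traversed in order
  mesh2 <- manual_mesh(rbind(c(25, 0, 25, 100), c(30, 0, 30, 100)), box)
  cr2 <- path_fence_crossings(c(24, 50), c(10, 0), mesh2)
  expect_equal(cr2$segment, c(1L, 2L))
  expect_true(all(diff(cr2$t) > 0))
  # wrap-around crossing through the periodic boundary image
  mesh3 <- manual_mesh(matrix(c(99, 0, 99, 100), 1), box)
  cr3 <- path_fence_crossings(c(0.5, 50), c(-2, 0), mesh3)
  expect_equal(nrow(cr3), 1L)
})

test_that("path_fence_crossings agrees with the exhaustive oracle on random paths", {
  mesh <- make_fixture("fig1_like")$mesh
  set.seed(99)
  for (k in 1:200) {
    p <- c(runif(1, 0, 100), runif(1, 0, 100))
    d <- rnorm(2, sd = 15)
    got <- path_fence_crossings(p, d, mesh)
    want <- oracle_crossings(p, d, mesh)
    expect_equal(got$segment, want$segment)
    expect_equal(got$t, want$t, tolerance = 1e-9)
  }
})

test_that("mesh serialization round-trips exactly", {
  mesh <- generate_periodic_voronoi(50, sim_box(100, 100), seed = 11)
  path <- tempfile(fileext = ".txt")
  write_mesh(mesh, path)
  back <- read_mesh(path)
  expect_identical(back$segments, mesh$segments)
  expect_identical(back$box$width, mesh$box$width)
  expect_identical(back$L_mesh, mesh$L_mesh)
  expect_identical(back$L_target, mesh$L_target)
  # writing the read-back mesh reproduces the same bytes for the segments
  path2 <- tempfile(fileext = ".txt")
  write_mesh(back, path2)
  expect_identical(readLines(path)[-(1:4)], readLines(path2)[-(1:4)])
})

test_that("locate_compartment identifies containing cells", {
  f <- make_fixture("square4")
  mesh <- f$mesh
  i <- locate_compartment(c(25, 25), mesh)
  expect_false(is.na(i))
  # the seed of each cell lies in its own cell
  for (k in seq_len(nrow(mesh$seeds)))
    expect_equal(locate_compartment(mesh$seeds[k, ], mesh), k)
})
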