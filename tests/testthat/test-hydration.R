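# fixture: unit-cube channel with waters placed by hand
cube_poly <- build_polyhedron(as.matrix(expand.grid(0:1, 0:1, 0:1)) * 10)

make_fs <- function(wcoords) waters_frame_series(wcoords)

test_that("visited-water tracking matches per-frame point tests", {
  # one water pinned at the cube centre, one far outside
  nt <- 10
  coords <- array(NA_real_, c(2, 3, nt))
  for (f in 1:nt) {
    coords[1, , f] <- c(5, 5, 5)
    coords[2, , f] <- c(50, 50, 50)
  }
  fs <- make_fs(coords)
  visited <- track_channel_waters(fs, cube_poly)
  expect_identical(visited, 1001L)

  # random walkers vs brute-force per-frame oracle
  set.seed(61)
  nw <- 20
  coords <- array(runif(nw * 3 * nt, -5, 15), c(nw, 3, nt))
  fs <- make_fs(coords)
  visited <- track_channel_waters(fs, cube_poly)
  oracle <- c()
  for (w in seq_len(nw)) for (f in seq_len(nt))
    if (oracle_point_in_hull(coords[w, , f], cube_poly))
      oracle <- union(oracle, 1000L + w)
  expect_setequal(visited, oracle)
})

test_that("hydration summary averages replicas with the standard error", {
  cyl <- build_cylinder(list(bottom = c(5, 5, -10), top = c(5, 5, 20)),
                        radius = 9.5)
  # replicas with constant in-polyhedron counts 4, 6, 8
  reps <- lapply(c(4, 6, 8), function(k) {
    coords <- array(NA_real_, c(8, 3, 5))
    for (f in 1:5) {
      for (w in 1:k) coords[w, , f] <- c(5, 5, 5) + w * 0.1
      for (w in seq_len(8 - k)) coords[k + w, , f] <- c(500, 500, 500)
    }
    make_fs(coords)
  })
  hs <- hydration_summary(reps, list(cube_poly, cube_poly, cube_poly), cyl)
  expect_equal(hs$mean_waters_polyhedron, 6.0)
  expect_equal(hs$se_waters_polyhedron, 2 / sqrt(3), tolerance = 1e-12)
  expect_true(hs$mean_waters_polyhedron <= hs$mean_waters_cylinder)

  # single replica: SE 0 with a warning
  expect_warning(h1 <- hydration_summary(reps[[1]], cube_poly, cyl),
                 "single replica")
  expect_identical(h1$se_waters_polyhedron, 0)
  expect_true(h1$single_replica)
})

test_that("poisson occupancy is recovered within sampling error", {
  set.seed(71)
  lambda <- 10
  nt <- 400
  nmax <- 30
  coords <- array(NA_real_, c(nmax, 3, nt))
  for (f in seq_len(nt)) {
    k <- min(rpois(1, lambda), nmax)
    if (k > 0)
      coords[seq_len(k), , f] <- matrix(runif(3 * k, 2, 8), ncol = 3)
    if (k < nmax)
      coords[(k + 1):nmax, , f] <- matrix(500 + runif(3 * (nmax - k)),
                                          ncol = 3)
  }
  fs <- make_fs(coords)
  cnt <- mean(vapply(seq_len(nt), function(f)
    sum(point_in_polyhedron(matrix(fs$coords[water_oxygen_index(fs), , f],
                                   ncol = 3), cube_poly)), numeric(1)))
  se <- sqrt(lambda / nt)
  expect_lt(abs(cnt - lambda), 3 * se)
})

test_that("occupancy profile localises waters and conserves the total", {
  cyl <- build_cylinder(list(bottom = c(0, 0, -15), top = c(0, 0, 15)))
  coords <- array(NA_real_, c(1, 3, 4))
  for (f in 1:4) coords[1, , f] <- c(0, 0, 0.5)   # slice 8
  prof <- occupancy_profile(make_fs(coords), cyl)
  expect_equal(prof$profile$mean[8], 1.0)
  expect_equal(sum(prof$profile$mean[-8]), 0)
  expect_equal(sum(prof$profile$mean), prof$mean_in_cylinder)

  # uniform waters: slice means proportional to slice volume (equal here)
  set.seed(81)
  nw <- 50; nt <- 200
  r <- sqrt(runif(nw * nt)) * 9.5
  th <- runif(nw * nt, 0, 2 * pi)
  coords <- array(NA_real_, c(nw, 3, nt))
  coords[, 1, ] <- r * cos(th)
  coords[, 2, ] <- r * sin(th)
  coords[, 3, ] <- runif(nw * nt, -15, 15)
  fs <- make_fs(coords)
  prof <- occupancy_profile(fs, cyl)
  expect_equal(sum(prof$profile$mean), prof$mean_in_cylinder,
               tolerance = 1e-12)
  expect_true(all(abs(prof$profile$mean - nw / 15) / (nw / 15) < 0.15))
})

test_that("cumulative profile is the running sum from the bottom", {
  prof <- structure(list(profile = data.frame(
    slice = 1:3, height = c(-1, 0, 1), mean = c(1, 0, 2), se = 0)),
    class = "occupancy_profile")
  cum <- cumulative_profile(prof)
  expect_equal(cum$cumulative, c(1, 1, 3))
  prof$profile$mean <- c(0, 0, 0)
  expect_equal(cumulative_profile(prof)$cumulative, c(0, 0, 0))
  set.seed(91)
  prof$profile$mean <- runif(3)
  expect_equal(cumulative_profile(prof)$cumulative,
               cumsum(prof$profile$mean))
})

test_that("2D occupancy projection is normalised per frame", {
  cyl <- build_cylinder(list(bottom = c(0, 0, -15), top = c(0, 0, 15)))
  coords <- array(NA_real_, c(1, 3, 5))
  for (f in 1:5) coords[1, , f] <- c(2.2, 0, 3.3)
  proj <- occupancy_projection(make_fs(coords), cyl)
  expect_equal(sum(proj$counts), 1.0)
  expect_identical(sum(proj$counts > 0), 1L)

  # conservation against the in-cylinder mean for scattered waters
  set.seed(92)
  nw <- 30; nt <- 50
  coords <- array(runif(nw * 3 * nt, -12, 12), c(nw, 3, nt))
  fs <- make_fs(coords)
  proj <- occupancy_projection(fs, cyl)
  prof <- occupancy_profile(fs, cyl)
  expect_equal(proj$total, prof$mean_in_cylinder, tolerance = 1e-12)
})
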