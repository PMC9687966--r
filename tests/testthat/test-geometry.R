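test_that("hull volume matches analytic solids", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(build_polyhedron(cube)$volume, 0.001, tolerance = 1e-9)
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(build_polyhedron(tet)$volume, (1 / 6) / 1000,
               tolerance = 1e-12)
})

test_that("hull volume agrees with the tetrahedral-decomposition oracle", {
  set.seed(101)
  for (i in 1:5) {
    pts <- matrix(runif(3 * sample(6:20, 1), 0, 10), ncol = 3)
    poly <- build_polyhedron(pts)
    expect_equal(poly$volume * 1000, oracle_hull_volume(poly),
                 tolerance = 1e-9)
  }
})

test_that("hull volume matches Monte-Carlo estimate within 1%", {
  set.seed(7)
  pts <- matrix(runif(45, 0, 10), ncol = 3)
  poly <- build_polyhedron(pts)
  hits <- 0L
  n_chunk <- 1e5; n_chunks <- 10
  for (k in seq_len(n_chunks)) {
    mc <- matrix(runif(3 * n_chunk, 0, 10), ncol = 3)
    hits <- hits + sum(point_in_polyhedron(mc, poly))
  }
  est <- hits / (n_chunk * n_chunks) * 1000   # box volume 1000 A^3
  expect_equal(poly$volume * 1000, est, tolerance = 0.01)
})

test_that("adding interior points leaves the hull unchanged", {
  set.seed(11)
  pts <- matrix(runif(30, 0, 10), ncol = 3)
  poly <- build_polyhedron(pts)
  centroid <- colMeans(pts)
  inner <- (pts + matrix(centroid, nrow(pts), 3, byrow = TRUE)) / 2
  poly2 <- build_polyhedron(rbind(pts, inner))
  expect_equal(poly2$volume, poly$volume, tolerance = 1e-12)
})

test_that("point-in-polyhedron agrees with the decomposition oracle", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  poly <- build_polyhedron(cube)
  expect_true(point_in_polyhedron(c(0.5, 0.5, 0.5), poly))
  expect_false(point_in_polyhedron(c(2, 0, 0), poly))
  set.seed(21)
  pts <- matrix(runif(36, 0, 10), ncol = 3)
  poly <- build_polyhedron(pts)
  probes <- matrix(runif(3000, -1, 11), ncol = 3)
  mine <- point_in_polyhedron(probes, poly)
  theirs <- vapply(seq_len(nrow(probes)), function(i)
    oracle_point_in_hull(probes[i, ], poly), logical(1))
  expect_identical(mine, theirs)
})

test_that("degenerate corner geometry raises a named error", {
  flat <- cbind(matrix(runif(10), ncol = 2), 0)
  rownames(flat) <- paste0("A:", 1:5)
  expect_error(build_polyhedron(flat), "A:1.*coplanar|coplanar")
  expect_error(build_polyhedron(flat[1:3, ]), "at least 4")
})

test_that("median frame minimises RMSD to the mean structure", {
  # frame 2 equals the mean of frames 1 and 3 exactly
  base <- matrix(runif(15), 5, 3)
  coords <- array(NA_real_, c(5, 3, 3))
  coords[, , 1] <- base - 1
  coords[, , 2] <- base
  coords[, , 3] <- base + 1
  atoms <- data.frame(atom_name = "CA", residue_id = 1:5,
                      residue_name = "GLY", chain_id = "A")
  fs <- frame_series(coords, atoms, dt = 2)
  expect_identical(find_median_frame(fs), 2L)

  # mirror-symmetric pair: tie broken to the lowest index
  fs2 <- frame_series(coords[, , c(1, 3)], atoms, dt = 2)
  expect_identical(find_median_frame(fs2), 1L)

  # exhaustive scan oracle on random frames
  set.seed(31)
  coords <- array(rnorm(5 * 3 * 50), c(5, 3, 50))
  fs3 <- frame_series(coords, atoms, dt = 2)
  mean_str <- apply(coords, c(1, 2), mean)
  rmsd <- vapply(1:50, function(f)
    sqrt(mean((coords[, , f] - mean_str)^2)), numeric(1))
  expect_identical(find_median_frame(fs3), which.min(rmsd))

  # invariance under global rigid translation
  fs4 <- fs3
  for (f in 1:50) fs4$coords[, , f] <- fs3$coords[, , f] + 5
  expect_identical(find_median_frame(fs4), find_median_frame(fs3))

  expect_error(find_median_frame(fs3, integer()), "empty")
})

test_that("cylinder construction elongates the axis by 10%", {
  cyl <- suppressWarnings(
    build_cylinder(list(bottom = c(0, 0, 0), top = c(0, 0, 27.27))))
  expect_equal(sqrt(sum((cyl$axis_top - cyl$axis_base)^2)), 30.0,
               tolerance = 1e-3)
  expect_identical(cyl$n_slices, 15L)
  expect_error(build_cylinder(list(bottom = c(0, 0, 0), top = c(0, 0, 0))),
               "zero-length")
  expect_error(build_cylinder(list(bottom = c(0, 0, 0), top = c(0, 0, 30)),
                              segment_width = 50), "divide 360")
  expect_error(build_cylinder(list(bottom = c(0, 0, 0), top = c(0, 0, 30)),
                              ring_bounds = c(1, 5)), "radius")
})

test_that("cell assignment follows the slice/ring/segment conventions", {
  cyl <- build_cylinder(list(bottom = c(0, 0, -15), top = c(0, 0, 15)))
  # axis point at height 0.5 -> slice 8, ring 1, segment 1
  c1 <- assign_cell(c(0, 0, 0.5), cyl)
  expect_identical(c1$slice, 8L)
  expect_identical(c1$ring, 1L)
  expect_identical(c1$segment, 1L)
  # r = 4, azimuth 0, height -14 -> slice 1, ring 3 (3.5 < r <= 5)
  c2 <- assign_cell(c(4, 0, -14), cyl)
  expect_identical(c2$slice, 1L)
  expect_identical(c2$ring, 3L)
  # near-bottom height lands in slice 1; beyond the radius is outside
  expect_identical(assign_cell(c(0, 0, -14.9), cyl)$slice, 1L)
  expect_true(assign_cell(c(10, 0, 0), cyl)$outside)
  # ring bounds inclusive on the upper edge
  expect_identical(assign_cell(c(1.0, 0, 0), cyl)$ring, 1L)
  expect_identical(assign_cell(c(3.5, 0, 0), cyl)$ring, 2L)
  # top boundary closed
  expect_identical(assign_cell(c(0, 0, 15), cyl)$slice, 15L)
})

test_that("cell assignment partitions the cylinder", {
  set.seed(41)
  cyl <- build_cylinder(list(bottom = c(0, 0, -15), top = c(0, 0, 15)))
  pts <- cbind(runif(2000, -12, 12), runif(2000, -12, 12),
               runif(2000, -18, 18))
  cells <- assign_cell(pts, cyl)
  inside <- !cells$outside
  expect_true(all(!is.na(cells$slice[inside])))
  expect_true(all(is.na(cells$slice[!inside])))
  # per-cell counts sum to the in-cylinder total
  key <- paste(cells$slice, cells$ring, cells$segment)[inside]
  expect_identical(sum(table(key)), sum(inside))
  expect_true(all(cells$segment[inside] >= 1 &
                  cells$segment[inside] <= cyl$n_segments))
})

test_that("the scaffold polyhedron lies inside its enveloping cylinder", {
  spec <- synthetic_channel_spec()
  sc <- generate_scaffold(spec)
  poly <- build_polyhedron(sc, 1, data.frame(chain_id = "S",
                                             residue_id = 1:8))
  cyl <- build_cylinder(sc, 1, data.frame(chain_id = "S", residue_id = 11L),
                        data.frame(chain_id = "S", residue_id = 12L))
  set.seed(51)
  probes <- cbind(runif(3000, -6, 6), runif(3000, -6, 6),
                  runif(3000, -16, 16))
  in_poly <- point_in_polyhedron(probes, poly)
  cells <- assign_cell(probes, cyl)
  expect_true(all(!cells$outside[in_poly]))
})
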