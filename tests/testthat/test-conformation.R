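test_that("torsion angles follow the standard sign convention", {
  # planar trans and cis arrangements
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)),
               180)
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  # constructed gauche: rotate the trans end atom by +60 about the bond
  rot <- function(p, axis, ang) {
    a <- axis / sqrt(sum(axis^2)); th <- ang * pi / 180
    p * cos(th) + cross_oracle(a, p) * sin(th) + a * sum(a * p) * (1 - cos(th))
  }
  p1 <- c(0, 1, 0); p2 <- c(0, 0, 0); p3 <- c(1.5, 0, 0)
  p4_trans <- c(1.5, -1, 0)
  # rotating the trans end atom by 240 deg about the bond lands at +60
  p4 <- p3 + rot(p4_trans - p3, p3 - p2, 240)
  expect_equal(dihedral(p1, p2, p3, p4), 60, tolerance = 1e-9)
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "degenerate")
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("torsion agrees with an established reference implementation", {
  set.seed(201)
  for (i in 1:50) {
    pts <- matrix(rnorm(12, sd = 3), 4, 3)
    ok <- tryCatch({
      mine <- dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
      ref <- bio3d::torsion.xyz(as.vector(t(pts)))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) next
    delta <- (mine - ref + 180) %% 360 - 180
    expect_lt(abs(delta), 1e-6)
  }
})

test_that("torsions are invariant under rigid motions", {
  set.seed(211)
  atoms <- data.frame(atom_name = c("N", "CA", "CB", "OG"),
                      residue_id = 5L, residue_name = "SER",
                      chain_id = "A")
  coords <- array(rnorm(4 * 3 * 10, sd = 2), c(4, 3, 10))
  fs <- frame_series(coords, atoms, dt = 2)
  base <- vapply(1:10, function(f)
    dihedral(coords[1, , f], coords[2, , f], coords[3, , f],
             coords[4, , f]), numeric(1))
  for (k in 1:5) {
    m <- random_rigid_motion()
    fs2 <- apply_rigid(fs, m)
    moved <- vapply(1:10, function(f)
      dihedral(fs2$coords[1, , f], fs2$coords[2, , f], fs2$coords[3, , f],
               fs2$coords[4, , f]), numeric(1))
    expect_equal(moved, base, tolerance = 1e-9)
  }
})

# serine-like residue whose chi1 is exactly `ang` in every listed frame
ser_fs <- function(angles) {
  atoms <- data.frame(atom_name = c("N", "CA", "CB", "OG"),
                      residue_id = 5L, residue_name = "SER", chain_id = "A")
  nt <- length(angles)
  coords <- array(NA_real_, c(4, 3, nt))
  for (f in seq_len(nt)) {
    # rotating the trans reference by (chi + 180) about the bond gives chi
    a <- (angles[f] + 180) * pi / 180
    coords[1, , f] <- c(0, 1.4, 0)
    coords[2, , f] <- c(0, 0, 0)
    coords[3, , f] <- c(1.5, 0, 0)
    ref <- c(0, -1.4, 0)
    axis <- c(1, 0, 0)
    coords[4, , f] <- coords[3, , f] + ref * cos(a) +
      cross_oracle(axis, ref) * sin(a)
  }
  frame_series(coords, atoms, dt = 2)
}

test_that("chi distributions localise at the generating rotamer", {
  fs <- ser_fs(rep(-60, 20))
  d <- chi_distributions(fs, "A", 5L)
  hist <- d$chis$chi1$histogram
  expect_identical(sum(hist$density > 0), 1L)
  expect_lt(abs(hist$mid[hist$density > 0] - (-60)), 2.6)
  # histogram integrates to 1
  expect_equal(sum(hist$density) * d$bin_width, 1)

  # 50/50 two-state trajectory: two equal modes
  fs2 <- ser_fs(rep(c(-60, 60), 10))
  d2 <- chi_distributions(fs2, "A", 5L)
  h2 <- d2$chis$chi1$histogram
  occupied <- h2$mid[h2$density > 0]
  expect_identical(length(occupied), 2L)
  expect_true(all(abs(abs(occupied) - 60) < 2.6))
  expect_equal(h2$density[h2$density > 0][1], h2$density[h2$density > 0][2])

  # jittered angles: histogram mean matches the circular mean
  set.seed(221)
  ang <- -60 + rnorm(500, sd = 8)
  fs3 <- ser_fs(ang)
  d3 <- chi_distributions(fs3, "A", 5L)
  h3 <- d3$chis$chi1$histogram
  hist_mean <- sum(h3$mid * h3$density) / sum(h3$density)
  circ_mean <- atan2(mean(sin(ang * pi / 180)),
                     mean(cos(ang * pi / 180))) * 180 / pi
  expect_lt(abs(hist_mean - circ_mean), 2.5)   # within a bin width

  expect_error(chi_distributions(fs, "A", 99L), "not found")
})

test_that("residue distances follow the atom conventions", {
  atoms <- data.frame(
    atom_name = c("CA", "OG", "CA", "NZ"),
    residue_id = c(1L, 1L, 2L, 2L),
    residue_name = c("SER", "SER", "LYS", "LYS"),
    chain_id = "A")
  nt <- 4
  coords <- array(NA_real_, c(4, 3, nt))
  for (f in 1:nt) {
    coords[1, , f] <- c(0, 0, 0)
    coords[2, , f] <- c(0, 0, 1)
    coords[3, , f] <- c(5, 0, 0)
    coords[4, , f] <- c(0, 0, if (f %% 2) 5 else 7)
  }
  fs <- frame_series(coords, atoms, dt = 2)
  a <- list(chain_id = "A", residue_id = 1L)
  b <- list(chain_id = "A", residue_id = 2L)
  d_ca <- residue_distances(fs, a, b, convention = "CA")
  expect_equal(d_ca$mean, 5.0)
  expect_equal(d_ca$se, 0)
  # polar convention: OG vs NZ, oscillating 4/6 -> mean 5
  d_pol <- residue_distances(fs, a, b, convention = "polar")
  expect_equal(d_pol$mean, 5.0)
  expect_equal(sort(unique(d_pol$distances[[1]])), c(4, 6))
  # random coordinates match direct norms and survive rigid motions
  set.seed(231)
  coords2 <- array(rnorm(4 * 3 * 20), c(4, 3, 20))
  fs2 <- frame_series(coords2, atoms, dt = 2)
  d2 <- residue_distances(fs2, a, b, convention = "CA")
  expect_equal(d2$distances[[1]],
               sqrt(colSums((coords2[1, , ] - coords2[3, , ])^2)))
  m <- random_rigid_motion()
  d3 <- residue_distances(apply_rigid(fs2, m), a, b, convention = "CA")
  expect_equal(d3$mean, d2$mean, tolerance = 1e-9)
})

test_that("up/down classification thresholds distances", {
  expect_equal(classify_up_down(rep(8, 10), 11.5)$fraction_up, 1)
  expect_equal(classify_up_down(rep(13, 10), 11.5)$fraction_down, 1)
  set.seed(241)
  d <- sample(c(10, 13), 200, replace = TRUE)
  cl <- classify_up_down(d, 11.5)
  expect_equal(cl$fraction_up, mean(d == 10))
  expect_identical(cl$labels[d == 10][1], "up")
})
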