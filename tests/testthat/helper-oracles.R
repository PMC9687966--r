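# Independent oracles used across the suite. These deliberately avoid the
# package's own half-space machinery, graph library and MSD bookkeeping.

# signed volume of tetrahedron (a, b, c, d)
tetra_volume <- function(a, b, c, d) {
  m <- rbind(b - a, c - a, d - a)
  det(m) / 6
}

# tetrahedral decomposition of a polyhedron: fan of tetrahedra from the
# vertex centroid over the facets. Total volume = sum of absolute volumes;
# a point is inside iff it lies in any tetrahedron (barycentric sign test).
tetra_decomposition <- function(poly) {
  centroid <- colMeans(poly$vertex_points)
  lapply(seq_len(nrow(poly$facets)), function(i) {
    v <- poly$vertex_points[poly$facets[i, ], , drop = FALSE]
    rbind(centroid, v)
  })
}

oracle_hull_volume <- function(poly) {
  sum(vapply(tetra_decomposition(poly), function(t)
    abs(tetra_volume(t[1, ], t[2, ], t[3, ], t[4, ])), numeric(1)))
}

point_in_tetra <- function(p, t, tol = 1e-9) {
  v0 <- tetra_volume(t[1, ], t[2, ], t[3, ], t[4, ])
  if (abs(v0) < 1e-15) return(FALSE)
  s <- sign(v0)
  d1 <- tetra_volume(p, t[2, ], t[3, ], t[4, ])
  d2 <- tetra_volume(t[1, ], p, t[3, ], t[4, ])
  d3 <- tetra_volume(t[1, ], t[2, ], p, t[4, ])
  d4 <- tetra_volume(t[1, ], t[2, ], t[3, ], p)
  all(s * c(d1, d2, d3, d4) >= -tol * abs(v0))
}

oracle_point_in_hull <- function(p, poly) {
  any(vapply(tetra_decomposition(poly), function(t)
    point_in_tetra(p, t), logical(1)))
}

# breadth-first reachability on an undirected edge list of node labels
oracle_bfs_connected <- function(edges, a, b) {
  if (a == b) return(TRUE)
  if (nrow(edges) == 0) return(FALSE)
  adj <- split(c(edges[[2]], edges[[1]]), c(edges[[1]], edges[[2]]))
  seen <- a
  frontier <- a
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    if (b %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

# naive double-loop per-slice MSD accumulation (total only)
oracle_slice_msd <- function(fs, cyl, lag_frames = 1) {
  wo <- water_oxygen_index(fs)
  nt <- n_frames(fs)
  sums <- numeric(cyl$n_slices)
  ns <- integer(cyl$n_slices)
  for (w in wo) {
    for (t in seq_len(nt - lag_frames)) {
      p0 <- fs$coords[w, , t]
      p1 <- fs$coords[w, , t + lag_frames]
      cell <- assign_cell(p0, cyl)
      if (cell$outside) next
      s <- cell$slice
      sums[s] <- sums[s] + sum((p1 - p0)^2)
      ns[s] <- ns[s] + 1L
    }
  }
  list(sums = sums, ns = ns)
}

# build a frame series from a waters-only coordinate array plus a minimal
# scaffold-free atom table; waters are single-oxygen residues
waters_frame_series <- function(wcoords, dt = 2) {
  nw <- dim(wcoords)[1]
  atoms <- data.frame(atom_name = "OH2", residue_id = 1000L + seq_len(nw),
                      residue_name = "HOH", chain_id = "W")
  frame_series(wcoords, atoms, dt = dt, water_ids = 1000L + seq_len(nw))
}

# a donor/acceptor pair frame series with explicit per-frame bonded states:
# acceptor sits collinear at 2.8 A when bonded, 5.0 A when not
pair_frame_series <- function(states, dt = 2) {
  nt <- length(states)
  atoms <- data.frame(
    atom_name = c("O1", "H1", "O1"),
    residue_id = c(101L, 101L, 201L),
    residue_name = c("DON", "DON", "ACC"),
    chain_id = "D")
  coords <- array(0, c(3, 3, nt))
  coords[2, 1, ] <- 1.0
  coords[3, 1, ] <- ifelse(states, 2.8, 5.0)
  frame_series(coords, atoms, dt = dt)
}

cross_oracle <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# random rigid motion: rotation from QR of a random matrix + translation
random_rigid_motion <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::rnorm(3, sd = 10))
}

apply_rigid <- function(fs, motion) {
  out <- fs
  for (f in seq_len(n_frames(fs)))
    out$coords[, , f] <- fs$coords[, , f] %*% t(motion$R) +
      matrix(motion$t, n_atoms(fs), 3, byrow = TRUE)
  out
}
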