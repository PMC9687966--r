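#' Specification of a synthetic channel trajectory
#'
#' Ground-truth generator settings: a box-shaped scaffold of corner
#' pseudo-residues enclosing a known analytic volume, Brownian waters
#' confined to a cylinder by reflecting boundaries, an optional fixed
#' hydronium-like particle, and donor/acceptor pairs whose bonded state
#' follows a two-state Markov process with prescribed dwell times.
#'
#' Defaults mirror the analysis conditions the package is built for: 2 ps
#' frame spacing, water diffusion 0.2 A^2/ps, a 9.5 A cylinder over a 30 A
#' channel.
#'
#' @param box corner-scaffold dimensions (x, y, z) in Angstrom; the corner
#'   polyhedron volume is the box volume
#' @param radius confinement cylinder radius, Angstrom
#' @param n_waters number of waters
#' @param d_water water diffusion coefficient, A^2/ps
#' @param dt frame spacing, ps
#' @param n_frames number of frames
#' @param hydronium optional fixed position (length-3, Angstrom) of a
#'   hydronium-like particle
#' @param hbond_pairs optional data frame with one row per donor/acceptor
#'   pair: columns `bonded_dwell`, `unbonded_dwell` (mean dwell times, ps)
#'   and optional `x`, `y`, `z` (donor position)
#' @param markers optional data frame with `label` and `height` (Angstrom)
#'   of static marker residues on the axis
#' @param water_hydrogens logical: add two rigidly attached hydrogens to
#'   each water (default FALSE; the oxygen carries the position)
#' @param seed RNG seed; the same spec and seed give a bit-identical
#'   trajectory
#' @return object of class `synthetic_channel_spec`
#' @export
synthetic_channel_spec <- function(box = c(10, 10, 30), radius = 9.5,
                                   n_waters = 20, d_water = 0.2, dt = 2,
                                   n_frames = 500, hydronium = NULL,
                                   hbond_pairs = NULL, markers = NULL,
                                   water_hydrogens = FALSE, seed = 1) {
  stopifnot(length(box) == 3, all(box > 0), radius > 0, d_water >= 0,
            dt > 0, n_frames >= 1, n_waters >= 0)
  if (!is.null(hbond_pairs))
    stopifnot(all(hbond_pairs$bonded_dwell > 0),
              all(hbond_pairs$unbonded_dwell > 0))
  structure(list(box = box, radius = radius, n_waters = n_waters,
                 d_water = d_water, dt = dt, n_frames = n_frames,
                 hydronium = hydronium, hbond_pairs = hbond_pairs,
                 markers = markers, water_hydrogens = water_hydrogens,
                 seed = as.integer(seed)),
            class = "synthetic_channel_spec")
}

# static atoms of the scaffold: 8 corner residues (COR) at the box
# vertices, axis-end residues (BOT/TOP) placed so the 10%-elongated axis
# spans the box height, optional markers, donor/acceptor groups in bonded
# geometry, optional hydronium.
.scaffold_atoms <- function(spec) {
  bx <- spec$box
  atoms <- list(); coords <- list()
  add <- function(name, resid, resname, chain, xyz) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      atom_name = name, residue_id = resid, residue_name = resname,
      chain_id = chain)
    coords[[length(coords) + 1L]] <<- xyz
  }
  corners <- as.matrix(expand.grid(x = c(-1, 1) * bx[1] / 2,
                                   y = c(-1, 1) * bx[2] / 2,
                                   z = c(-1, 1) * bx[3] / 2))
  for (i in 1:8) add("CA", i, "COR", "S", corners[i, ])
  zend <- bx[3] / 2.2           # elongating by 10% recovers the box height
  add("CA", 11L, "BOT", "S", c(0, 0, -zend))
  add("CA", 12L, "TOP", "S", c(0, 0, zend))
  if (!is.null(spec$markers)) {
    for (i in seq_len(nrow(spec$markers)))
      add("CA", 20L + i, "MRK", "S", c(0, 0, spec$markers$height[i]))
  }
  if (!is.null(spec$hbond_pairs)) {
    hp <- spec$hbond_pairs
    for (i in seq_len(nrow(hp))) {
      p <- if (all(c("x", "y", "z") %in% names(hp)))
        c(hp$x[i], hp$y[i], hp$z[i]) else c(3, 0, -10 + 4 * (i - 1))
      add("O1", 100L + i, "DON", "D", p)
      add("H1", 100L + i, "DON", "D", p + c(1.0, 0, 0))
      add("O1", 200L + i, "ACC", "D", p + c(2.8, 0, 0))
    }
  }
  hyd_id <- NULL
  if (!is.null(spec$hydronium)) {
    hyd_id <- 900L
    p <- spec$hydronium
    add("OH2", hyd_id, "H3O", "X", p)
    add("H1", hyd_id, "H3O", "X", p + c(0.98, 0, 0))
    add("H2", hyd_id, "H3O", "X", p + c(-0.49, 0.85, 0))
    add("H3", hyd_id, "H3O", "X", p + c(-0.49, -0.85, 0))
  }
  list(atoms = do.call(rbind, atoms),
       coords = do.call(rbind, coords), hydronium_id = hyd_id)
}

#' Static scaffold frame
#'
#' Deterministic single-frame geometry of the synthetic channel: corner
#' residues enclosing the analytic box volume, axis-end residues for
#' cylinder construction, markers, donor/acceptor groups (bonded geometry)
#' and the optional hydronium. Contains no waters.
#'
#' @param spec a [synthetic_channel_spec()]
#' @return a single-frame `frame_series`
#' @export
generate_scaffold <- function(spec) {
  sc <- .scaffold_atoms(spec)
  frame_series(sc$coords, sc$atoms, dt = spec$dt,
               hydronium_id = sc$hydronium_id)
}

# reflect scalar coordinates into [-b, b] (mirror at the walls)
reflect_interval <- function(x, b) {
  p <- (x + b) %% (4 * b)
  ifelse(p <= 2 * b, p - b, 3 * b - p)
}

#' Simulate the synthetic channel trajectory
#'
#' Waters perform independent 3D Gaussian random walks (per-axis step
#' variance `2 * d_water * dt`) confined to the cylinder of `radius` and
#' the box height by mirror reflection; donor/acceptor pairs toggle
#' between a bonded geometry (donor-acceptor distance 2.8 A, collinear
#' D-H...A) and an unbonded one (5.0 A) following a two-state Markov chain
#' whose per-frame switching probabilities `1 - exp(-dt/dwell)` realise
#' exponential dwell times with the prescribed means. Everything is
#' reproducible from the spec seed.
#'
#' @param spec a [synthetic_channel_spec()]
#' @return a `frame_series`; when the spec has hydrogen-bond pairs, the
#'   ground-truth per-frame bonded states are attached as attribute
#'   `bond_states` (matrix pairs x frames)
#' @export
simulate_channel <- function(spec) {
  set.seed(spec$seed)
  sc <- .scaffold_atoms(spec)
  nt <- spec$n_frames
  nw <- spec$n_waters
  half_h <- spec$box[3] / 2
  rad <- spec$radius

  # waters: uniform initial positions in the confinement cylinder
  watoms <- NULL; wcoords <- NULL
  if (nw > 0) {
    r0 <- rad * sqrt(stats::runif(nw))
    th0 <- stats::runif(nw, 0, 2 * pi)
    pos <- cbind(r0 * cos(th0), r0 * sin(th0),
                 stats::runif(nw, -half_h, half_h))
    sdstep <- sqrt(2 * spec$d_water * spec$dt)
    wtraj <- array(NA_real_, c(nw, 3, nt))
    wtraj[, , 1] <- pos
    if (nt > 1) for (t in 2:nt) {
      pos <- pos + matrix(stats::rnorm(3 * nw, sd = sdstep), nw, 3)
      pos[, 3] <- reflect_interval(pos[, 3], half_h)
      r <- sqrt(pos[, 1]^2 + pos[, 2]^2)
      out <- r > rad
      if (any(out)) {
        rr <- reflect_interval(r[out], rad)   # fold r into [0, rad]
        rr <- abs(rr)
        scale <- rr / r[out]
        pos[out, 1] <- pos[out, 1] * scale
        pos[out, 2] <- pos[out, 2] * scale
      }
      wtraj[, , t] <- pos
    }
    wids <- 1000L + seq_len(nw)
    watoms <- data.frame(atom_name = "OH2", residue_id = wids,
                         residue_name = "HOH", chain_id = "W")
    if (spec$water_hydrogens) {
      watoms <- watoms[rep(seq_len(nw), each = 3), ]
      watoms$atom_name <- rep(c("OH2", "H1", "H2"), nw)
      off <- rbind(c(0, 0, 0), c(0.9572, 0, 0), c(-0.2399, 0.9266, 0))
      wtraj2 <- array(NA_real_, c(3 * nw, 3, nt))
      for (k in 1:3) for (d in 1:3)
        wtraj2[seq(k, 3 * nw, by = 3), d, ] <- wtraj[, d, ] + off[k, d]
      wtraj <- wtraj2
    }
    wcoords <- wtraj
  }

  # hydrogen-bond Markov processes
  states <- NULL
  n_static <- nrow(sc$atoms)
  static_coords <- array(rep(sc$coords, nt), c(n_static, 3, nt))
  if (!is.null(spec$hbond_pairs)) {
    hp <- spec$hbond_pairs
    np <- nrow(hp)
    states <- matrix(NA, np, nt)
    for (i in seq_len(np)) {
      p_off <- 1 - exp(-spec$dt / hp$bonded_dwell[i])
      p_on <- 1 - exp(-spec$dt / hp$unbonded_dwell[i])
      stat_p <- p_on / (p_on + p_off)       # stationary bonded probability
      s <- logical(nt)
      s[1] <- stats::runif(1) < stat_p
      if (nt > 1) {
        u <- stats::runif(nt - 1)
        for (t in 2:nt)
          s[t] <- if (s[t - 1]) u[t - 1] >= p_off else u[t - 1] < p_on
      }
      states[i, ] <- s
      # acceptor oxygen sits collinear at 2.8 A (bonded) or 5.0 A apart
      don_row <- which(sc$atoms$residue_id == 100L + i &
                       sc$atoms$atom_name == "O1" & sc$atoms$chain_id == "D")
      acc_row <- which(sc$atoms$residue_id == 200L + i &
                       sc$atoms$chain_id == "D")
      dist <- ifelse(s, 2.8, 5.0)
      base <- sc$coords[don_row, ]
      static_coords[acc_row, 1, ] <- base[1] + dist
      static_coords[acc_row, 2, ] <- base[2]
      static_coords[acc_row, 3, ] <- base[3]
    }
  }

  atoms <- rbind(sc$atoms, watoms)
  coords <- array(NA_real_, c(nrow(atoms), 3, nt))
  coords[seq_len(n_static), , ] <- static_coords
  if (!is.null(wcoords))
    coords[n_static + seq_len(dim(wcoords)[1]), , ] <- wcoords
  fs <- frame_series(coords, atoms, dt = spec$dt,
                     water_ids = if (nw > 0) 1000L + seq_len(nw) else integer(),
                     hydronium_id = sc$hydronium_id)
  if (!is.null(states)) attr(fs, "bond_states") <- states
  fs
}

#' Simulate confined Brownian waters
#'
#' Convenience wrapper over [simulate_channel()] that drops any
#' hydrogen-bond pairs from the spec: scaffold plus diffusing waters only.
#'
#' @param spec a [synthetic_channel_spec()]
#' @return a `frame_series`
#' @export
simulate_waters <- function(spec) {
  spec$hbond_pairs <- NULL
  simulate_channel(spec)
}

#' Simulate two-state Markov hydrogen-bond events
#'
#' Convenience wrapper over [simulate_channel()] that drops the waters:
#' scaffold plus donor/acceptor pairs whose geometry toggles between
#' bonded and unbonded states. The realised ground-truth states are in
#' `attr(, "bond_states")`.
#'
#' @param spec a [synthetic_channel_spec()]; must have `hbond_pairs`
#' @return a `frame_series` with attribute `bond_states`
#' @export
simulate_hbond_events <- function(spec) {
  stopifnot(!is.null(spec$hbond_pairs))
  spec$n_waters <- 0L
  simulate_channel(spec)
}

#' Simulate independent replicas
#'
#' Runs [simulate_channel()] with per-replica seeds derived from the spec
#' seed (`seed + 7919 * (replica - 1)`).
#'
#' @param spec a [synthetic_channel_spec()]
#' @param n number of replicas
#' @return list of `frame_series`
#' @export
simulate_replicas <- function(spec, n = 3) {
  lapply(seq_len(n), function(i) {
    s <- spec
    s$seed <- spec$seed + 7919L * (i - 1L)
    simulate_channel(s)
  })
}
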