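#' Trajectory frame series
#'
#' The universal input container of the package: an ordered series of
#' snapshots of labelled atom coordinates with uniform time spacing.
#' Coordinates are stored as an `n_atoms x 3 x n_frames` array in Angstrom;
#' atoms carry name, residue id, residue name and chain id. Water molecules
#' are tracked through the position of their oxygen atom.
#'
#' @param coords numeric array of dimension `c(n_atoms, 3, n_frames)`
#'   (a plain `n_atoms x 3` matrix is accepted for a single frame), in
#'   Angstrom.
#' @param atoms data frame with columns `atom_name`, `residue_id`,
#'   `residue_name`, `chain_id`; optional `element` and `mass` columns are
#'   filled in from the atom name and a standard mass table when absent.
#' @param dt time spacing between frames in ps (must be > 0).
#' @param times optional explicit frame times in ps; defaults to
#'   `dt * (0:(n_frames-1))`. Must be uniformly spaced by `dt`.
#' @param water_ids integer residue ids flagged as water; each must resolve
#'   to exactly one oxygen atom.
#' @param hydronium_id optional residue id of a hydronium-like particle.
#'
#' @return An object of class `frame_series`.
#' @export
frame_series <- function(coords, atoms, dt, times = NULL,
                         water_ids = integer(), hydronium_id = NULL) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(nrow(coords), 3L, 1L))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n_at <- dim(coords)[1]
  n_fr <- dim(coords)[3]
  if (n_fr < 1L) stop("frame series needs at least one frame")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a single positive number (ps)")
  req <- c("atom_name", "residue_id", "residue_name", "chain_id")
  if (!all(req %in% names(atoms)))
    stop("'atoms' must have columns: ", paste(req, collapse = ", "))
  if (nrow(atoms) != n_at)
    stop("atom table has ", nrow(atoms), " rows but coords has ", n_at, " atoms")
  atoms$atom_name <- as.character(atoms$atom_name)
  atoms$residue_id <- as.integer(atoms$residue_id)
  atoms$residue_name <- as.character(atoms$residue_name)
  atoms$chain_id <- as.character(atoms$chain_id)
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$atom_name)
  if (is.null(atoms$mass)) atoms$mass <- atomic_mass(atoms$element)
  if (is.null(times)) times <- dt * (seq_len(n_fr) - 1)
  if (length(times) != n_fr) stop("'times' length must equal frame count")
  if (n_fr > 1L && max(abs(diff(times) - dt)) > 1e-8)
    stop("'times' must be uniformly spaced by dt")
  water_ids <- as.integer(water_ids)
  fs <- structure(
    list(coords = coords, atoms = atoms, dt = dt, times = times,
         water_ids = water_ids,
         hydronium_id = if (is.null(hydronium_id)) NULL else as.integer(hydronium_id)),
    class = "frame_series")
  # every water id must resolve to exactly one oxygen
  wo <- water_oxygen_index(fs)
  stopifnot(length(wo) == length(water_ids))
  fs
}

#' @export
print.frame_series <- function(x, ...) {
  cat("frame_series:", n_frames(x), "frames,", n_atoms(x), "atoms, dt =",
      x$dt, "ps\n")
  cat("  waters:", length(x$water_ids),
      if (!is.null(x$hydronium_id)) sprintf(" | hydronium residue %d", x$hydronium_id)
      else "", "\n")
  invisible(x)
}

#' Number of frames / atoms in a frame series
#' @param fs a `frame_series`
#' @return integer count
#' @export
n_frames <- function(fs) dim(fs$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(fs) dim(fs$coords)[1]

#' Coordinates of one frame
#' @param fs a `frame_series`
#' @param frame frame index
#' @return `n_atoms x 3` matrix (Angstrom)
#' @export
frame_coords <- function(fs, frame) {
  stopifnot(frame >= 1, frame <= n_frames(fs))
  fs$coords[, , frame, drop = TRUE]
}

#' Indices of the oxygen atom of each flagged water
#'
#' @param fs a `frame_series`
#' @return integer vector of atom indices, named by water residue id
#' @export
water_oxygen_index <- function(fs) {
  if (length(fs$water_ids) == 0L) return(integer())
  at <- fs$atoms
  ox <- which(at$element == "O" & at$residue_id %in% fs$water_ids)
  ids <- at$residue_id[ox]
  if (anyDuplicated(ids) || !setequal(ids, fs$water_ids)) {
    bad <- unique(c(fs$water_ids[!fs$water_ids %in% ids], ids[duplicated(ids)]))
    stop("water residue(s) without exactly one oxygen atom: ",
         paste(bad, collapse = ", "))
  }
  structure(ox[match(fs$water_ids, ids)], names = fs$water_ids)
}

#' Select atom indices by chain / residue / atom name
#'
#' @param fs a `frame_series`
#' @param chain_id chain id(s), or NULL for any
#' @param residue_id residue id(s), or NULL for any
#' @param atom_name atom name(s), or NULL for any
#' @return integer vector of atom indices
#' @export
select_atoms <- function(fs, chain_id = NULL, residue_id = NULL,
                         atom_name = NULL) {
  at <- fs$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain_id)) keep <- keep & at$chain_id %in% chain_id
  if (!is.null(residue_id)) keep <- keep & at$residue_id %in% residue_id
  if (!is.null(atom_name)) keep <- keep & at$atom_name %in% atom_name
  which(keep)
}

#' Mass-weighted centre of mass of a set of atoms in one frame
#'
#' @param fs a `frame_series`
#' @param frame frame index
#' @param idx atom indices
#' @return length-3 numeric vector (Angstrom)
#' @export
centre_of_mass <- function(fs, frame, idx) {
  if (length(idx) == 0L) stop("empty atom selection")
  xyz <- fs$coords[idx, , frame, drop = FALSE]
  m <- fs$atoms$mass[idx]
  colSums(matrix(xyz, ncol = 3) * m) / sum(m)
}

#' Centres of mass of corner residues in one frame
#'
#' @param fs a `frame_series`
#' @param frame frame index
#' @param residues data frame with columns `chain_id` and `residue_id`
#'   (one row per corner residue); an optional `atom_name` column restricts
#'   the selection (e.g. "CA").
#' @return matrix of points, one row per residue
#' @export
residue_com <- function(fs, frame, residues) {
  stopifnot(all(c("chain_id", "residue_id") %in% names(residues)))
  out <- matrix(NA_real_, nrow(residues), 3)
  for (i in seq_len(nrow(residues))) {
    an <- if ("atom_name" %in% names(residues) && !is.na(residues$atom_name[i]))
      residues$atom_name[i] else NULL
    idx <- select_atoms(fs, residues$chain_id[i], residues$residue_id[i], an)
    if (length(idx) == 0L)
      stop("residue not found: chain ", residues$chain_id[i], " resid ",
           residues$residue_id[i])
    out[i, ] <- centre_of_mass(fs, frame, idx)
  }
  rownames(out) <- paste0(residues$chain_id, ":", residues$residue_id)
  out
}

# residue label used for graph nodes and tables, e.g. "A:362" or "W:1201"
residue_label <- function(fs, atom_idx) {
  at <- fs$atoms
  ifelse(at$residue_id[atom_idx] %in% fs$water_ids,
         paste0("W:", at$residue_id[atom_idx]),
         paste0(at$chain_id[atom_idx], ":", at$residue_id[atom_idx]))
}
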