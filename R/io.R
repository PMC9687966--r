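#' Subset frames of a frame series
#'
#' @param fs a `frame_series`
#' @param idx frame indices to keep (must be uniformly spaced)
#' @return a `frame_series`
#' @export
subset_frames <- function(fs, idx) {
  idx <- as.integer(idx)
  stopifnot(length(idx) >= 1, all(idx >= 1), all(idx <= n_frames(fs)))
  stride <- if (length(idx) > 1) unique(diff(idx)) else 1L
  if (length(stride) != 1L) stop("frame subset must be uniformly spaced")
  frame_series(fs$coords[, , idx, drop = FALSE], fs$atoms,
               dt = fs$dt * stride, water_ids = fs$water_ids,
               hydronium_id = fs$hydronium_id)
}

.water_residue_names <- c("HOH", "TIP3", "TIP", "WAT", "SOL", "SPC")

#' Load a trajectory into a frame series
#'
#' Reads a PDB topology and optional DCD coordinate trajectories (frames
#' concatenated in file order). Waters are recognised by residue name
#' (HOH/TIP3/WAT/SOL/SPC), the hydronium by residue name H3O. XTC is not
#' supported; convert to DCD first.
#'
#' @param topology path to a PDB file
#' @param trajectories character vector of DCD paths (optional; with none,
#'   the PDB coordinates give a single frame)
#' @param dt frame spacing of the trajectory files in ps
#' @param stride keep every `stride`-th frame (the effective spacing
#'   becomes `dt * stride`)
#' @return a `frame_series`
#' @export
load_trajectory <- function(topology, trajectories = NULL, dt = 2,
                            stride = 1) {
  if (!file.exists(topology)) stop("topology file not found: ", topology)
  pdb <- bio3d::read.pdb(topology)
  at <- pdb$atom
  atoms <- data.frame(atom_name = at$elety, residue_id = at$resno,
                      residue_name = at$resid, chain_id = at$chain)
  atoms$chain_id[is.na(atoms$chain_id)] <- "A"
  n_at <- nrow(atoms)
  if (is.null(trajectories) || length(trajectories) == 0L) {
    coords <- array(matrix(pdb$xyz, ncol = 3, byrow = TRUE), c(n_at, 3, 1))
  } else {
    xyz <- NULL
    for (tr in trajectories) {
      if (!file.exists(tr)) stop("trajectory file not found: ", tr)
      if (grepl("\\.xtc$", tr, ignore.case = TRUE))
        stop("XTC trajectories are not supported; convert to DCD")
      if (!grepl("\\.dcd$", tr, ignore.case = TRUE))
        stop("unknown trajectory format: ", tr)
      # a clean read of this dialect emits no conditions; reader warnings
      # signal a malformed/truncated file and must not pass silently
      cons_before <- getAllConnections()
      drop_new_cons <- function() {
        for (k in setdiff(getAllConnections(), cons_before))
          try(close(getConnection(k)), silent = TRUE)
      }
      x <- tryCatch(
        bio3d::read.dcd(tr, verbose = FALSE),
        error = function(e) {
          drop_new_cons()
          stop("failed to read DCD '", tr, "': ", conditionMessage(e),
               call. = FALSE)
        },
        warning = function(w) {
          drop_new_cons()
          stop("malformed or truncated DCD '", tr, "': ",
               conditionMessage(w), call. = FALSE)
        })
      if (ncol(x) != 3 * n_at)
        stop("atom-count mismatch: topology has ", n_at,
             " atoms, trajectory '", tr, "' has ", ncol(x) / 3)
      # declared frame count must match what was actually read (no silent
      # truncation)
      con <- file(tr, "rb")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readChar(con, 4))
      declared <- readBin(con, "integer", 1, size = 4, endian = "little")
      close(con)
      if (declared > 0 && declared != nrow(x))
        stop("truncated trajectory '", tr, "': header declares ", declared,
             " frames but ", nrow(x), " were read")
      xyz <- rbind(xyz, unclass(x))
    }
    nf <- nrow(xyz)
    coords <- array(NA_real_, c(n_at, 3, nf))
    for (f in seq_len(nf))
      coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  water_ids <- unique(atoms$residue_id[atoms$residue_name %in%
                                         .water_residue_names])
  hyd <- unique(atoms$residue_id[atoms$residue_name == "H3O"])
  fs <- frame_series(coords, atoms, dt = dt,
                     water_ids = water_ids,
                     hydronium_id = if (length(hyd)) hyd[1] else NULL)
  if (stride > 1) fs <- subset_frames(fs, seq(1, n_frames(fs), by = stride))
  fs
}

# minimal CHARMM-dialect DCD writer (little-endian, no unit cell);
# round-trip tested against bio3d::read.dcd
write_dcd <- function(fs, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(fs); na_ <- n_atoms(fs)
  rec <- function(writer) writer()
  wint <- function(x) writeBin(as.integer(x), con, size = 4,
                               endian = "little")
  # header record (84 bytes): CORD + 20 control words
  wint(84)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  wint(c(nf, 1, 1, nf, 0, 0, 0, 0, 0))
  writeBin(as.numeric(fs$dt), con, size = 4, endian = "little")  # delta
  wint(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 24))
  wint(84)
  # title record
  title <- formatC("generated by hydrochan", width = -80)
  wint(4 + 80); wint(1)
  writeChar(title, con, nchars = 80, eos = NULL)
  wint(4 + 80)
  # atom-count record
  wint(4); wint(na_); wint(4)
  for (f in seq_len(nf)) {
    for (d in 1:3) {
      wint(4 * na_)
      writeBin(as.numeric(fs$coords[, d, f]), con, size = 4,
               endian = "little")
      wint(4 * na_)
    }
  }
  invisible(path)
}

#' Write a frame series to PDB + DCD
#'
#' Writes the topology (first-frame coordinates) as PDB and the full
#' coordinate series as a CHARMM-dialect DCD, the same dialect
#' [load_trajectory()] consumes.
#'
#' @param fs a `frame_series`
#' @param prefix output path prefix; writes `<prefix>.pdb` and
#'   `<prefix>.dcd`
#' @return invisibly, the two paths
#' @export
write_frame_series <- function(fs, prefix) {
  pdb_path <- paste0(prefix, ".pdb")
  dcd_path <- paste0(prefix, ".dcd")
  xyz1 <- as.vector(t(fs$coords[, , 1]))
  bio3d::write.pdb(file = pdb_path, xyz = xyz1,
                   resno = fs$atoms$residue_id,
                   resid = fs$atoms$residue_name,
                   elety = fs$atoms$atom_name,
                   chain = fs$atoms$chain_id)
  write_dcd(fs, dcd_path)
  invisible(c(pdb = pdb_path, dcd = dcd_path))
}

#' Read a run configuration
#'
#' Parses a YAML run configuration and fills defaults. See
#' [run_pipeline()] for the recognised fields.
#'
#' @param path YAML file path
#' @return a `run_config` list
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a plain list with configuration fields
#' @export
as_run_config <- function(cfg) {
  defaults <- list(
    seed = 1L,
    equilibration_fraction = 0.2,
    median_window_ps = 10000,
    cylinder = list(radius = 9.5, n_slices = 15, slice_thickness = 2,
                    ring_bounds = c(1.0, 3.5, 5.0, 9.5), segment_width = 30),
    hbond = list(max_da_distance = 3.5, max_deviation = 35),
    lifetime = list(max_lag = 100, origin_spacing = 120),
    projection_bin = 1)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in names(defaults$cylinder))
    if (is.null(cfg$cylinder[[nm]])) cfg$cylinder[[nm]] <- defaults$cylinder[[nm]]
  if (is.null(cfg$synthetic) && is.null(cfg$files))
    stop("config needs a 'synthetic' or a 'files' section")
  structure(cfg, class = "run_config")
}
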