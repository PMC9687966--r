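#' Signed torsion angle of four points
#'
#' Standard IUPAC convention: looking along the p2->p3 bond, the angle is
#' positive for a clockwise rotation of the p3-p4 bond relative to the
#' p1-p2 bond; trans is 180 degrees, cis is 0. The value lies in
#' (-180, 180] and is invariant under rigid motions.
#'
#' @param p1,p2,p3,p4 length-3 numeric vectors (Angstrom)
#' @return torsion angle in degrees
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sum(b1^2) < 1e-18 || sum(b2^2) < 1e-18 || sum(b3^2) < 1e-18)
    stop("degenerate geometry: consecutive points coincide")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-18 || sum(n2^2) < 1e-18)
    stop("degenerate geometry: collinear points")
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# chi dihedral atom quadruples for the supported residue types
chi_atom_map <- function() {
  list(
    SER = list(chi1 = c("N", "CA", "CB", "OG")),
    THR = list(chi1 = c("N", "CA", "CB", "OG1")),
    TYR = list(chi1 = c("N", "CA", "CB", "CG"),
               chi2 = c("CA", "CB", "CG", "CD1")),
    HIS = list(chi1 = c("N", "CA", "CB", "CG"),
               chi2 = c("CA", "CB", "CG", "ND1")),
    GLU = list(chi1 = c("N", "CA", "CB", "CG"),
               chi2 = c("CA", "CB", "CG", "CD"),
               chi3 = c("CB", "CG", "CD", "OE1")),
    LYS = list(chi1 = c("N", "CA", "CB", "CG"),
               chi2 = c("CA", "CB", "CG", "CD"),
               chi3 = c("CB", "CG", "CD", "CE"),
               chi4 = c("CG", "CD", "CE", "NZ"))
  )
}

# polar / conventional side-chain atom used for distance analyses:
# hydroxyl O for Ser/Thr/Tyr, NZ for Lys, the CE1 carbon bridging the two
# imidazole nitrogens for His, and the CD carbon bridging the two
# carboxylate oxygens for Glu.
polar_distance_atom <- function(residue_name) {
  tab <- c(SER = "OG", THR = "OG1", TYR = "OH", LYS = "NZ", HIS = "CE1",
           HSD = "CE1", HSE = "CE1", HSP = "CE1", GLU = "CD")
  a <- tab[toupper(residue_name)]
  if (anyNA(a)) stop("no polar-atom convention for residue type: ",
                     paste(residue_name[is.na(a)], collapse = ", "))
  unname(a)
}

#' Side-chain chi dihedral distributions
#'
#' Per-frame chi1..chi4 angles (where defined for the residue type) and
#' their replica-averaged histograms on 5-degree bins over (-180, 180].
#' Histograms are normalised to integrate to 1 (density per degree).
#'
#' @param replicas a `frame_series` or list of them
#' @param chain_id,residue_id the residue
#' @param residue_name residue type for the chi atom map; default taken
#'   from the atom table
#' @param bin_width histogram bin width in degrees (default 5)
#' @return object of class `dihedral_series`: list per chi index with
#'   per-replica angle series and a pooled histogram data frame
#'   (`mid`, `density`)
#' @export
chi_distributions <- function(replicas, chain_id, residue_id,
                              residue_name = NULL, bin_width = 5) {
  replicas <- as_replica_list(replicas)
  fs1 <- replicas[[1]]
  if (is.null(residue_name)) {
    idx <- select_atoms(fs1, chain_id, residue_id)
    if (length(idx) == 0L) stop("residue not found: ", chain_id, ":",
                                residue_id)
    residue_name <- fs1$atoms$residue_name[idx[1]]
  }
  map <- chi_atom_map()[[toupper(residue_name)]]
  if (is.null(map)) stop("no chi definition for residue type ", residue_name)
  edges <- seq(-180, 180, by = bin_width)
  out <- list()
  for (chi in names(map)) {
    names4 <- map[[chi]]
    angles <- lapply(replicas, function(fs) {
      idx <- vapply(names4, function(a) {
        i <- select_atoms(fs, chain_id, residue_id, a)
        if (length(i) != 1L)
          stop("missing or ambiguous atom ", a, " in residue ", chain_id,
               ":", residue_id)
        i
      }, integer(1))
      vapply(seq_len(n_frames(fs)), function(f) {
        xyz <- fs$coords[idx, , f]
        dihedral(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
      }, numeric(1))
    })
    per <- vapply(angles, function(a) {
      hh <- graphics::hist(a, breaks = edges, plot = FALSE)
      hh$counts / (length(a) * bin_width)
    }, numeric(length(edges) - 1))
    per <- matrix(per, nrow = length(edges) - 1)
    out[[chi]] <- list(
      angles = angles,
      histogram = data.frame(mid = (edges[-1] + edges[-length(edges)]) / 2,
                             density = rowMeans(per)))
  }
  structure(list(chain_id = chain_id, residue_id = residue_id,
                 residue_name = residue_name, bin_width = bin_width,
                 chis = out),
            class = "dihedral_series")
}

#' @export
print.dihedral_series <- function(x, ...) {
  cat("dihedral_series:", x$residue_name, paste0(x$chain_id, ":",
      x$residue_id), "-", paste(names(x$chis), collapse = ", "), "\n")
  invisible(x)
}

#' Inter-residue distance series
#'
#' Per-frame Euclidean distances between one atom of each residue, with
#' replica mean and standard error. The atom convention is either "CA"
#' (channel-width measure between backbone C-alpha atoms) or "polar"
#' (hydroxyl O for Ser/Thr/Tyr, NZ for Lys, CE1 for His, CD for Glu), or
#' explicit atom names.
#'
#' @param replicas a `frame_series` or list of them
#' @param res_a,res_b lists/rows with `chain_id`, `residue_id` and optional
#'   `atom_name`
#' @param convention "CA", "polar", or "explicit" (use `atom_name` fields)
#' @return object of class `distance_series`: per-replica distance vectors,
#'   `mean`, `se`
#' @export
residue_distances <- function(replicas, res_a, res_b, convention = "CA") {
  replicas <- as_replica_list(replicas)
  atom_of <- function(fs, res) {
    nm <- switch(convention,
      CA = "CA",
      polar = {
        idx <- select_atoms(fs, res$chain_id, res$residue_id)
        if (length(idx) == 0L) stop("residue not found: ", res$chain_id,
                                    ":", res$residue_id)
        polar_distance_atom(fs$atoms$residue_name[idx[1]])
      },
      explicit = res$atom_name,
      stop("unknown atom convention: ", convention))
    i <- select_atoms(fs, res$chain_id, res$residue_id, nm)
    if (length(i) != 1L)
      stop("atom ", nm, " missing or ambiguous in residue ", res$chain_id,
           ":", res$residue_id)
    i
  }
  dists <- lapply(replicas, function(fs) {
    ia <- atom_of(fs, res_a); ib <- atom_of(fs, res_b)
    d <- fs$coords[ia, , , drop = TRUE] - fs$coords[ib, , , drop = TRUE]
    if (is.null(dim(d))) d <- matrix(d, nrow = 3)
    sqrt(colSums(d^2))
  })
  per <- vapply(dists, mean, numeric(1))
  st <- replica_mean_se(per)
  structure(list(distances = dists, per_replica = per, mean = st$mean,
                 se = st$se, convention = convention,
                 pair = paste0(res_a$chain_id, ":", res_a$residue_id, "-",
                               res_b$chain_id, ":", res_b$residue_id)),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("distance_series %s (%s): %.2f +/- %.2f A\n", x$pair,
              x$convention, x$mean, x$se))
  invisible(x)
}

#' Up/down side-chain classification
#'
#' Labels each frame "up" when the distance to a reference residue is at or
#' below the threshold (side chain pointing toward the reference/BNC side)
#' and "down" otherwise, and reports occupancy fractions.
#'
#' @param distances numeric vector of per-frame distances (Angstrom), or a
#'   `distance_series` (its pooled frames are used)
#' @param threshold classification threshold in Angstrom (default 11.5)
#' @return list with `labels` (character per frame), `fraction_up`,
#'   `fraction_down`
#' @export
classify_up_down <- function(distances, threshold = 11.5) {
  stopifnot(threshold > 0)
  if (inherits(distances, "distance_series"))
    distances <- unlist(distances$distances, use.names = FALSE)
  lab <- ifelse(distances <= threshold, "up", "down")
  list(labels = lab, fraction_up = mean(lab == "up"),
       fraction_down = mean(lab == "down"))
}
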