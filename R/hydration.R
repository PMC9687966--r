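#' Per-frame channel polyhedra
#'
#' Convenience wrapper building the corner-residue polyhedron for every
#' frame of a trajectory.
#'
#' @param fs a `frame_series`
#' @param corners corner residue selection (see [build_polyhedron()])
#' @return list of `channel_polyhedron`, one per frame
#' @export
channel_polyhedra <- function(fs, corners = NULL) {
  lapply(seq_len(n_frames(fs)), function(f) build_polyhedron(fs, f, corners))
}

#' Waters that ever visit the channel polyhedron
#'
#' Returns the ids of all waters whose oxygen lies inside the per-frame
#' channel polyhedron in at least one frame. This visited set gates which
#' waters enter the cylinder-based analyses.
#'
#' @param fs a `frame_series`
#' @param polys a single `channel_polyhedron` (applied to every frame) or a
#'   list with one polyhedron per frame
#' @return integer vector of water residue ids
#' @export
track_channel_waters <- function(fs, polys) {
  wo <- water_oxygen_index(fs)
  if (length(wo) == 0L) return(integer())
  if (inherits(polys, "channel_polyhedron"))
    polys <- rep(list(polys), n_frames(fs))
  stopifnot(length(polys) == n_frames(fs))
  seen <- rep(FALSE, length(wo))
  for (f in seq_len(n_frames(fs))) {
    pts <- fs$coords[wo, , f, drop = FALSE]
    seen <- seen | point_in_polyhedron(matrix(pts, ncol = 3), polys[[f]])
  }
  as.integer(names(wo))[seen]
}

# per-frame water counts inside the polyhedron series
.polyhedron_counts <- function(fs, polys, water_ids = NULL) {
  wo <- water_oxygen_index(fs)
  if (!is.null(water_ids)) wo <- wo[names(wo) %in% as.character(water_ids)]
  if (inherits(polys, "channel_polyhedron"))
    polys <- rep(list(polys), n_frames(fs))
  vapply(seq_len(n_frames(fs)), function(f) {
    if (length(wo) == 0L) return(0L)
    pts <- matrix(fs$coords[wo, , f, drop = FALSE], ncol = 3)
    sum(point_in_polyhedron(pts, polys[[f]]))
  }, integer(1))
}

#' Channel hydration summary
#'
#' Average number of waters inside the channel polyhedron and inside the
#' enveloping cylinder, and the average polyhedron volume. Counts are
#' instantaneous per-frame occupancies averaged over frames within each
#' replica, then averaged across replicas with the standard error of the
#' replica means.
#'
#' @param replicas a `frame_series` or list of them (one per replica)
#' @param polys_list per-replica polyhedra: for each replica either a single
#'   `channel_polyhedron` or a per-frame list (as [channel_polyhedra()])
#' @param cyl a `channel_cylinder`
#' @param water_ids optional restriction to a water id set (e.g. the visited
#'   set from [track_channel_waters()]); applied to both counts
#' @return object of class `hydration_summary`
#' @export
hydration_summary <- function(replicas, polys_list, cyl, water_ids = NULL) {
  replicas <- as_replica_list(replicas)
  if (inherits(polys_list, "channel_polyhedron") ||
      (is.list(polys_list) && length(polys_list) &&
       inherits(polys_list[[1]], "channel_polyhedron") &&
       length(replicas) == 1L))
    polys_list <- list(polys_list)
  stopifnot(length(polys_list) == length(replicas))
  per <- lapply(seq_along(replicas), function(i) {
    fs <- replicas[[i]]
    wc <- water_cylinder_series(fs, cyl_for(cyl, i), water_ids)
    n_cyl <- colSums(wc$inside)
    n_poly <- .polyhedron_counts(fs, polys_list[[i]], water_ids)
    polys <- polys_list[[i]]
    if (inherits(polys, "channel_polyhedron")) polys <- list(polys)
    vols <- vapply(polys, `[[`, numeric(1), "volume")
    data.frame(replica = i, mean_waters_polyhedron = mean(n_poly),
               mean_waters_cylinder = mean(n_cyl),
               mean_volume = mean(vols))
  })
  per <- do.call(rbind, per)
  mp <- replica_mean_se(per$mean_waters_polyhedron)
  mc <- replica_mean_se(per$mean_waters_cylinder)
  mv <- replica_mean_se(per$mean_volume)
  if (mp$single_replica)
    warning("single replica: standard errors reported as 0")
  structure(
    list(mean_waters_polyhedron = mp$mean, se_waters_polyhedron = mp$se,
         mean_waters_cylinder = mc$mean, se_waters_cylinder = mc$se,
         mean_volume = mv$mean, se_volume = mv$se,
         per_replica = per, single_replica = mp$single_replica),
    class = "hydration_summary")
}

#' @export
print.hydration_summary <- function(x, ...) {
  cat(sprintf("hydration_summary (%d replica%s)\n", nrow(x$per_replica),
              if (nrow(x$per_replica) > 1) "s" else ""))
  cat(sprintf("  waters in polyhedron: %.2f +/- %.2f\n",
              x$mean_waters_polyhedron, x$se_waters_polyhedron))
  cat(sprintf("  waters in cylinder:   %.2f +/- %.2f\n",
              x$mean_waters_cylinder, x$se_waters_cylinder))
  cat(sprintf("  polyhedron volume:    %.3f +/- %.3f nm^3\n",
              x$mean_volume, x$se_volume))
  invisible(x)
}

#' Slice-resolved water occupancy profile
#'
#' Mean per-frame water count in each cylinder slice, replica-averaged,
#' together with the mean projected heights of optional marker residues
#' (used to annotate profiles with residue positions).
#'
#' @param replicas a `frame_series` or list of them
#' @param cyl a `channel_cylinder`
#' @param markers optional data frame (`chain_id`, `residue_id`, optional
#'   `label`) of residues whose mean projected height is reported
#' @param water_ids optional restriction to a water id set
#' @return object of class `occupancy_profile` with a `profile` data frame
#'   (slice, height, mean, se) and a `markers` data frame (label, height)
#' @export
occupancy_profile <- function(replicas, cyl, markers = NULL,
                              water_ids = NULL) {
  replicas <- as_replica_list(replicas)
  cyl1 <- cyl_for(cyl, 1)
  per <- vapply(seq_along(replicas), function(i) {
    fs <- replicas[[i]]
    ci <- cyl_for(cyl, i)
    wc <- water_cylinder_series(fs, ci, water_ids)
    sl <- factor(wc$slice[!is.na(wc$slice)], levels = seq_len(ci$n_slices))
    as.numeric(table(sl)) / n_frames(fs)
  }, numeric(cyl1$n_slices))
  per <- matrix(per, nrow = cyl1$n_slices)
  mean_ <- rowMeans(per)
  se <- if (ncol(per) > 1) apply(per, 1, stats::sd) / sqrt(ncol(per))
        else rep(0, cyl1$n_slices)
  mk <- NULL
  if (!is.null(markers)) {
    lab <- if ("label" %in% names(markers)) markers$label
           else paste0(markers$chain_id, ":", markers$residue_id)
    hts <- vapply(seq_len(nrow(markers)), function(i) {
      hs <- unlist(lapply(seq_along(replicas), function(r) {
        fs <- replicas[[r]]
        vapply(seq_len(n_frames(fs)), function(f)
          cylinder_coords(residue_com(fs, f, markers[i, , drop = FALSE]),
                          cyl_for(cyl, r))$h, numeric(1))
      }))
      mean(hs)
    }, numeric(1))
    mk <- data.frame(label = lab, height = hts)
  }
  structure(
    list(profile = data.frame(slice = seq_len(cyl1$n_slices),
                              height = slice_heights(cyl1),
                              mean = mean_, se = se),
         markers = mk, mean_in_cylinder = sum(mean_),
         n_replicas = ncol(per)),
    class = "occupancy_profile")
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat("occupancy_profile:", nrow(x$profile), "slices, mean in-cylinder count",
      signif(x$mean_in_cylinder, 5), "\n")
  print(utils::head(x$profile, 5))
  invisible(x)
}

#' Accumulated water count up to each height
#'
#' Running sum of the slice occupancy profile from the bottom slice upward;
#' the final value equals the total mean in-cylinder count.
#'
#' @param profile an `occupancy_profile`
#' @return data frame with columns `slice`, `height`, `cumulative`
#' @export
cumulative_profile <- function(profile) {
  stopifnot(inherits(profile, "occupancy_profile"))
  data.frame(slice = profile$profile$slice,
             height = profile$profile$height,
             cumulative = cumsum(profile$profile$mean))
}

#' 2D projection of water occupancy
#'
#' Bins in-cylinder water oxygen positions on a (height, in-plane
#' coordinate) grid, where the in-plane coordinate is the signed projection
#' onto a configurable azimuth direction. Counts are divided by the total
#' number of frames, so the histogram total equals the mean in-cylinder
#' water count.
#'
#' @param replicas a `frame_series` or list of them
#' @param cyl a `channel_cylinder`
#' @param bin bin width in Angstrom for both axes
#' @param azimuth projection azimuth in degrees (in-plane direction)
#' @param markers optional residue data frame; projected marker positions
#'   are included for annotation
#' @param water_ids optional restriction to a water id set
#' @return object of class `occupancy_projection`: `counts` matrix (rows =
#'   height bins, cols = in-plane bins), bin edges, and `markers`
#' @export
occupancy_projection <- function(replicas, cyl, bin = 1, azimuth = 0,
                                 markers = NULL, water_ids = NULL) {
  replicas <- as_replica_list(replicas)
  cyl1 <- cyl_for(cyl, 1)
  half <- cyl1$span / 2
  hedges <- seq(-half, half, by = bin)
  if (hedges[length(hedges)] < half) hedges <- c(hedges, half)
  dedges <- seq(-cyl1$radius, cyl1$radius, by = bin)
  if (dedges[length(dedges)] < cyl1$radius) dedges <- c(dedges, cyl1$radius)
  ca <- cos(azimuth * pi / 180); sa <- sin(azimuth * pi / 180)
  counts <- matrix(0, length(hedges) - 1, length(dedges) - 1)
  total_frames <- 0
  for (i in seq_along(replicas)) {
    fs <- replicas[[i]]
    wc <- water_cylinder_series(fs, cyl_for(cyl, i), water_ids)
    d <- wc$x1 * ca + wc$x2 * sa
    keep <- wc$inside
    hi <- findInterval(wc$h[keep], hedges, rightmost.closed = TRUE,
                       all.inside = TRUE)
    di <- findInterval(d[keep], dedges, rightmost.closed = TRUE,
                       all.inside = TRUE)
    tab <- table(factor(hi, seq_len(nrow(counts))),
                 factor(di, seq_len(ncol(counts))))
    counts <- counts + unclass(tab)
    total_frames <- total_frames + n_frames(fs)
  }
  counts <- counts / total_frames
  mk <- NULL
  if (!is.null(markers)) {
    fs1 <- replicas[[1]]
    pts <- residue_com(fs1, 1, markers)
    ccs <- cylinder_coords(pts, cyl1)
    rel <- sweep(pts, 2, cyl1$origin)
    d <- as.vector(rel %*% cyl1$e1) * ca + as.vector(rel %*% cyl1$e2) * sa
    lab <- if ("label" %in% names(markers)) markers$label
           else paste0(markers$chain_id, ":", markers$residue_id)
    mk <- data.frame(label = lab, height = ccs$h, inplane = d)
  }
  structure(list(counts = counts, height_edges = hedges,
                 inplane_edges = dedges, azimuth = azimuth, markers = mk,
                 total = sum(counts)),
            class = "occupancy_projection")
}

#' @export
print.occupancy_projection <- function(x, ...) {
  cat("occupancy_projection:", nrow(x$counts), "x", ncol(x$counts),
      "bins, total", signif(x$total, 5), "waters/frame\n")
  invisible(x)
}
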