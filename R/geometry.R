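#' Median-structure frame
#'
#' Returns the frame (within a window) whose coordinates have the lowest
#' root-mean-square deviation, without refitting, to the coordinate-wise
#' mean structure over that window. Ties break to the lowest index. The
#' analysis cylinder is anchored on this frame.
#'
#' @param fs a `frame_series`
#' @param window integer frame indices to consider (default: all frames)
#' @return single frame index
#' @export
find_median_frame <- function(fs, window = NULL) {
  if (is.null(window)) window <- seq_len(n_frames(fs))
  window <- as.integer(window)
  if (length(window) == 0L) stop("empty frame window")
  stopifnot(all(window >= 1), all(window <= n_frames(fs)))
  sub <- fs$coords[, , window, drop = FALSE]
  mean_str <- apply(sub, c(1, 2), mean)
  rmsd <- vapply(seq_along(window), function(i)
    sqrt(mean((sub[, , i] - mean_str)^2)), numeric(1))
  window[which.min(rmsd)]
}

#' Channel analysis cylinder
#'
#' Constructs the cylinder that envelops the channel polyhedron: the axis
#' runs from the centre of mass of the C-alpha atoms of the lowermost
#' residues to that of the uppermost residues, elongated by 10% (5% beyond
#' each end) so the channel entrance and exit are covered. The cylinder
#' height is partitioned into `n_slices` slices of `slice_thickness`
#' Angstrom; the sliced span (by default 15 x 2 = 30 Angstrom) is centred
#' on the axis midpoint. Slices are subdivided radially at `ring_bounds`
#' and angularly into `segment_width`-degree segments.
#'
#' Heights are signed: origin at the axis midpoint, positive toward the top
#' (exit / BNC) end.
#'
#' @param x a `frame_series` (its `frame` is used), or directly a list with
#'   numeric `bottom` and `top` points (Angstrom) bypassing residue lookup.
#' @param frame frame index of the median structure.
#' @param bottom,top residue selections (data frames with `chain_id`,
#'   `residue_id`) for the lowermost / uppermost residues; their C-alpha
#'   ("CA") atoms define the axis end points.
#' @param radius cylinder radius, Angstrom.
#' @param n_slices number of axial slices.
#' @param slice_thickness slice thickness, Angstrom.
#' @param ring_bounds increasing radial bounds, Angstrom; the last must
#'   equal `radius`. Defaults to the four rings
#'   r <= 1.0 < r <= 3.5 < r <= 5.0 < r <= 9.5.
#' @param segment_width angular segment width in degrees; must divide 360.
#' @return An object of class `channel_cylinder`.
#' @export
build_cylinder <- function(x, frame = 1, bottom = NULL, top = NULL,
                           radius = 9.5, n_slices = 15, slice_thickness = 2,
                           ring_bounds = c(1.0, 3.5, 5.0, 9.5),
                           segment_width = 30) {
  if (inherits(x, "frame_series")) {
    stopifnot(!is.null(bottom), !is.null(top))
    bottom$atom_name <- "CA"
    top$atom_name <- "CA"
    b <- colMeans(residue_com(x, frame, bottom))
    t_ <- colMeans(residue_com(x, frame, top))
  } else {
    b <- x$bottom
    t_ <- x$top
  }
  axis_vec <- t_ - b
  len <- sqrt(sum(axis_vec^2))
  if (len <= 1e-9) stop("zero-length cylinder axis")
  u <- axis_vec / len
  # elongate 5% beyond each end (10% total)
  base <- b - 0.05 * len * u
  tip <- t_ + 0.05 * len * u
  elong_len <- 1.10 * len
  span <- n_slices * slice_thickness
  if (elong_len < span * 0.99)   # small rounding deficits are tolerated
    warning("sliced span (", span, " A) exceeds the elongated axis (",
            signif(elong_len, 4), " A); slices extend beyond the axis ends")
  stopifnot(radius > 0, n_slices >= 1, slice_thickness > 0)
  ring_bounds <- sort(as.numeric(ring_bounds))
  if (abs(ring_bounds[length(ring_bounds)] - radius) > 1e-9)
    stop("last ring bound must equal the cylinder radius")
  if (abs(360 / segment_width - round(360 / segment_width)) > 1e-9)
    stop("segment_width must divide 360")
  mid <- (base + tip) / 2
  # deterministic in-plane reference frame for azimuth
  zref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- cross3(zref, u); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(u, e1)
  structure(
    list(axis_base = base, axis_top = tip, axis_unit = u, origin = mid,
         e1 = e1, e2 = e2, radius = radius, n_slices = as.integer(n_slices),
         slice_thickness = slice_thickness, span = span,
         ring_bounds = ring_bounds, segment_width = segment_width,
         n_rings = length(ring_bounds),
         n_segments = as.integer(round(360 / segment_width))),
    class = "channel_cylinder")
}

#' @export
print.channel_cylinder <- function(x, ...) {
  cat("channel_cylinder: radius", x$radius, "A,", x$n_slices, "slices x",
      x$slice_thickness, "A,", x$n_rings, "rings,", x$n_segments,
      "segments\n")
  cat("  axis", signif(sqrt(sum((x$axis_top - x$axis_base)^2)), 4),
      "A; height origin at axis midpoint, + toward top\n")
  invisible(x)
}

#' Cylinder coordinates of points
#'
#' Projects points into the cylinder frame: signed height along the axis
#' (origin at the midpoint, positive toward the top end), radial distance
#' from the axis, and azimuth in degrees in [0, 360).
#'
#' @param points `n x 3` matrix (or length-3 vector), Angstrom
#' @param cyl a `channel_cylinder`
#' @return data frame with columns `h`, `r`, `azimuth`
#' @export
cylinder_coords <- function(points, cyl) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  rel <- sweep(points, 2, cyl$origin)
  h <- as.vector(rel %*% cyl$axis_unit)
  x1 <- as.vector(rel %*% cyl$e1)
  x2 <- as.vector(rel %*% cyl$e2)
  r <- sqrt(x1^2 + x2^2)
  az <- (atan2(x2, x1) * 180 / pi) %% 360
  az[r == 0] <- 0
  data.frame(h = h, r = r, azimuth = az)
}

#' Assign points to cylinder cells
#'
#' Each point maps to exactly one cell (slice, ring, segment) or to the
#' sentinel "outside". Slices are half-open `[low, high)` intervals with
#' the topmost slice closed at the top; ring bounds are inclusive on their
#' upper edge; segments are half-open `[0, w)` degrees with r = 0 assigned
#' to segment 1 by convention.
#'
#' @param points `n x 3` matrix (or length-3 vector), Angstrom
#' @param cyl a `channel_cylinder`
#' @return data frame with integer columns `slice`, `ring`, `segment` and
#'   logical `outside` (cell columns are NA for outside points)
#' @export
assign_cell <- function(points, cyl) {
  cc <- cylinder_coords(points, cyl)
  half <- cyl$span / 2
  tol <- 1e-9
  inside <- cc$r <= cyl$radius + tol & cc$h >= -half - tol & cc$h <= half + tol
  slice <- floor((cc$h + half) / cyl$slice_thickness) + 1
  slice[cc$h >= half - tol] <- cyl$n_slices   # topmost slice closed at top
  slice[slice < 1] <- NA
  ring <- as.integer(cut(cc$r, breaks = c(-Inf, cyl$ring_bounds),
                         right = TRUE, labels = FALSE))
  seg <- floor(cc$azimuth / cyl$segment_width) + 1
  seg[seg > cyl$n_segments] <- 1L
  out <- data.frame(slice = as.integer(slice), ring = ring,
                    segment = as.integer(seg), outside = !inside)
  out$slice[!inside] <- NA_integer_
  out$ring[!inside] <- NA_integer_
  out$segment[!inside] <- NA_integer_
  out
}

#' Slice centre heights of a cylinder
#' @param cyl a `channel_cylinder`
#' @return numeric vector of signed slice-centre heights (Angstrom)
#' @export
slice_heights <- function(cyl) {
  -cyl$span / 2 + (seq_len(cyl$n_slices) - 0.5) * cyl$slice_thickness
}
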