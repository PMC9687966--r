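# 3D convex hull by incremental insertion.
#
# Point sets here are small (channel corner residues: ~15 points), so an
# O(n * faces) incremental construction in plain R is more than fast enough
# and keeps the geometry auditable. Faces are kept as index triples with
# outward orientation; tolerances are absolute in Angstrom, scaled to the
# point cloud extent.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# faces: k x 3 index matrix. Returns list(normals, offsets) with unit
# normals n and offsets d such that the face plane is {x: n.x = d}.
.face_planes <- function(pts, faces) {
  k <- nrow(faces)
  nrm <- matrix(0, k, 3)
  off <- numeric(k)
  for (i in seq_len(k)) {
    a <- pts[faces[i, 1], ]; b <- pts[faces[i, 2], ]; cc <- pts[faces[i, 3], ]
    n <- cross3(b - a, cc - a)
    ln <- sqrt(sum(n^2))
    if (ln > 0) n <- n / ln
    nrm[i, ] <- n
    off[i] <- sum(n * a)
  }
  list(normals = nrm, offsets = off)
}

convex_hull_3d <- function(pts, tol = 1e-9) {
  stopifnot(is.matrix(pts), ncol(pts) == 3)
  n <- nrow(pts)
  if (n < 4) stop("convex hull needs at least 4 points")
  scale <- max(apply(pts, 2, function(v) diff(range(v))), 1)
  eps <- tol * scale + 1e-12

  # initial simplex: two extreme points, then max distance from the line,
  # then max distance from the plane
  i1 <- which.min(pts[, 1])
  d1 <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d1)
  if (sqrt(d1[i2]) <= eps) stop("degenerate geometry: all points coincide")
  u <- (pts[i2, ] - pts[i1, ]) / sqrt(d1[i2])
  rel <- sweep(pts, 2, pts[i1, ])
  perp2 <- rowSums(rel^2) - (rel %*% u)[, 1]^2
  i3 <- which.max(perp2)
  if (sqrt(max(perp2[i3], 0)) <= eps)
    stop("degenerate geometry: points are collinear")
  nrm <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  pl <- abs((rel %*% nrm)[, 1])
  i4 <- which.max(pl)
  if (pl[i4] <= eps) stop("degenerate geometry: points are coplanar")

  interior <- colMeans(pts[c(i1, i2, i3, i4), ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  orient <- function(f) {
    a <- pts[f[1], ]
    nn <- cross3(pts[f[2], ] - a, pts[f[3], ] - a)
    if (sum(nn * (interior - a)) > 0) f[c(1, 3, 2)] else f
  }
  faces <- t(apply(faces, 1, orient))

  remaining <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in remaining) {
    pl <- .face_planes(pts, faces)
    vis <- (pl$normals %*% pts[p, ])[, 1] - pl$offsets > eps
    if (!any(vis)) next
    visf <- faces[vis, , drop = FALSE]
    # horizon: directed edges of visible faces whose reverse is not among them
    edges <- rbind(visf[, c(1, 2)], visf[, c(2, 3)], visf[, c(3, 1)])
    key <- paste(edges[, 1], edges[, 2])
    rkey <- paste(edges[, 2], edges[, 1])
    horizon <- edges[!(key %in% rkey), , drop = FALSE]
    newf <- cbind(horizon, p)
    faces <- rbind(faces[!vis, , drop = FALSE], newf)
  }

  pl <- .face_planes(pts, faces)
  # signed volume via divergence theorem over the closed outward surface
  vol <- 0
  for (i in seq_len(nrow(faces))) {
    a <- pts[faces[i, 1], ]; b <- pts[faces[i, 2], ]; cc <- pts[faces[i, 3], ]
    vol <- vol + sum(a * cross3(b, cc)) / 6
  }
  list(points = pts, facets = faces, normals = pl$normals,
       offsets = pl$offsets, volume = vol,
       vertex_idx = sort(unique(as.vector(faces))))
}

#' Channel polyhedron from corner residues
#'
#' Builds the convex hull of the centres of mass of the chosen corner
#' residues in one frame: the volume-maximal polyhedron on those vertices.
#' This polyhedron defines the channel region; water oxygens inside it in
#' at least one frame are retained for all downstream channel analyses.
#'
#' @param x a `frame_series`, or directly an `n x 3` matrix of corner
#'   points in Angstrom (rows optionally named).
#' @param frame frame index (when `x` is a `frame_series`).
#' @param corners data frame of corner residues with columns `chain_id`,
#'   `residue_id` (required when `x` is a `frame_series`). The K-channel
#'   defaults are in [kchannel_corner_residues()].
#'
#' @return An object of class `channel_polyhedron` with elements
#'   `vertex_points` (corner coordinates, Angstrom), `facets` (index
#'   triples, outward oriented), `normals`, `offsets`, and `volume` in nm^3.
#' @export
build_polyhedron <- function(x, frame = 1, corners = NULL) {
  if (inherits(x, "frame_series")) {
    if (is.null(corners)) corners <- kchannel_corner_residues()
    pts <- residue_com(x, frame, corners)
  } else {
    pts <- as.matrix(x)
  }
  labels <- rownames(pts)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(pts)))
  hull <- tryCatch(convex_hull_3d(pts), error = function(e)
    stop("degenerate channel geometry for corners [",
         paste(labels, collapse = ", "), "]: ", conditionMessage(e),
         call. = FALSE))
  structure(
    list(vertex_points = pts, facets = hull$facets, normals = hull$normals,
         offsets = hull$offsets, volume = hull$volume / 1000,
         labels = labels),
    class = "channel_polyhedron")
}

#' @export
print.channel_polyhedron <- function(x, ...) {
  cat("channel_polyhedron:", nrow(x$vertex_points), "corners,",
      nrow(x$facets), "facets, volume", signif(x$volume, 6), "nm^3\n")
  invisible(x)
}

#' Point-in-polyhedron test
#'
#' A point is inside iff it satisfies every facet half-space inequality;
#' points on the boundary count as inside.
#'
#' @param points an `n x 3` matrix (or length-3 vector) of points, Angstrom.
#' @param poly a `channel_polyhedron` from [build_polyhedron()].
#' @param tol boundary tolerance in Angstrom.
#' @return logical vector, one verdict per point.
#' @export
point_in_polyhedron <- function(points, poly, tol = 1e-7) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  s <- points %*% t(poly$normals)            # n_pts x n_facets
  apply(sweep(s, 2, poly$offsets) <= tol, 1, all)
}

#' Default K-channel corner residues
#'
#' The fifteen residues whose centres of mass span the channel polyhedron
#' in cytochrome c oxidase: twelve on chain A and three on chain B.
#'
#' @return data frame with columns `chain_id`, `residue_id`, `residue_name`.
#' @export
kchannel_corner_residues <- function() {
  data.frame(
    chain_id = c(rep("A", 12), rep("B", 3)),
    residue_id = c(227L, 238L, 284L, 287L, 315L, 324L, 327L, 356L, 363L,
                   365L, 366L, 398L, 96L, 100L, 101L),
    residue_name = c("LEU", "LEU", "HIS", "VAL", "PRO", "GLY", "GLY", "ALA",
                     "ILE", "SER", "TRP", "GLY", "HIS", "LEU", "GLU"),
    stringsAsFactors = FALSE)
}
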