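#' Per-slice squared displacements of channel waters
#'
#' Accumulates, for every ordered frame pair `(t, t + lag)` and every water
#' inside the cylinder at the start frame, the squared displacement of the
#' water oxygen into the slice occupied at the start frame ("mobilities of
#' waters leaving a slice in one time frame are assigned to the starting
#' slice"). Waters outside the cylinder at the start frame contribute
#' nothing. All consecutive origins are used.
#'
#' The squared displacement is also decomposed into axial (along the
#' cylinder axis), radial (change of axis distance) and angular (residual)
#' components, which sum exactly to the total.
#'
#' @param fs a `frame_series`
#' @param cyl a `channel_cylinder`
#' @param lag lag time in ps; must be an integer multiple of the frame
#'   spacing `dt` (default: one frame)
#' @param water_ids optional restriction to a water id set
#' @return object of class `slice_msd`: per-slice sums of squared
#'   displacement (total and components), observation counts `ns`, the
#'   fraction of frames in which each slice is occupied, and the lag
#' @export
slice_msd <- function(fs, cyl, lag = fs$dt, water_ids = NULL) {
  k <- lag / fs$dt
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("lag must be a positive integer multiple of dt = ", fs$dt, " ps")
  k <- as.integer(round(k))
  nt <- n_frames(fs)
  if (nt <= k) stop("not enough frames for lag ", lag, " ps")
  wc <- water_cylinder_series(fs, cyl, water_ids)
  ix0 <- seq_len(nt - k)
  ix1 <- ix0 + k
  dh <- wc$h[, ix1, drop = FALSE] - wc$h[, ix0, drop = FALSE]
  dx1 <- wc$x1[, ix1, drop = FALSE] - wc$x1[, ix0, drop = FALSE]
  dx2 <- wc$x2[, ix1, drop = FALSE] - wc$x2[, ix0, drop = FALSE]
  dr <- wc$r[, ix1, drop = FALSE] - wc$r[, ix0, drop = FALSE]
  total <- dh^2 + dx1^2 + dx2^2
  axial <- dh^2
  radial <- dr^2
  angular <- total - axial - radial
  start <- wc$slice[, ix0, drop = FALSE]       # NA when outside at start
  ok <- !is.na(start)
  f <- factor(start[ok], levels = seq_len(cyl$n_slices))
  sums <- data.frame(
    slice = seq_len(cyl$n_slices),
    height = slice_heights(cyl),
    sum_sq = as.numeric(tapply(total[ok], f, sum, default = 0)),
    sum_axial = as.numeric(tapply(axial[ok], f, sum, default = 0)),
    sum_radial = as.numeric(tapply(radial[ok], f, sum, default = 0)),
    sum_angular = as.numeric(tapply(angular[ok], f, sum, default = 0)),
    ns = as.integer(table(f)))
  # slice occupancy over all frames (for the insufficient-data rule)
  occ <- vapply(seq_len(cyl$n_slices), function(s)
    mean(colSums(wc$slice == s, na.rm = TRUE) > 0), numeric(1))
  structure(list(sums = sums, lag = lag, occupied_fraction = occ,
                 n_observations = sum(ok)),
            class = "slice_msd")
}

#' @export
print.slice_msd <- function(x, ...) {
  cat("slice_msd: lag", x$lag, "ps,", x$n_observations, "observations\n")
  invisible(x)
}

#' Decompose a displacement into axial, radial and angular parts
#'
#' @param from,to start and end points (`n x 3` matrices or length-3
#'   vectors), Angstrom
#' @param cyl a `channel_cylinder`
#' @return data frame with columns `axial`, `radial`, `angular`, `total`
#'   (squared Angstrom); components sum exactly to the total
#' @export
decompose_msd <- function(from, to, cyl) {
  a <- cylinder_coords(from, cyl)
  b <- cylinder_coords(to, cyl)
  if (is.null(dim(from))) from <- matrix(from, ncol = 3)
  if (is.null(dim(to))) to <- matrix(to, ncol = 3)
  total <- rowSums((to - from)^2)
  axial <- (b$h - a$h)^2
  radial <- (b$r - a$r)^2
  data.frame(axial = axial, radial = radial,
             angular = total - axial - radial, total = total)
}

#' Slice-resolved diffusion coefficients
#'
#' Converts per-slice squared-displacement sums into diffusion coefficients
#' `Ds = MSD / (6 tau)` per slice, with the insufficient-data rule: slices
#' empty in more than `empty_threshold` of the frames (default 95%) of a
#' replica get `Ds = 0` and are flagged. Replica values are combined as the
#' Ns-weighted average, with the Ns-weighted standard deviation of the
#' replica values as the spread.
#'
#' @param msd a `slice_msd` or a list of them (one per replica)
#' @param empty_threshold occupancy rule: a slice empty in more than this
#'   fraction of frames is flagged and reported as 0
#' @return object of class `diffusion_profile` with a `profile` data frame:
#'   slice, height, `ds` (A^2/ps), `ns`, directional components
#'   (`ds_axial` + `ds_radial` + `ds_angular` = `ds`), `spread`, and
#'   logical `insufficient`
#' @export
diffusion_profile <- function(msd, empty_threshold = 0.95) {
  if (inherits(msd, "slice_msd")) msd <- list(msd)
  stopifnot(all(vapply(msd, inherits, logical(1), "slice_msd")))
  lag <- msd[[1]]$lag
  stopifnot(all(vapply(msd, `[[`, numeric(1), "lag") == lag))
  if (lag <= 0) stop("lag must be positive")
  n_slices <- nrow(msd[[1]]$sums)
  per <- lapply(msd, function(m) {
    s <- m$sums
    flagged <- (1 - m$occupied_fraction) > empty_threshold
    ds <- ifelse(s$ns > 0, s$sum_sq / s$ns / (6 * lag), 0)
    comp <- lapply(c("sum_axial", "sum_radial", "sum_angular"), function(cn)
      ifelse(s$ns > 0, s[[cn]] / s$ns / (6 * lag), 0))
    ds[flagged] <- 0
    for (i in 1:3) comp[[i]][flagged] <- 0
    list(ds = ds, axial = comp[[1]], radial = comp[[2]],
         angular = comp[[3]], ns = ifelse(flagged, 0L, s$ns),
         flagged = flagged)
  })
  ns_mat <- vapply(per, `[[`, numeric(n_slices), "ns")
  ns_mat <- matrix(ns_mat, nrow = n_slices)
  wsum <- rowSums(ns_mat)
  wavg <- function(field) {
    v <- matrix(vapply(per, `[[`, numeric(n_slices), field), nrow = n_slices)
    ifelse(wsum > 0, rowSums(v * ns_mat) / wsum, 0)
  }
  ds <- wavg("ds")
  dsv <- matrix(vapply(per, `[[`, numeric(n_slices), "ds"), nrow = n_slices)
  spread <- vapply(seq_len(n_slices), function(s) {
    if (wsum[s] == 0) return(0)
    sqrt(sum(ns_mat[s, ] * (dsv[s, ] - ds[s])^2) / wsum[s])
  }, numeric(1))
  flag_mat <- matrix(vapply(per, `[[`, logical(n_slices), "flagged"),
                     nrow = n_slices)
  all_flagged <- rowSums(!flag_mat) == 0
  structure(
    list(profile = data.frame(
           slice = msd[[1]]$sums$slice, height = msd[[1]]$sums$height,
           ds = ds, ns = as.integer(wsum),
           ds_axial = wavg("axial"), ds_radial = wavg("radial"),
           ds_angular = wavg("angular"), spread = spread,
           insufficient = all_flagged),
         lag = lag, n_replicas = length(msd)),
    class = "diffusion_profile")
}

#' @export
print.diffusion_profile <- function(x, ...) {
  cat("diffusion_profile: lag", x$lag, "ps,", x$n_replicas, "replica(s)\n")
  print(utils::head(x$profile[, c("slice", "height", "ds", "ns",
                                  "insufficient")], 8))
  invisible(x)
}
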