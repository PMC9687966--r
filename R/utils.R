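# replica averaging: mean of per-replica values with the standard error of
# that mean (sd / sqrt(n)); a single replica reports SE 0 and is flagged.
replica_mean_se <- function(values) {
  values <- as.numeric(values)
  n <- sum(!is.na(values))
  m <- mean(values, na.rm = TRUE)
  se <- if (n > 1) stats::sd(values, na.rm = TRUE) / sqrt(n) else 0
  list(mean = m, se = se, n = n, single_replica = n == 1)
}

# accept a single frame_series or a list of them; always return a list
as_replica_list <- function(x) {
  if (inherits(x, "frame_series")) list(x)
  else if (is.list(x) && all(vapply(x, inherits, logical(1), "frame_series"))) x
  else stop("expected a frame_series or a list of frame_series")
}

# per-replica cylinder lookup: a single cylinder applies to every replica,
# or a list supplies one per replica (each replica anchored on its own
# median structure)
cyl_for <- function(cyl, i) {
  if (inherits(cyl, "channel_cylinder")) cyl else cyl[[i]]
}

# cylinder-frame coordinates of all water oxygens across frames; each
# element is an n_waters x n_frames matrix
water_cylinder_series <- function(fs, cyl, water_ids = NULL) {
  wo <- water_oxygen_index(fs)
  if (!is.null(water_ids)) wo <- wo[names(wo) %in% as.character(water_ids)]
  nw <- length(wo)
  nt <- n_frames(fs)
  if (nw == 0L) {
    e <- matrix(numeric(0), 0, nt)
    return(list(h = e, r = e, x1 = e, x2 = e, inside = matrix(logical(0), 0, nt),
                slice = matrix(integer(0), 0, nt), ids = integer()))
  }
  w <- fs$coords[wo, , , drop = FALSE]                  # nw x 3 x nt
  m <- matrix(aperm(w, c(1, 3, 2)), ncol = 3)           # (w fastest, then t)
  rel <- sweep(m, 2, cyl$origin)
  h <- matrix(rel %*% cyl$axis_unit, nw, nt)
  x1 <- matrix(rel %*% cyl$e1, nw, nt)
  x2 <- matrix(rel %*% cyl$e2, nw, nt)
  r <- sqrt(x1^2 + x2^2)
  half <- cyl$span / 2
  tol <- 1e-9
  inside <- r <= cyl$radius + tol & h >= -half - tol & h <= half + tol
  slice <- floor((h + half) / cyl$slice_thickness) + 1
  slice[h >= half - tol] <- cyl$n_slices
  slice[!inside] <- NA_integer_
  list(h = h, r = r, x1 = x1, x2 = x2, inside = inside,
       slice = slice, ids = as.integer(names(wo)))
}
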