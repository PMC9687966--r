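#' Geometric hydrogen-bond criterion
#'
#' A bond exists iff the donor-acceptor distance is at most
#' `max_da_distance` and the donor-hydrogen-acceptor angle deviates from
#' linear by at most `max_deviation` degrees (i.e. angle at the hydrogen
#' >= 180 - max_deviation). Both boundaries are inclusive.
#'
#' @param max_da_distance donor-acceptor cutoff, Angstrom (default 3.5)
#' @param max_deviation maximal deviation from linearity, degrees (default 35)
#' @return object of class `hbond_criterion`
#' @export
hbond_criterion <- function(max_da_distance = 3.5, max_deviation = 35) {
  stopifnot(max_da_distance > 0, max_deviation > 0)
  structure(list(max_da_distance = max_da_distance,
                 max_deviation = max_deviation),
            class = "hbond_criterion")
}

# Built-in donor/acceptor chemistry of the polar side-chain groups, water
# and hydronium, plus the synthetic donor/acceptor pseudo-residues (DON,
# ACC) emitted by the trajectory generator. hydrogens: candidate H names
# attached to the heavy atom (a donor entry with no H present simply acts
# as acceptor where allowed).
polar_chemistry <- function() {
  e <- function(res, atom, donor, acceptor, hyd = "")
    data.frame(residue_name = res, atom_name = atom, donor = donor,
               acceptor = acceptor, hydrogens = hyd)
  rbind(
    e("SER", "OG", TRUE, TRUE, "HG,HG1"),
    e("THR", "OG1", TRUE, TRUE, "HG1"),
    e("TYR", "OH", TRUE, TRUE, "HH"),
    e("LYS", "NZ", TRUE, TRUE, "HZ1,HZ2,HZ3"),
    e("GLU", "OE1", FALSE, TRUE), e("GLU", "OE2", TRUE, TRUE, "HE2"),
    e("ASP", "OD1", FALSE, TRUE), e("ASP", "OD2", TRUE, TRUE, "HD2"),
    e("ASN", "OD1", FALSE, TRUE), e("ASN", "ND2", TRUE, FALSE, "HD21,HD22"),
    e("GLN", "OE1", FALSE, TRUE), e("GLN", "NE2", TRUE, FALSE, "HE21,HE22"),
    e("ARG", "NE", TRUE, FALSE, "HE"),
    e("ARG", "NH1", TRUE, FALSE, "HH11,HH12"),
    e("ARG", "NH2", TRUE, FALSE, "HH21,HH22"),
    e("TRP", "NE1", TRUE, FALSE, "HE1"),
    e("HIS", "ND1", TRUE, TRUE, "HD1"), e("HIS", "NE2", TRUE, TRUE, "HE2"),
    e("HSD", "ND1", TRUE, TRUE, "HD1"), e("HSD", "NE2", TRUE, TRUE, "HE2"),
    e("HSE", "ND1", TRUE, TRUE, "HD1"), e("HSE", "NE2", TRUE, TRUE, "HE2"),
    e("HSP", "ND1", TRUE, TRUE, "HD1"), e("HSP", "NE2", TRUE, TRUE, "HE2"),
    e("HOH", "O", TRUE, TRUE, "H1,H2"), e("HOH", "OH2", TRUE, TRUE, "H1,H2"),
    e("TIP3", "OH2", TRUE, TRUE, "H1,H2"), e("TIP3", "O", TRUE, TRUE, "H1,H2"),
    e("WAT", "O", TRUE, TRUE, "H1,H2"), e("SOL", "OW", TRUE, TRUE, "HW1,HW2"),
    e("H3O", "O", TRUE, TRUE, "H1,H2,H3"),
    e("H3O", "OH2", TRUE, TRUE, "H1,H2,H3"),
    e("DON", "O1", TRUE, TRUE, "H1"),
    e("ACC", "O1", FALSE, TRUE)
  )
}

#' Donor and acceptor sites of a frame series
#'
#' Resolves the polar-atom chemistry table against the atom labelling:
#' donors are (heavy atom, attached hydrogen) pairs, acceptors are heavy
#' atoms. Computed once per trajectory and reused across frames.
#'
#' @param fs a `frame_series`
#' @param chemistry chemistry table (default [polar_chemistry()])
#' @return list with data frames `donors` (d_idx, h_idx, residue_id,
#'   chain_id) and `acceptors` (a_idx, residue_id, chain_id)
#' @export
hbond_sites <- function(fs, chemistry = polar_chemistry()) {
  at <- fs$atoms
  key <- paste(at$residue_name, at$atom_name)
  hit <- match(key, paste(chemistry$residue_name, chemistry$atom_name))
  heavy <- which(!is.na(hit))
  donors <- list(); acceptors <- list()
  # atoms grouped by residue for hydrogen lookup
  res_key <- paste(at$chain_id, at$residue_id)
  for (i in heavy) {
    row <- chemistry[hit[i], ]
    if (row$acceptor)
      acceptors[[length(acceptors) + 1L]] <-
        data.frame(a_idx = i, residue_id = at$residue_id[i],
                   chain_id = at$chain_id[i])
    if (row$donor && nzchar(row$hydrogens)) {
      hn <- strsplit(row$hydrogens, ",")[[1]]
      hidx <- which(res_key == res_key[i] & at$atom_name %in% hn)
      for (h in hidx)
        donors[[length(donors) + 1L]] <-
          data.frame(d_idx = i, h_idx = h, residue_id = at$residue_id[i],
                     chain_id = at$chain_id[i])
    }
  }
  bind <- function(l, cols) if (length(l)) do.call(rbind, l)
    else stats::setNames(data.frame(matrix(integer(), 0, length(cols))), cols)
  list(donors = bind(donors, c("d_idx", "h_idx", "residue_id", "chain_id")),
       acceptors = bind(acceptors, c("a_idx", "residue_id", "chain_id")))
}

#' Detect hydrogen bonds in one frame
#'
#' Applies the geometric criterion to every donor-hydrogen/acceptor
#' combination (intra-residue pairs are excluded). Waters and hydronium act
#' as both donors and acceptors; protein residues contribute their polar
#' side-chain atoms.
#'
#' @param fs a `frame_series`
#' @param frame frame index
#' @param criterion an [hbond_criterion()]
#' @param sites precomputed [hbond_sites()]; pass explicitly when scanning
#'   many frames. If the donor table has any pair without a resolvable
#'   hydrogen, this is a configuration error.
#' @return data frame with one row per bond: `d_idx`, `h_idx`, `a_idx`,
#'   `donor_res`, `acceptor_res` (labels), `distance`, `angle`
#' @export
detect_hbonds <- function(fs, frame, criterion = hbond_criterion(),
                          sites = NULL) {
  if (is.null(sites)) sites <- hbond_sites(fs)
  don <- sites$donors; acc <- sites$acceptors
  if (nrow(don) && (anyNA(don$h_idx) || any(don$h_idx < 1)))
    stop("donor without attached hydrogen in site table")
  empty <- data.frame(d_idx = integer(), h_idx = integer(),
                      a_idx = integer(), donor_res = character(),
                      acceptor_res = character(), distance = numeric(),
                      angle = numeric())
  if (nrow(don) == 0L || nrow(acc) == 0L) return(empty)
  xyz <- frame_coords(fs, frame)
  dpos <- xyz[don$d_idx, , drop = FALSE]
  apos <- xyz[acc$a_idx, , drop = FALSE]
  d2 <- outer(rowSums(dpos^2), rowSums(apos^2), "+") - 2 * dpos %*% t(apos)
  same_res <- outer(paste(don$chain_id, don$residue_id),
                    paste(acc$chain_id, acc$residue_id), "==")
  cand <- which(d2 <= criterion$max_da_distance^2 + 1e-12 & !same_res,
                arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  di <- cand[, 1]; ai <- cand[, 2]
  hpos <- xyz[don$h_idx[di], , drop = FALSE]
  v1 <- xyz[don$d_idx[di], , drop = FALSE] - hpos
  v2 <- xyz[acc$a_idx[ai], , drop = FALSE] - hpos
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  keep <- ang >= 180 - criterion$max_deviation - 1e-9
  if (!any(keep)) return(empty)
  di <- di[keep]; ai <- ai[keep]
  data.frame(
    d_idx = don$d_idx[di], h_idx = don$h_idx[di], a_idx = acc$a_idx[ai],
    donor_res = residue_label(fs, don$d_idx[di]),
    acceptor_res = residue_label(fs, acc$a_idx[ai]),
    distance = sqrt(pmax(d2[cbind(di, ai)], 0)),
    angle = ang[keep])
}

# restrict site tables to a residue selection and/or water set
.sites_for <- function(fs, sites, chain_id = NULL, residue_id = NULL,
                       waters = FALSE) {
  pick <- function(tab) {
    keep <- rep(FALSE, nrow(tab))
    if (!is.null(residue_id))
      keep <- keep | (tab$residue_id %in% residue_id &
                      (is.null(chain_id) | tab$chain_id %in% chain_id))
    if (waters) keep <- keep | tab$residue_id %in% fs$water_ids
    tab[keep, , drop = FALSE]
  }
  list(donors = pick(sites$donors), acceptors = pick(sites$acceptors))
}

# per-frame count of residue--water hydrogen bonds for one residue,
# vectorised across frames: loop over the (donor-H, acceptor) combinations
# that can link the residue to a water, compute all frame distances at
# once, and evaluate angles only where the distance cutoff passes.
.residue_water_bonds <- function(fs, chain_id, residue_id, criterion,
                                 sites, waters) {
  nt <- n_frames(fs)
  counts <- integer(nt)
  don <- sites$donors; acc <- sites$acceptors
  if (nrow(don) == 0L || nrow(acc) == 0L) return(counts)
  is_target_d <- don$residue_id %in% residue_id & don$chain_id %in% chain_id
  is_target_a <- acc$residue_id %in% residue_id & acc$chain_id %in% chain_id
  is_water_d <- don$residue_id %in% waters & !(don$residue_id %in% residue_id)
  is_water_a <- acc$residue_id %in% waters & !(acc$residue_id %in% residue_id)
  combos <- rbind(
    expand.grid(d = which(is_target_d), a = which(is_water_a)),
    expand.grid(d = which(is_water_d), a = which(is_target_a)))
  if (nrow(combos) == 0L) return(counts)
  cut2 <- criterion$max_da_distance^2 + 1e-12
  min_ang <- 180 - criterion$max_deviation - 1e-9
  for (i in seq_len(nrow(combos))) {
    di <- combos$d[i]; ai <- combos$a[i]
    dxyz <- fs$coords[don$d_idx[di], , ]   # 3 x nt
    axyz <- fs$coords[acc$a_idx[ai], , ]
    if (nt == 1L) { dxyz <- matrix(dxyz, 3); axyz <- matrix(axyz, 3) }
    d2 <- colSums((dxyz - axyz)^2)
    cand <- which(d2 <= cut2)
    if (length(cand) == 0L) next
    hxyz <- fs$coords[don$h_idx[di], , cand, drop = FALSE]
    hxyz <- matrix(hxyz, nrow = 3)
    v1 <- dxyz[, cand, drop = FALSE] - hxyz
    v2 <- axyz[, cand, drop = FALSE] - hxyz
    cosang <- colSums(v1 * v2) / (sqrt(colSums(v1^2)) * sqrt(colSums(v2^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    hit <- cand[ang >= min_ang]
    counts[hit] <- counts[hit] + 1L
  }
  counts
}

#' Mean residue-water hydrogen-bond counts
#'
#' Per-frame counts of hydrogen bonds between each selected residue and any
#' water (bonds, not distinct partners: a doubly-bonded water counts
#' twice), averaged within each replica and then across replicas with the
#' standard error of the replica means. A hydronium particle may be listed
#' as a residue; it is then excluded from the water side of its own counts.
#'
#' @param replicas a `frame_series` or list of them
#' @param residues data frame with columns `chain_id`, `residue_id` and
#'   optional `label`
#' @param criterion an [hbond_criterion()]
#' @return data frame: label, mean, se, plus one column per replica
#' @export
mean_hbond_counts <- function(replicas, residues,
                              criterion = hbond_criterion()) {
  replicas <- as_replica_list(replicas)
  lab <- if ("label" %in% names(residues)) residues$label
         else paste0(residues$chain_id, ":", residues$residue_id)
  per <- matrix(NA_real_, nrow(residues), length(replicas))
  for (r in seq_along(replicas)) {
    fs <- replicas[[r]]
    sites <- hbond_sites(fs)
    waters <- unique(c(fs$water_ids, fs$hydronium_id))
    for (i in seq_len(nrow(residues))) {
      cnt <- .residue_water_bonds(fs, residues$chain_id[i],
                                  residues$residue_id[i], criterion, sites,
                                  waters)
      per[i, r] <- mean(cnt)
    }
  }
  se <- if (length(replicas) > 1) apply(per, 1, stats::sd) / sqrt(length(replicas))
        else rep(0, nrow(residues))
  out <- data.frame(label = lab, mean = rowMeans(per), se = se)
  colnames(per) <- paste0("replica", seq_along(replicas))
  cbind(out, per)
}

#' Any-water bond presence series of a residue
#'
#' The binary indicator h(t): 1 iff the residue has at least one hydrogen
#' bond to any water (or the hydronium) in frame t, irrespective of water
#' identity and of which atoms form the bond.
#'
#' @param fs a `frame_series`
#' @param chain_id,residue_id the residue
#' @param criterion an [hbond_criterion()]
#' @param partner_ids residue ids counted as the "water" side (default: the
#'   flagged waters plus the hydronium)
#' @return logical vector with one element per frame
#' @export
bond_presence_series <- function(fs, chain_id, residue_id,
                                 criterion = hbond_criterion(),
                                 partner_ids = NULL) {
  sites <- hbond_sites(fs)
  if (is.null(partner_ids))
    partner_ids <- unique(c(fs$water_ids, fs$hydronium_id))
  cnt <- .residue_water_bonds(fs, chain_id, residue_id, criterion, sites,
                              partner_ids)
  cnt > 0
}

#' Continuous any-water survival curve
#'
#' C(tau): the probability that a residue bonded to some water at a time
#' origin remains bonded to some water at every frame through `t0 + tau`
#' (continuous survival; the partner water and the bonding atoms may
#' change). Time origins are spaced `origin_spacing` ps apart so that with
#' the default maximal lag of 100 ps the correlation windows do not
#' overlap; C is the fraction of bonded origins that survive each lag.
#'
#' @param h binary bond-presence series (from [bond_presence_series()]), or
#'   a `frame_series` (then `chain_id`/`residue_id`/`criterion` are used to
#'   compute it)
#' @param dt frame spacing in ps (taken from the `frame_series` if given)
#' @param max_lag maximal lag, ps (default 100)
#' @param origin_spacing spacing between time origins, ps (default 120);
#'   must exceed `max_lag`
#' @param chain_id,residue_id,criterion,partner_ids used when `h` is a
#'   `frame_series` (see [bond_presence_series()])
#' @return object of class `survival_curve`: data frame `curve` (lag, c),
#'   `n_origins` (bonded origins used), and `defined` flag (FALSE when no
#'   origin was bonded)
#' @export
survival_curve <- function(h, dt = NULL, max_lag = 100, origin_spacing = 120,
                           chain_id = NULL, residue_id = NULL,
                           criterion = hbond_criterion(),
                           partner_ids = NULL) {
  if (inherits(h, "frame_series")) {
    dt <- h$dt
    h <- bond_presence_series(h, chain_id, residue_id, criterion,
                              partner_ids)
  }
  stopifnot(!is.null(dt), dt > 0)
  if (origin_spacing <= max_lag)
    stop("origin_spacing must exceed max_lag (non-overlapping windows)")
  h <- as.logical(h)
  nt <- length(h)
  kmax <- floor(max_lag / dt)
  if (nt <= kmax) stop("series shorter than the maximal lag")
  # remaining TRUE-run length starting at each frame
  r <- rle(h)
  runlen <- unlist(lapply(seq_along(r$lengths), function(i)
    if (r$values[i]) rev(seq_len(r$lengths[i])) else rep(0L, r$lengths[i])),
    use.names = FALSE)
  spacing <- max(1L, as.integer(round(origin_spacing / dt)))
  origins <- seq.int(1L, nt - kmax, by = spacing)
  bonded <- origins[h[origins]]
  lags <- (0:kmax) * dt
  if (length(bonded) == 0L) {
    return(structure(list(curve = data.frame(lag = lags, c = NA_real_),
                          n_origins = 0L, defined = FALSE, dt = dt),
                     class = "survival_curve"))
  }
  cc <- vapply(0:kmax, function(k) mean(runlen[bonded] >= k + 1L),
               numeric(1))
  structure(list(curve = data.frame(lag = lags, c = cc),
                 n_origins = length(bonded), defined = TRUE, dt = dt),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  if (!x$defined) {
    cat("survival_curve: undefined (no bonded time origins)\n")
  } else {
    cat("survival_curve:", nrow(x$curve), "lags,", x$n_origins,
        "bonded origins, C(max lag) =",
        signif(x$curve$c[nrow(x$curve)], 4), "\n")
  }
  invisible(x)
}

#' Bi-exponential fit of a survival curve
#'
#' Fits C(t) = A exp(-t/tau1) + B exp(-t/tau2) with the constraints
#' A + B = 1, A in [0, 1] and tau1, tau2 > 0, by bounded least squares with
#' a multi-start grid (the surface is multimodal). Time constants are
#' additionally capped at 10 times the longest sampled lag: slower
#' processes are not identifiable from the curve and would otherwise let a
#' vanishing tail amplitude dominate the weighted lifetime. Parameters are
#' reported with tau1 <= tau2; the hydrogen-bond lifetime is the weighted
#' sum A tau1 + B tau2.
#'
#' @param curve a `survival_curve`, or a data frame with columns `lag`, `c`
#' @param starts optional data frame of starting values (columns `A`,
#'   `tau1`, `tau2`); defaults to the grid tau1 in \{2, 10\}, tau2 in
#'   \{50, 200\}, A in \{0.3, 0.7\}
#' @return object of class `biexp_fit`: `A`, `B`, `tau1`, `tau2`,
#'   `lifetime` (ps), `rss`, `valid`
#' @export
fit_biexponential <- function(curve, starts = NULL) {
  df <- if (inherits(curve, "survival_curve")) curve$curve else curve
  df <- df[!is.na(df$c), , drop = FALSE]
  if (nrow(df) < 5L) stop("need at least 5 lag points to fit")
  if (inherits(curve, "survival_curve") && !curve$defined)
    return(structure(list(A = NA, B = NA, tau1 = NA, tau2 = NA,
                          lifetime = NA, rss = NA, valid = FALSE),
                     class = "biexp_fit"))
  if (is.null(starts))
    starts <- expand.grid(A = c(0.3, 0.7), tau1 = c(2, 10),
                          tau2 = c(50, 200))
  t <- df$lag; y <- df$c
  tau_max <- 10 * max(t)
  starts$tau1 <- pmin(starts$tau1, tau_max)
  starts$tau2 <- pmin(starts$tau2, tau_max)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * exp(-t / tau1) + (1 - A) * exp(-t / tau2),
        start = list(A = starts$A[i], tau1 = starts$tau1[i],
                     tau2 = starts$tau2[i]),
        lower = c(A = 0, tau1 = 1e-6, tau2 = 1e-6),
        upper = c(A = 1, tau1 = tau_max, tau2 = tau_max),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = stats::coef(fit), rss = rss)
  }
  if (is.null(best)) {
    # fall back to direct bounded optimisation from the same grid
    obj <- function(p) {
      A <- stats::plogis(p[1])
      t1 <- min(exp(p[2]), tau_max); t2 <- min(exp(p[3]), tau_max)
      sum((A * exp(-t / t1) + (1 - A) * exp(-t / t2) - y)^2)
    }
    for (i in seq_len(nrow(starts))) {
      o <- tryCatch(stats::optim(c(stats::qlogis(starts$A[i]),
                                   log(starts$tau1[i]), log(starts$tau2[i])),
                                 obj, control = list(maxit = 2000)),
                    error = function(e) NULL)
      if (is.null(o)) next
      par <- c(A = stats::plogis(o$par[1]), tau1 = exp(o$par[2]),
               tau2 = exp(o$par[3]))
      if (is.null(best) || o$value < best$rss)
        best <- list(par = par, rss = o$value)
    }
  }
  if (is.null(best))
    return(structure(list(A = NA, B = NA, tau1 = NA, tau2 = NA,
                          lifetime = NA, rss = NA, valid = FALSE),
                     class = "biexp_fit"))
  A <- unname(best$par["A"]); t1 <- unname(best$par["tau1"])
  t2 <- unname(best$par["tau2"])
  if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp; A <- 1 - A }
  structure(list(A = A, B = 1 - A, tau1 = t1, tau2 = t2,
                 lifetime = A * t1 + (1 - A) * t2, rss = best$rss,
                 valid = TRUE),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  if (!x$valid) { cat("biexp_fit: invalid (not converged)\n"); return(invisible(x)) }
  cat(sprintf(
    "biexp_fit: A = %.3f (tau1 = %.2f ps), B = %.3f (tau2 = %.2f ps)\n",
    x$A, x$tau1, x$B, x$tau2))
  cat(sprintf("  weighted lifetime = %.2f ps (rss %.3g)\n", x$lifetime,
              x$rss))
  invisible(x)
}

#' Replica-averaged hydrogen-bond lifetime
#'
#' Averages per-replica weighted lifetimes with the standard error of the
#' mean. Following the reporting convention for poorly determined
#' lifetimes, a value whose standard error exceeds the mean is reported as
#' not available (`reported = NA`).
#'
#' @param lifetimes numeric vector of per-replica weighted lifetimes (ps),
#'   or a list of `biexp_fit` objects (invalid fits are dropped)
#' @return list with `mean`, `se`, `reported` (NA when SE > mean or no
#'   valid replica), `n`
#' @export
lifetime_summary <- function(lifetimes) {
  if (is.list(lifetimes) && all(vapply(lifetimes, inherits, logical(1),
                                       "biexp_fit")))
    lifetimes <- vapply(lifetimes, function(f)
      if (isTRUE(f$valid)) f$lifetime else NA_real_, numeric(1))
  lifetimes <- lifetimes[!is.na(lifetimes)]
  if (length(lifetimes) == 0L)
    return(list(mean = NA_real_, se = NA_real_, reported = NA_real_, n = 0L))
  st <- replica_mean_se(lifetimes)
  reported <- if (st$n > 1 && st$se > st$mean) NA_real_ else st$mean
  list(mean = st$mean, se = st$se, reported = reported, n = st$n)
}
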