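#' Run the full channel-analysis pipeline
#'
#' Executes every analysis stage per replica and replica-averages the
#' results: channel polyhedra and hydration summary, slice occupancy and
#' cumulative profiles, 2D occupancy projection, slice-resolved diffusion,
#' residue-water hydrogen-bond counts and survival lifetimes, the
#' water-mediated connection network, and conformational statistics.
#' All tables are written as CSV (plus a JSON run summary) to `out_dir`;
#' outputs are a pure function of the configuration and seed, so a rerun
#' with the same inputs is byte-identical.
#'
#' Configuration fields (YAML file via [read_run_config()] or a list via
#' [as_run_config()]):
#' \describe{
#'   \item{synthetic}{generator settings passed to
#'     [synthetic_channel_spec()], plus `n_replicas` (default 3)}
#'   \item{files}{`topology`, `trajectories` (list of DCD path vectors,
#'     one per replica), `dt`, `stride`}
#'   \item{seed}{base RNG seed}
#'   \item{equilibration_fraction}{leading fraction of frames discarded
#'     (default 0.2)}
#'   \item{median_window_ps}{window from the start of the analysed span
#'     used to locate the median structure (default 10000 ps)}
#'   \item{corners, axis}{residue selections for the polyhedron corners and
#'     the cylinder axis ends (defaults fit the synthetic scaffold)}
#'   \item{cylinder, hbond, lifetime}{geometry / criterion / protocol
#'     parameters}
#'   \item{analysis_residues}{residues for hydrogen-bond counts, lifetimes
#'     and the connection network}
#'   \item{distance_pairs, chi_residues}{conformational analyses}
#' }
#'
#' @param config a `run_config` (or plain list, coerced)
#' @param out_dir output directory (created if missing)
#' @return invisibly, a list with all result objects
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    s <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[hydrochan] %-18s %6.2f s", name,
                    as.numeric(difftime(Sys.time(), s, units = "secs"))))
    res
  }
  set.seed(config$seed)

  replicas <- stage("load", {
    if (!is.null(config$synthetic)) {
      sy <- config$synthetic
      n_rep <- if (is.null(sy$n_replicas)) 3L else sy$n_replicas
      sy$n_replicas <- NULL
      sy$seed <- config$seed
      hp <- sy$hbond_pairs
      if (!is.null(hp) && !is.data.frame(hp))
        sy$hbond_pairs <- do.call(rbind, lapply(hp, as.data.frame))
      mk <- sy$markers
      if (!is.null(mk) && !is.data.frame(mk))
        sy$markers <- do.call(rbind, lapply(mk, as.data.frame))
      if (!is.null(sy$box)) sy$box <- as.numeric(sy$box)
      spec <- do.call(synthetic_channel_spec, sy)
      simulate_replicas(spec, n_rep)
    } else {
      fl <- config$files
      lapply(fl$trajectories, function(tr)
        load_trajectory(fl$topology, unlist(tr),
                        dt = if (is.null(fl$dt)) 2 else fl$dt,
                        stride = if (is.null(fl$stride)) 1 else fl$stride))
    }
  })

  replicas <- stage("equilibration", {
    lapply(replicas, function(fs) {
      drop <- floor(config$equilibration_fraction * n_frames(fs))
      if (drop > 0 && drop < n_frames(fs))
        subset_frames(fs, (drop + 1):n_frames(fs)) else fs
    })
  })
  fs1 <- replicas[[1]]

  sel_df <- function(x) {   # one selection or a list of selections
    if (is.null(x)) return(NULL)
    if (is.data.frame(x)) return(x)
    if (!is.null(names(x)) && !is.list(x[[1]])) x <- list(x)
    do.call(rbind, lapply(x, as.data.frame))
  }
  corners <- if (!is.null(config$corners)) sel_df(config$corners)
  else data.frame(chain_id = "S", residue_id = 1:8)   # synthetic scaffold
  axis_bottom <- if (!is.null(config$axis$bottom)) sel_df(config$axis$bottom)
  else data.frame(chain_id = "S", residue_id = 11L)
  axis_top <- if (!is.null(config$axis$top)) sel_df(config$axis$top)
  else data.frame(chain_id = "S", residue_id = 12L)

  geom <- stage("geometry", {
    cylp <- config$cylinder
    lapply(replicas, function(fs) {
      win <- seq_len(min(n_frames(fs),
                         max(1, floor(config$median_window_ps / fs$dt))))
      med <- find_median_frame(fs, win)
      cyl <- build_cylinder(fs, med, axis_bottom, axis_top,
                            radius = cylp$radius, n_slices = cylp$n_slices,
                            slice_thickness = cylp$slice_thickness,
                            ring_bounds = cylp$ring_bounds,
                            segment_width = cylp$segment_width)
      polys <- channel_polyhedra(fs, corners)
      list(median_frame = med, cyl = cyl, polys = polys)
    })
  })
  cyls <- lapply(geom, `[[`, "cyl")
  polys_list <- lapply(geom, `[[`, "polys")

  visited <- stage("track_waters", {
    sort(unique(unlist(lapply(seq_along(replicas), function(i)
      track_channel_waters(replicas[[i]], polys_list[[i]])))))
  })

  hyd <- stage("hydration", {
    hs <- hydration_summary(replicas, polys_list, cyls, water_ids = visited)
    prof <- occupancy_profile(replicas, cyls, water_ids = visited)
    proj <- occupancy_projection(replicas, cyls, bin = config$projection_bin,
                                 water_ids = visited)
    list(summary = hs, profile = prof, cumulative = cumulative_profile(prof),
         projection = proj)
  })

  mob <- stage("mobility", {
    msds <- lapply(seq_along(replicas), function(i)
      slice_msd(replicas[[i]], cyls[[i]], water_ids = visited))
    diffusion_profile(msds)
  })

  crit <- hbond_criterion(config$hbond$max_da_distance,
                          config$hbond$max_deviation)
  res_sel <- if (!is.null(config$analysis_residues))
    sel_df(config$analysis_residues)
  else {
    don <- unique(fs1$atoms$residue_id[fs1$atoms$residue_name == "DON"])
    if (length(don))
      data.frame(chain_id = "D", residue_id = don,
                 label = paste0("D:", don))
    else NULL
  }

  # synthetic acceptor pseudo-residues count as bond partners alongside
  # the waters, so donor/acceptor fixtures yield defined survival curves
  acc_ids <- unique(fs1$atoms$residue_id[fs1$atoms$residue_name == "ACC"])
  partner_ids <- unique(c(fs1$water_ids, fs1$hydronium_id, acc_ids))

  hb <- stage("hbonds", if (is.null(res_sel)) NULL else {
    counts <- mean_hbond_counts(replicas, res_sel, crit)
    curves <- list(); fits <- list(); lt <- list()
    for (i in seq_len(nrow(res_sel))) {
      lab <- counts$label[i]
      per_rep <- lapply(replicas, function(fs)
        survival_curve(fs, max_lag = config$lifetime$max_lag,
                       origin_spacing = config$lifetime$origin_spacing,
                       chain_id = res_sel$chain_id[i],
                       residue_id = res_sel$residue_id[i], criterion = crit,
                       partner_ids = partner_ids))
      curves[[lab]] <- per_rep
      fits[[lab]] <- lapply(per_rep, function(sc)
        if (sc$defined && nrow(sc$curve) >= 5) fit_biexponential(sc)
        else structure(list(A = NA, B = NA, tau1 = NA, tau2 = NA,
                            lifetime = NA, rss = NA, valid = FALSE),
                       class = "biexp_fit"))
      lt[[lab]] <- lifetime_summary(fits[[lab]])
    }
    list(counts = counts, curves = curves, fits = fits, lifetimes = lt)
  })

  net <- stage("network", {
    if (is.null(res_sel) || nrow(res_sel) < 2) NULL
    else connection_probabilities(replicas, res_sel, crit)
  })

  conf <- stage("conformers", {
    out <- list()
    if (!is.null(config$distance_pairs)) {
      out$distances <- lapply(config$distance_pairs, function(p)
        residue_distances(replicas, as.data.frame(p$a), as.data.frame(p$b),
                          convention = if (is.null(p$convention)) "CA"
                                       else p$convention))
    }
    if (!is.null(config$chi_residues)) {
      out$chi <- lapply(config$chi_residues, function(r)
        chi_distributions(replicas, r$chain_id, r$residue_id))
    }
    out
  })

  stage("write", {
    w <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                          row.names = FALSE)
    hs <- hyd$summary
    w(data.frame(
        quantity = c("waters_polyhedron", "waters_cylinder", "volume_nm3"),
        mean = c(hs$mean_waters_polyhedron, hs$mean_waters_cylinder,
                 hs$mean_volume),
        se = c(hs$se_waters_polyhedron, hs$se_waters_cylinder,
               hs$se_volume)), "hydration_summary.csv")
    w(hyd$profile$profile, "occupancy_profile.csv")
    w(hyd$cumulative, "cumulative_profile.csv")
    pj <- hyd$projection
    hmid <- (pj$height_edges[-1] + pj$height_edges[-length(pj$height_edges)]) / 2
    dmid <- (pj$inplane_edges[-1] + pj$inplane_edges[-length(pj$inplane_edges)]) / 2
    w(data.frame(height = rep(hmid, times = length(dmid)),
                 inplane = rep(dmid, each = length(hmid)),
                 density = as.vector(pj$counts)), "occupancy_projection.csv")
    w(mob$profile, "diffusion_profile.csv")
    if (!is.null(hb)) {
      w(hb$counts, "hbond_counts.csv")
      sc_rows <- list()
      for (lab in names(hb$curves))
        for (r in seq_along(hb$curves[[lab]])) {
          cv <- hb$curves[[lab]][[r]]$curve
          sc_rows[[length(sc_rows) + 1L]] <-
            data.frame(residue = lab, replica = r, lag = cv$lag, c = cv$c)
        }
      w(do.call(rbind, sc_rows), "survival_curves.csv")
      lt_rows <- lapply(names(hb$lifetimes), function(lab) {
        l <- hb$lifetimes[[lab]]
        data.frame(residue = lab, mean = l$mean, se = l$se,
                   reported = l$reported, n = l$n)
      })
      w(do.call(rbind, lt_rows), "lifetimes.csv")
    }
    if (!is.null(net)) w(connection_edges(net), "connection_network.csv")
    if (!is.null(conf$distances)) {
      w(do.call(rbind, lapply(conf$distances, function(d)
        data.frame(pair = d$pair, convention = d$convention, mean = d$mean,
                   se = d$se))), "distances.csv")
    }
    if (!is.null(conf$chi)) {
      rows <- list()
      for (cd in conf$chi)
        for (chi in names(cd$chis))
          rows[[length(rows) + 1L]] <- data.frame(
            residue = paste0(cd$chain_id, ":", cd$residue_id), chi = chi,
            mid = cd$chis[[chi]]$histogram$mid,
            density = cd$chis[[chi]]$histogram$density)
      w(do.call(rbind, rows), "chi_histograms.csv")
    }
    jsonlite::write_json(
      list(seed = config$seed, n_replicas = length(replicas),
           n_frames_analysed = vapply(replicas, n_frames, integer(1)),
           n_waters_visited = length(visited),
           median_frames = vapply(geom, `[[`, integer(1), "median_frame")),
      file.path(out_dir, "run_info.json"), auto_unbox = TRUE, digits = NA)
    NULL
  })
  message(sprintf("[hydrochan] pipeline done in %.1f s",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(replicas = replicas, cylinders = cyls,
                 visited_waters = visited, hydration = hyd, mobility = mob,
                 hbonds = hb, network = net, conformation = conf))
}
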