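#' Per-frame hydrogen-bond graph
#'
#' Builds the simple undirected graph whose nodes are residues, waters and
#' the hydronium, and whose edges are the hydrogen bonds of one frame;
#' multiple bonds between the same pair collapse to a single edge.
#'
#' @param bonds a bond table from [detect_hbonds()] (columns `donor_res`,
#'   `acceptor_res`), or any two-column data frame of node labels
#' @param nodes optional character vector of node labels that must be
#'   present even when isolated (e.g. the analysis residues)
#' @return an `igraph` graph
#' @export
build_hbond_graph <- function(bonds, nodes = NULL) {
  if (nrow(bonds) > 0) {
    if (all(c("donor_res", "acceptor_res") %in% names(bonds)))
      el <- cbind(bonds$donor_res, bonds$acceptor_res)
    else
      el <- cbind(as.character(bonds[[1]]), as.character(bonds[[2]]))
  } else el <- matrix(character(), 0, 2)
  verts <- unique(c(nodes, as.vector(el)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  missing <- setdiff(verts, igraph::V(g)$name)
  if (length(missing)) g <- igraph::add_vertices(g, length(missing),
                                                 name = missing)
  igraph::simplify(g)
}

#' Are two residues hydrogen-bond connected?
#'
#' TRUE iff a path of hydrogen bonds (possibly through waters) links the
#' two residues in the frame graph; a direct residue-residue bond is a path
#' of length one. The search is a shortest-path (Dijkstra) query with unit
#' edge weights.
#'
#' @param graph an `igraph` graph from [build_hbond_graph()]
#' @param res_a,res_b node labels of the two residues
#' @return logical
#' @export
residues_connected <- function(graph, res_a, res_b) {
  vn <- igraph::V(graph)$name
  if (!(res_a %in% vn)) stop("unknown residue node: ", res_a)
  if (!(res_b %in% vn)) stop("unknown residue node: ", res_b)
  if (res_a == res_b) return(TRUE)
  d <- igraph::distances(graph, v = res_a, to = res_b,
                         weights = rep(1, igraph::ecount(graph)),
                         algorithm = "dijkstra")
  is.finite(d[1, 1])
}

#' Water-mediated residue connection probabilities
#'
#' For each frame, builds the hydrogen-bond graph and checks every residue
#' pair for a (possibly water-mediated) connection; the per-pair
#' probability is the fraction of connected frames, averaged across
#' replicas with the standard error of the replica means. The matrix is
#' symmetric with diagonal 1 by convention.
#'
#' @param x per-replica input: a `frame_series` or list of them (bonds are
#'   detected with `criterion`), or a list of per-frame bond tables, or a
#'   list of replicas each being a list of per-frame bond tables
#' @param residues character vector of residue node labels (e.g. "A:362"),
#'   or a data frame with `chain_id`/`residue_id` (labels are formed as
#'   "chain:resid")
#' @param criterion an [hbond_criterion()] (used for `frame_series` input)
#' @return object of class `connection_network`: `probability` and `se`
#'   matrices, `per_replica` array, `residues`
#' @export
connection_probabilities <- function(x, residues,
                                     criterion = hbond_criterion()) {
  if (is.data.frame(residues))
    residues <- paste0(residues$chain_id, ":", residues$residue_id)
  # normalise input to a list of replicas of per-frame bond tables
  if (inherits(x, "frame_series")) x <- list(x)
  stopifnot(is.list(x), length(x) >= 1)
  frames_of <- function(rep) {
    if (inherits(rep, "frame_series")) {
      sites <- hbond_sites(rep)
      lapply(seq_len(n_frames(rep)), function(f)
        detect_hbonds(rep, f, criterion, sites))
    } else if (is.data.frame(rep)) list(rep) else rep
  }
  np <- length(residues)
  per <- array(NA_real_, c(np, np, length(x)))
  for (r in seq_along(x)) {
    frames <- frames_of(x[[r]])
    conn <- matrix(0, np, np)
    for (b in frames) {
      g <- build_hbond_graph(b, nodes = residues)
      for (i in seq_len(np - 1)) for (j in (i + 1):np) {
        if (residues_connected(g, residues[i], residues[j]))
          conn[i, j] <- conn[i, j] + 1
      }
    }
    conn <- conn / length(frames)
    conn <- conn + t(conn)
    diag(conn) <- 1
    per[, , r] <- conn
  }
  prob <- apply(per, c(1, 2), mean)
  se <- if (length(x) > 1) apply(per, c(1, 2), stats::sd) / sqrt(length(x))
        else matrix(0, np, np)
  dimnames(prob) <- dimnames(se) <- list(residues, residues)
  structure(list(probability = prob, se = se, per_replica = per,
                 residues = residues, n_replicas = length(x)),
            class = "connection_network")
}

#' @export
print.connection_network <- function(x, ...) {
  cat("connection_network:", length(x$residues), "residues,",
      x$n_replicas, "replica(s)\n")
  print(round(x$probability, 3))
  invisible(x)
}

#' Edge list of a connection network
#'
#' @param net a `connection_network`
#' @return data frame `res_a`, `res_b`, `probability`, `se` (upper
#'   triangle), ready for network drawing
#' @export
connection_edges <- function(net) {
  stopifnot(inherits(net, "connection_network"))
  np <- length(net$residues)
  out <- list()
  for (i in seq_len(np - 1)) for (j in (i + 1):np)
    out[[length(out) + 1L]] <- data.frame(
      res_a = net$residues[i], res_b = net$residues[j],
      probability = net$probability[i, j], se = net$se[i, j])
  do.call(rbind, out)
}
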