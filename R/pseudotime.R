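## Centroid-MST trajectory inference over the embedding: minimum spanning
## tree over cluster centroids with forced terminal leaves, orthogonal edge
## projection of observations, per-path and common pseudotime, and
## treatment-density along a chosen path.

#' Build the terminal-forced centroid MST
#'
#' Computes cluster centroids in the embedding, builds the
#' Euclidean-weighted minimum spanning tree over the non-terminal centroids,
#' then attaches every designated terminal cluster as a leaf to its nearest
#' non-terminal centroid. This guarantees that terminal states (e.g.
#' resistant, sensitive, invasive clusters) end paths regardless of where
#' the unconstrained MST would have placed them.
#'
#' @param labels integer cluster labels per observation.
#' @param coords n x 2 embedding coordinates.
#' @param terminals cluster ids forced to be leaves (may be empty).
#' @return a [TrajectoryModel-class] with topology slots filled.
#' @export
centroidMST <- function(labels, coords, terminals = integer()) {
  ids <- sort(unique(labels))
  C <- length(ids)
  if (C < 2L) {
    .orgscreenError("need at least 2 clusters for a trajectory",
                    "orgscreen_data_error")
  }
  terminals <- as.integer(terminals)
  if (!all(terminals %in% ids)) {
    .orgscreenError("terminals must be existing cluster ids",
                    "orgscreen_data_error")
  }
  if (length(setdiff(ids, terminals)) == 0L) {
    .orgscreenError("all clusters designated terminal: no backbone remains",
                    "orgscreen_data_error")
  }
  cent <- t(vapply(ids, function(cid) {
    colMeans(coords[labels == cid, , drop = FALSE])
  }, numeric(2)))
  rownames(cent) <- ids
  nonterm <- setdiff(ids, terminals)
  edges <- NULL
  if (length(nonterm) >= 2L) {
    idx <- match(nonterm, ids)
    dm <- as.matrix(dist(cent[idx, , drop = FALSE]))
    full <- igraph::graph_from_adjacency_matrix(dm, mode = "undirected",
                                                weighted = TRUE)
    tree <- igraph::mst(full, weights = igraph::E(full)$weight)
    el <- igraph::as_edgelist(tree)  # vertex names are the cluster ids
    edges <- data.frame(
      from = as.integer(el[, 1L]),
      to = as.integer(el[, 2L]),
      length = igraph::E(tree)$weight
    )
  }
  for (tm in terminals) {
    d <- sqrt(colSums((t(cent[match(nonterm, ids), , drop = FALSE]) -
                         cent[match(tm, ids), ])^2))
    near <- nonterm[which.min(d)]
    edges <- rbind(edges,
                   data.frame(from = near, to = tm, length = min(d)))
  }
  edges <- edges[order(edges$length, edges$from, edges$to), ]
  edges$edge_id <- seq_len(nrow(edges))
  rownames(edges) <- NULL
  new("TrajectoryModel", centroids = cent,
      edges = edges[c("edge_id", "from", "to", "length")],
      terminals = terminals)
}

#' Project observations onto the MST
#'
#' Maps each observation to the closest MST edge by orthogonal projection
#' clamped to the edge's endpoints; ties are broken deterministically by
#' the lowest edge id.
#'
#' @param coords n x 2 embedding coordinates.
#' @param model a [TrajectoryModel-class] from [centroidMST()].
#' @return the model with the `projections` slot filled (`edge_id`, `t`
#'   position along the edge from its `from` endpoint in [0, 1], `dist`).
#' @export
projectToMST <- function(coords, model) {
  edges <- model@edges
  cent <- model@centroids
  ids <- as.integer(rownames(cent))
  n <- nrow(coords)
  best_d <- rep(Inf, n)
  best_e <- rep(NA_integer_, n)
  best_t <- rep(NA_real_, n)
  for (i in seq_len(nrow(edges))) {
    a <- cent[match(edges$from[i], ids), ]
    b <- cent[match(edges$to[i], ids), ]
    ab <- b - a
    len2 <- sum(ab^2)
    tt <- if (len2 == 0) rep(0, n) else
      pmin(pmax(((coords[, 1L] - a[1L]) * ab[1L] +
                   (coords[, 2L] - a[2L]) * ab[2L]) / len2, 0), 1)
    dx <- coords[, 1L] - (a[1L] + tt * ab[1L])
    dy <- coords[, 2L] - (a[2L] + tt * ab[2L])
    d <- sqrt(dx^2 + dy^2)
    upd <- d < best_d - 1e-12
    best_d[upd] <- d[upd]
    best_e[upd] <- edges$edge_id[i]
    best_t[upd] <- tt[upd]
  }
  model@projections <- data.frame(edge_id = best_e, t = best_t,
                                  dist = best_d)
  validObject(model)
  model
}

#' Per-path and common pseudotime
#'
#' Enumerates every root-to-leaf path of the MST, assigns each observation
#' projecting onto a path edge the distance from the root centroid along
#' the path to its projection, leaves observations on off-path edges
#' undefined for that path, and averages over the defined paths into the
#' common pseudotime. Every MST edge belongs to at least one root-to-leaf
#' path, so the common pseudotime is defined for every observation.
#'
#' @param model a projected [TrajectoryModel-class] (see [projectToMST()]).
#' @param root root cluster id, typically the baseline-enriched cluster
#'   from [clusterProfiles()].
#' @return the model with `root`, `paths`, `pseudotimePaths` (observations
#'   x paths, NA off-path) and `commonPseudotime` filled.
#' @export
pseudotimeVectors <- function(model, root) {
  edges <- model@edges
  if (!nrow(model@projections)) {
    .orgscreenError("call projectToMST() before pseudotimeVectors()",
                    "orgscreen_data_error")
  }
  root <- as.integer(root)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$from), to = as.character(edges$to),
               weight = edges$length),
    directed = FALSE,
    vertices = data.frame(name = as.character(as.integer(rownames(model@centroids))))
  )
  stopifnot(igraph::is_connected(g))
  degs <- igraph::degree(g)
  leaves <- setdiff(names(degs)[degs == 1L], as.character(root))
  if (!length(leaves)) {
    .orgscreenError("root has no leaf to path to", "orgscreen_data_error")
  }
  proj <- model@projections
  n <- nrow(proj)
  paths <- list()
  ptm <- matrix(NA_real_, n, length(leaves))
  for (pi in seq_along(leaves)) {
    vp <- igraph::shortest_paths(g, from = as.character(root),
                                 to = leaves[pi],
                                 weights = igraph::E(g)$weight)$vpath[[1L]]
    vseq <- as.integer(names(vp))
    paths[[pi]] <- vseq
    cum <- 0
    for (s in seq_len(length(vseq) - 1L)) {
      u <- vseq[s]; v <- vseq[s + 1L]
      ei <- which((edges$from == u & edges$to == v) |
                    (edges$from == v & edges$to == u))
      len <- edges$length[ei]
      on_edge <- which(proj$edge_id == edges$edge_id[ei])
      if (length(on_edge)) {
        # orient position from the path-upstream endpoint
        tt <- proj$t[on_edge]
        if (edges$from[ei] != u) tt <- 1 - tt
        ptm[on_edge, pi] <- cum + tt * len
      }
      cum <- cum + len
    }
  }
  names(paths) <- vapply(paths, function(p) as.character(p[length(p)]),
                         character(1))
  colnames(ptm) <- names(paths)
  model@root <- root
  model@paths <- paths
  model@pseudotimePaths <- ptm
  model@commonPseudotime <- rowMeans(ptm, na.rm = TRUE)
  model
}

#' Common pseudotime accessor
#'
#' @param model a [TrajectoryModel-class] after [pseudotimeVectors()].
#' @return numeric pseudotime per observation.
#' @export
commonPseudotime <- function(model) model@commonPseudotime

#' MST edge table accessor
#'
#' @param model a [TrajectoryModel-class].
#' @return data.frame of edges (`edge_id`, `from`, `to`, `length`).
#' @export
mstEdges <- function(model) model@edges

#' Treatment-arm density along one trajectory path
#'
#' Restricts observations to those whose closest edge lies on the
#' root-to-terminal path, estimates a Gaussian kernel density of their path
#' pseudotime per treatment arm (shared bandwidth from the pooled
#' pseudotimes, standard reference rule), and reports each arm's mass on
#' the path: the fraction of the arm's observations projecting onto it.
#'
#' @param model a [TrajectoryModel-class] after [pseudotimeVectors()].
#' @param arm character/factor vector, one treatment-arm label per
#'   observation.
#' @param terminal cluster id of the path's terminal leaf.
#' @return list with `mass` (data.frame: arm, n_total, n_on_path, mass) and
#'   `density` (data.frame: arm, x, y; empty for arms with < 2 on-path
#'   observations, which are omitted with a warning).
#' @export
densityAlongPath <- function(model, arm, terminal) {
  key <- as.character(as.integer(terminal))
  if (!key %in% names(model@paths)) {
    .orgscreenError(sprintf("no root-to-leaf path ends at cluster %s", key),
                    "orgscreen_data_error")
  }
  pt <- model@pseudotimePaths[, key]
  arm <- as.character(arm)
  if (length(arm) != length(pt)) {
    .orgscreenError("arm labels must match the number of observations",
                    "orgscreen_data_error")
  }
  on_path <- !is.na(pt)
  pooled <- pt[on_path]
  bw <- if (length(pooled) >= 2L && sd(pooled) > 0)
    stats::bw.nrd0(pooled) else NULL
  mass_rows <- list()
  dens_rows <- list()
  for (a in unique(arm)) {
    sel <- arm == a
    n_on <- sum(sel & on_path)
    mass_rows[[a]] <- data.frame(arm = a, n_total = sum(sel),
                                 n_on_path = n_on,
                                 mass = n_on / sum(sel),
                                 stringsAsFactors = FALSE)
    if (n_on >= 2L && !is.null(bw) && sd(pt[sel & on_path]) >= 0) {
      d <- density(pt[sel & on_path], bw = bw)
      dens_rows[[a]] <- data.frame(arm = a, x = d$x, y = d$y,
                                   stringsAsFactors = FALSE)
    } else {
      warning(sprintf("arm '%s' has < 2 on-path observations; density omitted", a),
              call. = FALSE)
    }
  }
  list(mass = do.call(rbind, c(mass_rows, list(make.row.names = FALSE))),
       density = if (length(dens_rows)) do.call(rbind, dens_rows) else
         data.frame(arm = character(), x = numeric(), y = numeric()))
}
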