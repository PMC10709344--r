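## Population heterogeneity mapping: six-feature matrix, permutation-based
## informative-PC selection (parallel analysis), t-SNE, kNN-graph Louvain
## clustering, rank normalization and cluster characterization.

.FEATURE_COLS <- c("bf_area", "inv_area", "fa", "inv_fraction",
                   "brightness", "texture")

#' Assemble the standardized single-organoid feature matrix
#'
#' One row per organoid-timepoint observation, six feature columns (area,
#' invasive area, fraction affected, invasive fraction, brightness,
#' texture), centered and scaled to unit variance. Rows with missing
#' features are dropped and counted; constant columns are excluded with a
#' warning (they carry no variance for PCA).
#'
#' @param states data.frame from [organoidStates()].
#' @return list with `X` (standardized matrix), `meta` (data.frame of
#'   well/regimen/concentration/timepoint per retained row), `center`,
#'   `scale`, `dropped_rows` (count), `dropped_columns` (names).
#' @export
buildFeatureMatrix <- function(states) {
  feats <- states[.FEATURE_COLS]
  keep <- complete.cases(feats)
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message(sprintf("dropping %d row(s) with missing feature values", n_drop))
  }
  feats <- feats[keep, , drop = FALSE]
  meta <- states[keep, intersect(
    c("plate_id", "well", "organoid_id", "role", "regimen", "concentration",
      "time_h"), names(states)), drop = FALSE]
  X <- as.matrix(feats)
  const <- apply(X, 2L, sd) == 0
  if (any(const)) {
    warning(sprintf("excluding constant feature column(s): %s",
                    paste(colnames(X)[const], collapse = ", ")),
            call. = FALSE)
    X <- X[, !const, drop = FALSE]
  }
  sc <- .scaleColumns(X)
  list(X = sc$X, meta = meta, center = sc$center, scale = sc$scale,
       dropped_rows = n_drop,
       dropped_columns = colnames(feats)[const])
}

#' Select informative principal components by column permutation
#'
#' Parallel-analysis-style test: the observed percentage of variance
#' explained by each PC is compared against a null built by independently
#' permuting every column of the matrix, which destroys between-feature
#' correlation while preserving marginals. Permutation p-values
#' `p = (1 + #{null >= observed}) / (1 + n_perm)` are Holm-adjusted in
#' eigenvalue order and the retained set is the leading contiguous block of
#' significant PCs (retention stops at the first non-significant PC).
#'
#' @param X standardized feature matrix (rows = observations).
#' @param n_perm number of column permutations (default 1000; below 100 the
#'   p-value resolution is poor and a warning is given).
#' @param alpha significance level after Holm adjustment.
#' @param seed RNG seed for the permutations.
#' @return list with `n_retained`, `scores` (observations x retained PCs),
#'   `loadings`, `p_values`, `p_adjusted`, `var_explained`.
#' @export
selectInformativePCs <- function(X, n_perm = 1000L, alpha = 0.05,
                                 seed = 1L) {
  if (ncol(X) < 2L) {
    .orgscreenError("need at least 2 feature columns", "orgscreen_data_error")
  }
  if (nrow(X) < 10L) {
    .orgscreenError("need at least 10 observations for PC selection",
                    "orgscreen_data_error")
  }
  if (nrow(X) < ncol(X)) {
    .orgscreenError("fewer rows than features after filtering",
                    "orgscreen_data_error")
  }
  if (n_perm < 100L) {
    warning("fewer than 100 permutations gives coarse p-value resolution",
            call. = FALSE)
  }
  pc <- prcomp(X, center = FALSE, scale. = FALSE)
  obs_var <- pc$sdev^2 / sum(pc$sdev^2)
  n_pc <- length(obs_var)
  set.seed(seed)
  exceed <- integer(n_pc)
  for (b in seq_len(n_perm)) {
    Xp <- apply(X, 2L, sample)
    sv <- svd(Xp, nu = 0L, nv = 0L)$d
    null_var <- sv^2 / sum(sv^2)
    exceed <- exceed + (null_var >= obs_var)
  }
  p <- (1 + exceed) / (1 + n_perm)
  p_adj <- stats::p.adjust(p, method = "holm")
  sig <- p_adj < alpha
  n_ret <- if (!sig[1L]) 0L else which.max(c(!sig, TRUE)) - 1L
  list(n_retained = n_ret,
       scores = pc$x[, seq_len(n_ret), drop = FALSE],
       loadings = pc$rotation[, seq_len(n_ret), drop = FALSE],
       p_values = p, p_adjusted = p_adj, var_explained = obs_var)
}

#' t-SNE embedding with the square-root perplexity rule
#'
#' Embeds the retained PC scores (or the feature matrix itself) in two
#' dimensions with perplexity `floor(sqrt(n))`. When n is too small for
#' that perplexity (the embedder requires `n - 1 >= 3 * perplexity`), the
#' perplexity is lowered to `floor((n - 1) / 3)` with a warning.
#' Deterministic for a fixed seed.
#'
#' @param X numeric matrix, observations in rows.
#' @param seed RNG seed.
#' @param perplexity override of the square-root rule.
#' @param ... further arguments to [Rtsne::Rtsne()] (e.g. `max_iter`).
#' @return list with `coords` (n x 2 matrix) and `perplexity` used.
#' @export
embedTSNE <- function(X, seed = 1L, perplexity = NULL, ...) {
  n <- nrow(X)
  if (n < 4L) {
    .orgscreenError("too few observations for t-SNE", "orgscreen_data_error")
  }
  if (is.null(perplexity)) perplexity <- floor(sqrt(n))
  max_perp <- floor((n - 1) / 3)
  if (perplexity > max_perp) {
    warning(sprintf("perplexity %d too large for n = %d; lowered to %d",
                    perplexity, n, max_perp), call. = FALSE)
    perplexity <- max_perp
  }
  set.seed(seed)
  fit <- Rtsne::Rtsne(X, dims = 2L, perplexity = perplexity,
                      check_duplicates = FALSE, pca = FALSE, verbose = FALSE,
                      ...)
  list(coords = fit$Y, perplexity = perplexity)
}

#' Louvain clustering of an embedding via a complement-weighted kNN graph
#'
#' Connects each observation to its k nearest neighbours in the embedding
#' (k capped at n - 1), weights each realized edge by the complement of its
#' Euclidean distance rescaled by the longest realized edge
#' (`w = 1 - d / d_max`, bounded in [0, 1] and order-reversing), and
#' partitions the resulting undirected graph with Louvain community
#' detection at resolution 1.
#'
#' @param coords n x 2 embedding coordinates.
#' @param k neighbours per observation (default 1000, the screen-scale
#'   setting; capped at n - 1).
#' @param seed RNG seed for the Louvain pass.
#' @param weight_scheme "complement" (default, `1 - d/d_max`) or "linear"
#'   (`d_max - d`).
#' @param resolution Louvain resolution parameter.
#' @return list with `labels` (integer 1..C per observation), `graph`
#'   (igraph object), `modularity`.
#' @export
clusterEmbedding <- function(coords, k = 1000L, seed = 1L,
                             weight_scheme = c("complement", "linear"),
                             resolution = 1) {
  weight_scheme <- match.arg(weight_scheme)
  n <- nrow(coords)
  if (n < 2L) {
    .orgscreenError("need at least 2 observations", "orgscreen_data_error")
  }
  k_eff <- min(k, n - 1L)
  nn <- FNN::get.knn(coords, k = k_eff)
  from <- rep(seq_len(n), k_eff)
  to <- as.vector(nn$nn.index)
  d <- as.vector(nn$nn.dist)
  d_max <- max(d)
  w <- if (d_max == 0) rep(1, length(d)) else switch(weight_scheme,
    complement = 1 - d / d_max,
    linear = d_max - d
  )
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w),
    directed = FALSE, vertices = data.frame(name = seq_len(n))
  )
  g <- igraph::simplify(g, edge.attr.comb = list(weight = "mean"))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- as.integer(igraph::membership(comm))
  list(labels = labels, graph = g,
       modularity = igraph::modularity(g, labels,
                                       weights = igraph::E(g)$weight))
}

#' Rank-normalize a vector
#'
#' Average ranks divided by the number of values, giving values in (0, 1];
#' used to enhance contrast before mapping features onto the embedding.
#'
#' @param values numeric vector.
#' @return normalized ranks, same length.
#' @examples
#' rankNormalize(c(5, 1, 3))  # 1.0 0.333 0.667
#' @export
rankNormalize <- function(values) {
  if (!length(values)) {
    .orgscreenError("empty input", "orgscreen_data_error")
  }
  rank(values, ties.method = "average") / length(values)
}

#' Characterize clusters by rank-normalized features and enrichment
#'
#' Per-cluster means of the rank-normalized feature columns, plus the
#' enrichment of each metadata level (within-cluster fraction divided by
#' overall fraction; 1 means no enrichment). The baseline-enriched cluster
#' — the trajectory root — is the cluster with maximal enrichment of the
#' earliest timepoint.
#'
#' @param labels integer cluster labels.
#' @param fm feature-matrix list from [buildFeatureMatrix()].
#' @param enrich_by metadata column used for enrichment (default
#'   `"time_h"`).
#' @return list with `feature_means` (cluster x feature, rank-normalized),
#'   `enrichment` (cluster x level), `baseline_cluster`.
#' @export
clusterProfiles <- function(labels, fm, enrich_by = "time_h") {
  X <- fm$X
  meta <- fm$meta
  ranks <- apply(X, 2L, rankNormalize)
  fmeans <- aggregate(ranks, by = list(cluster = labels), FUN = mean)
  lev <- meta[[enrich_by]]
  overall <- table(lev) / length(lev)
  cl_ids <- sort(unique(labels))
  enr <- t(vapply(cl_ids, function(cid) {
    within <- table(factor(lev[labels == cid], levels = names(overall))) /
      sum(labels == cid)
    as.numeric(within / overall)
  }, numeric(length(overall))))
  dimnames(enr) <- list(cluster = cl_ids, level = names(overall))
  base_level <- as.character(min(as.numeric(names(overall))))
  baseline_cluster <- cl_ids[which.max(enr[, base_level])]
  list(feature_means = fmeans, enrichment = enr,
       baseline_cluster = baseline_cluster)
}
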