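## S4 classes for the screen container, the simulator configuration and the
## trajectory model. Tabular results elsewhere are returned as data.frames.

#' @noRd
.MEASUREMENT_COLS <- c(
  "plate_id", "well", "time_h", "organoid_id",
  "bf_area", "green_area", "inv_area", "inv_green_area",
  "brightness", "texture"
)

#' @noRd
.LAYOUT_ROLES <- c("negative_control", "positive_control", "treatment",
                   "baseline", "empty")

#' OrganoidScreen: container for one organoid drug screen
#'
#' Holds the long-format per-organoid, per-timepoint measurement table, the
#' plate layout (well roles, drug regimens, concentrations, replicates) and an
#' optional per-patient clinical table. All downstream metrics take this
#' container as input.
#'
#' @slot measurements data.frame with columns `plate_id`, `well`, `time_h`,
#'   `organoid_id`, `bf_area`, `green_area`, `inv_area`, `inv_green_area`,
#'   `brightness`, `texture`; areas in square micrometres.
#' @slot layout data.frame with columns `plate_id`, `well`, `role`,
#'   `compound`, `concentration`, `replicate_id`, `patient_id`; one row per
#'   well and compound (combination regimens span several rows per well).
#' @slot clinical data.frame with columns `patient_id`, `pfs_months`,
#'   `censored`, `response_category`, `regimen`, or a zero-row data.frame
#'   when no clinical data are attached.
#'
#' @seealso [OrganoidScreen()] for construction with validation,
#'   [measurements()], [plateLayout()], [clinicalData()] for access.
#' @exportClass OrganoidScreen
setClass("OrganoidScreen",
  slots = c(
    measurements = "data.frame",
    layout = "data.frame",
    clinical = "data.frame"
  )
)

setValidity("OrganoidScreen", function(object) {
  m <- object@measurements
  l <- object@layout
  msgs <- character()
  missing_cols <- setdiff(.MEASUREMENT_COLS, names(m))
  if (length(missing_cols)) {
    msgs <- c(msgs, sprintf("measurements missing column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  } else {
    areas <- c("bf_area", "green_area", "inv_area", "inv_green_area")
    for (a in areas) {
      if (any(!is.finite(m[[a]])) || any(m[[a]] < 0)) {
        msgs <- c(msgs, sprintf("negative or non-finite %s", a))
      }
    }
    if (!length(msgs)) {
      if (any(m$green_area > m$bf_area * (1 + 1e-9))) {
        msgs <- c(msgs, "green_area exceeds bf_area (run readMeasurements or clipOverlaps)")
      }
      if (any(m$inv_green_area > m$inv_area * (1 + 1e-9))) {
        msgs <- c(msgs, "inv_green_area exceeds inv_area")
      }
      if (any(m$time_h < 0)) msgs <- c(msgs, "negative time_h")
    }
  }
  need_l <- c("plate_id", "well", "role")
  if (length(setdiff(need_l, names(l)))) {
    msgs <- c(msgs, "layout missing plate_id/well/role")
  } else if (nrow(l)) {
    bad <- setdiff(unique(l$role), .LAYOUT_ROLES)
    if (length(bad)) {
      msgs <- c(msgs, sprintf("unknown layout role(s): %s",
                              paste(bad, collapse = ", ")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Simulator configuration for a synthetic organoid plate
#'
#' Defines the generative model of a 384-well organoid screen: clone mixture
#' (growth rates, drug potency, death rates, invasion propensity), dose
#' series per regimen, control wells, seeding statistics, the imaging time
#' grid and the measurement-noise level. Construct with [simConfig()].
#'
#' @slot nReplicates integer, technical replicate wells per condition.
#' @slot organoidsPerWell numeric, mean seeded organoid count (Poisson).
#' @slot times numeric vector of imaging times in hours, starting at 0.
#' @slot clones data.frame: one row per clone with columns `fraction`,
#'   `growth_rate` (per hour), `ec50` (nM), `hill`, `max_death_rate`
#'   (per hour), `invasion_propensity` (unitless >= 0).
#' @slot regimens data.frame: one row per regimen x concentration with
#'   columns `regimen`, `concentration` (nM, anchor compound),
#'   `invasion_induction` (multiplier >= 0 applied to clone propensity).
#' @slot meanInitialArea numeric, median initial organoid area (um^2).
#' @slot areaSdLog numeric, log-sd of the initial-area log-normal.
#' @slot noiseSd numeric, log-sd of multiplicative measurement noise per
#'   channel (0 disables noise).
#' @slot posControlDeathRate numeric, per-hour death rate in staurosporine
#'   wells (default gives complete kill well before the final timepoint).
#' @slot seed integer RNG seed.
#' @exportClass SimConfig
setClass("SimConfig",
  slots = c(
    nReplicates = "integer",
    organoidsPerWell = "numeric",
    times = "numeric",
    clones = "data.frame",
    regimens = "data.frame",
    meanInitialArea = "numeric",
    areaSdLog = "numeric",
    noiseSd = "numeric",
    posControlDeathRate = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msgs <- character()
  cl <- object@clones
  if (abs(sum(cl$fraction) - 1) > 1e-8) msgs <- c(msgs, "clone fractions must sum to 1")
  if (any(cl$ec50 <= 0)) msgs <- c(msgs, "EC50 must be > 0")
  num_ok <- vapply(cl[c("fraction", "growth_rate", "ec50", "hill",
                        "max_death_rate", "invasion_propensity")],
                   function(x) all(is.finite(x)), logical(1))
  if (!all(num_ok)) msgs <- c(msgs, "clone parameters must be finite")
  if (any(cl$fraction < 0)) msgs <- c(msgs, "clone fractions must be >= 0")
  if (any(cl$max_death_rate < 0) || any(cl$invasion_propensity < 0)) {
    msgs <- c(msgs, "rates and propensities must be >= 0")
  }
  if (nrow(object@regimens) &&
      any(object@regimens$concentration <= 0)) {
    msgs <- c(msgs, "treatment concentrations must be > 0")
  }
  if (length(object@times) < 2L || object@times[1L] != 0 ||
      is.unsorted(object@times, strictly = TRUE)) {
    msgs <- c(msgs, "times must be ascending and start at 0")
  }
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  if (object@organoidsPerWell <= 0) msgs <- c(msgs, "organoidsPerWell must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Centroid-MST trajectory model over an embedding
#'
#' Minimum spanning tree over cluster centroids in the 2-D embedding, with
#' designated terminal clusters forced to be leaves, per-observation edge
#' projections, per-path pseudotime and the common (path-averaged)
#' pseudotime. Built by [centroidMST()] and completed by
#' [pseudotimeVectors()].
#'
#' @slot centroids matrix (clusters x 2) of centroid coordinates.
#' @slot edges data.frame of MST edges: `edge_id`, `from`, `to`, `length`.
#' @slot terminals integer vector of cluster ids forced to be leaves.
#' @slot root integer cluster id (baseline-enriched) or NA before rooting.
#' @slot projections data.frame per observation: `edge_id`, `t` (position
#'   along the edge in [0,1] from `from`), `dist` (distance to projection).
#' @slot paths list of root-to-leaf paths (integer cluster-id vectors).
#' @slot pseudotimePaths matrix (observations x paths); NA off-path.
#' @slot commonPseudotime numeric per observation.
#' @exportClass TrajectoryModel
setClass("TrajectoryModel",
  slots = c(
    centroids = "matrix",
    edges = "data.frame",
    terminals = "integer",
    root = "integer",
    projections = "data.frame",
    paths = "list",
    pseudotimePaths = "matrix",
    commonPseudotime = "numeric"
  ),
  prototype = list(
    root = NA_integer_,
    projections = data.frame(),
    paths = list(),
    pseudotimePaths = matrix(numeric(), 0, 0),
    commonPseudotime = numeric()
  )
)

setValidity("TrajectoryModel", function(object) {
  msgs <- character()
  C <- nrow(object@centroids)
  if (C >= 2L && nrow(object@edges) != C - 1L) {
    msgs <- c(msgs, "MST over C centroids must have C-1 edges")
  }
  if (nrow(object@edges)) {
    ids <- rownames(object@centroids)
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(object@edges$from),
                 to = as.character(object@edges$to)),
      directed = FALSE, vertices = data.frame(name = ids)
    )
    if (!igraph::is_connected(g)) msgs <- c(msgs, "MST must be connected")
    if (length(object@terminals)) {
      degs <- igraph::degree(g)[as.character(object@terminals)]
      if (any(degs != 1L)) msgs <- c(msgs, "terminal clusters must have degree 1")
    }
  }
  if (length(msgs)) msgs else TRUE
})
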