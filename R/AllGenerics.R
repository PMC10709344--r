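#' Access the measurement table of a screen
#'
#' @param object an [OrganoidScreen-class].
#' @return data.frame of per-organoid, per-timepoint measurements.
#' @export
setGeneric("measurements", function(object) standardGeneric("measurements"))

#' Access the plate layout of a screen
#'
#' @param object an [OrganoidScreen-class].
#' @return data.frame mapping wells to roles, compounds and concentrations.
#' @export
setGeneric("plateLayout", function(object) standardGeneric("plateLayout"))

#' Access the clinical table of a screen
#'
#' @param object an [OrganoidScreen-class].
#' @return data.frame of per-patient clinical annotation (may be empty).
#' @export
setGeneric("clinicalData", function(object) standardGeneric("clinicalData"))

#' @rdname measurements
#' @export
setMethod("measurements", "OrganoidScreen", function(object) object@measurements)

#' @rdname plateLayout
#' @export
setMethod("plateLayout", "OrganoidScreen", function(object) object@layout)

#' @rdname clinicalData
#' @export
setMethod("clinicalData", "OrganoidScreen", function(object) object@clinical)

setMethod("show", "OrganoidScreen", function(object) {
  m <- object@measurements
  l <- object@layout
  cat("OrganoidScreen\n")
  cat(sprintf("  measurements: %d rows, %d organoid tracks, %d wells, %d timepoints\n",
              nrow(m), nrow(unique(m[c("plate_id", "well", "organoid_id")])),
              length(unique(paste(m$plate_id, m$well))),
              length(unique(m$time_h))))
  if (nrow(l)) {
    tab <- table(unique(l[c("plate_id", "well", "role")])$role)
    cat("  layout wells:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  if (nrow(object@clinical)) {
    cat(sprintf("  clinical: %d patients\n", nrow(object@clinical)))
  }
  invisible(NULL)
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  %d clone(s), %d regimen x dose condition(s), %d timepoints (0-%g h)\n",
              nrow(object@clones), nrow(object@regimens),
              length(object@times), max(object@times)))
  cat(sprintf("  ~%g organoids/well, %d replicate(s), noise sd %g, seed %d\n",
              object@organoidsPerWell, object@nReplicates, object@noiseSd,
              object@seed))
  invisible(NULL)
})

setMethod("show", "TrajectoryModel", function(object) {
  cat("TrajectoryModel\n")
  cat(sprintf("  %d cluster centroids, %d MST edges, terminals: %s, root: %s\n",
              nrow(object@centroids), nrow(object@edges),
              paste(object@terminals, collapse = ","),
              ifelse(is.na(object@root), "<unset>", object@root)))
  if (length(object@paths)) {
    cat(sprintf("  %d root-to-leaf path(s); pseudotime computed for %d observations\n",
                length(object@paths), length(object@commonPseudotime)))
  }
  invisible(NULL)
})
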