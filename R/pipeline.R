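## End-to-end orchestration: simulate (or read) -> well metrics ->
## single-organoid states -> heterogeneity map -> pseudotime -> clinical.

#' Default pipeline configuration
#'
#' Every threshold defaults to the screen-standard value: response-class
#' cuts 0.15/0.34, invasive-fraction cut 0.2, signature cuts NDR -0.5 and
#' 40% cell death, kNN k = 1000, 1000 PC-selection permutations.
#'
#' @param seed integer seed governing every stochastic stage.
#' @return nested configuration list (see [runPipeline()]).
#' @export
defaultRunConfig <- function(seed = 17L) {
  list(
    seed = as.integer(seed),
    simulate = list(scenario = "heterogeneous", organoids_per_well = 200),
    inputs = list(measurements = NULL, layout = NULL, clinical = NULL),
    thresholds = list(resistant = 0.15, highly_sensitive = 0.34,
                      invasive = 0.2, ndr_cut = -0.5, death_cut = 40),
    map = list(n_perm = 1000L, alpha = 0.05, knn_k = 1000L, resolution = 1)
  )
}

#' @noRd
.checkRunConfig <- function(cfg) {
  th <- cfg$thresholds
  if (th$resistant >= th$highly_sensitive) {
    .orgscreenError(
      "config error: thresholds.resistant must be below thresholds.highly_sensitive",
      "orgscreen_config_error"
    )
  }
  if (th$invasive < 0 || th$death_cut < 0 || th$death_cut > 100) {
    .orgscreenError("config error: invalid invasive/death thresholds",
                    "orgscreen_config_error")
  }
  if (is.null(cfg$seed)) {
    .orgscreenError("config error: seed is required", "orgscreen_config_error")
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Chains every stage on either a simulated scenario or user-supplied
#' measurement/layout files, writing one delimited text file per stage
#' output plus a machine-readable run manifest (config hash, seed, package
#' version, output checksums). Reruns with an identical configuration
#' reproduce identical outputs and manifest. A stage failure aborts with
#' the stage name.
#'
#' @param config configuration list (see [defaultRunConfig()]) or path to
#'   a YAML file with the same structure; partial configs are completed
#'   with defaults.
#' @param outDir output directory, created if missing.
#' @return invisibly, a list with the main in-memory results per stage.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(defaultRunConfig(), config)
  cfg <- .checkRunConfig(cfg)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  out <- list(config = cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .orgscreenError(sprintf("stage '%s' failed: %s", name,
                              conditionMessage(e)),
                      "orgscreen_stage_error")
    })
  }
  wr <- function(d, f) {
    write.csv(d, file.path(outDir, f), row.names = FALSE)
    f
  }
  files <- character()

  ## --- ingest or simulate -------------------------------------------------
  ingested <- stage("ingest", {
    if (!is.null(cfg$inputs$measurements)) {
      m <- readMeasurements(cfg$inputs$measurements)
      l <- readPlateLayout(cfg$inputs$layout)
      cl <- if (!is.null(cfg$inputs$clinical))
        readClinical(cfg$inputs$clinical) else NULL
      list(screen = OrganoidScreen(m, l, cl), truth = NULL)
    } else {
      scen <- defaultScenarios(
        seed = cfg$seed,
        organoidsPerWell = cfg$simulate$organoids_per_well
      )[[cfg$simulate$scenario]]
      if (is.null(scen)) {
        .orgscreenError(sprintf("unknown scenario '%s'",
                                cfg$simulate$scenario),
                        "orgscreen_config_error")
      }
      sim <- simulatePlate(scen)
      list(screen = sim$screen, truth = sim$truth)
    }
  })
  screen <- ingested$screen
  truth <- ingested$truth
  files <- c(files, wr(measurements(screen), "measurements.csv"),
             wr(plateLayout(screen), "layout.csv"))
  if (!is.null(truth)) {
    files <- c(files, wr(truth$organoids, "ground_truth_organoids.csv"),
               wr(truth$wells, "ground_truth_wells.csv"))
  }

  ## --- well metrics -------------------------------------------------------
  out$well_metrics <- stage("wellmetrics", wellMetrics(screen))
  out$dose_response <- stage("wellmetrics", doseResponse(screen))
  files <- c(files, wr(out$well_metrics, "well_metrics.csv"),
             wr(out$dose_response$profile, "dose_response_profile.csv"),
             wr(out$dose_response$auc, "dose_response_auc.csv"))

  ## --- single-organoid states --------------------------------------------
  th <- cfg$thresholds
  out$states <- stage("singleorg", organoidStates(
    screen, cuts = c(th$resistant, th$highly_sensitive),
    invasiveThreshold = th$invasive))
  out$class_fractions <- stage("singleorg", classFractions(out$states))
  files <- c(files, wr(out$states, "organoid_states.csv"),
             wr(out$class_fractions, "class_fractions.csv"))

  ## --- heterogeneity map --------------------------------------------------
  out$map <- stage("map", {
    fm <- buildFeatureMatrix(out$states)
    pcs <- selectInformativePCs(fm$X, n_perm = cfg$map$n_perm,
                                alpha = cfg$map$alpha, seed = cfg$seed)
    Xe <- if (pcs$n_retained >= 2L) pcs$scores else fm$X
    emb <- embedTSNE(Xe, seed = cfg$seed)
    clu <- clusterEmbedding(emb$coords, k = cfg$map$knn_k, seed = cfg$seed,
                            resolution = cfg$map$resolution)
    prof <- clusterProfiles(clu$labels, fm)
    list(fm = fm, pcs = pcs, embedding = emb, clusters = clu,
         profiles = prof)
  })
  emb_tab <- cbind(out$map$fm$meta,
                   tsne1 = out$map$embedding$coords[, 1L],
                   tsne2 = out$map$embedding$coords[, 2L],
                   cluster = out$map$clusters$labels)
  files <- c(files, wr(emb_tab, "embedding.csv"),
             wr(out$map$profiles$feature_means, "cluster_profiles.csv"))

  ## --- pseudotime ---------------------------------------------------------
  out$trajectory <- stage("pseudotime", {
    prof <- out$map$profiles
    fmn <- prof$feature_means
    root <- prof$baseline_cluster
    cand <- function(col, decreasing = TRUE) {
      if (is.null(fmn[[col]])) return(NA_integer_)
      ord <- fmn$cluster[order(fmn[[col]], decreasing = decreasing)]
      setdiff(ord, root)[1L]
    }
    # terminal states: sensitive (top fraction affected), invasive (top
    # invasive fraction), resistant (bottom fraction affected)
    terminals <- unique(c(cand("fa"), cand("inv_fraction"),
                          cand("fa", decreasing = FALSE)))
    terminals <- terminals[!is.na(terminals)]
    n_clu <- nrow(fmn)
    terminals <- head(terminals, max(0L, n_clu - 1L - 1L))
    model <- centroidMST(out$map$clusters$labels,
                         out$map$embedding$coords, terminals = terminals)
    model <- projectToMST(out$map$embedding$coords, model)
    pseudotimeVectors(model, root = root)
  })
  traj_tab <- cbind(out$map$fm$meta,
                    common_pseudotime = commonPseudotime(out$trajectory))
  files <- c(files, wr(traj_tab, "pseudotime.csv"))
  inv_term <- out$trajectory@terminals[1L]
  if (length(inv_term) && !is.na(inv_term) &&
      as.character(inv_term) %in% names(out$trajectory@paths)) {
    dens <- stage("pseudotime", densityAlongPath(
      out$trajectory, arm = out$map$fm$meta$regimen, terminal = inv_term))
    out$path_density <- dens
    files <- c(files, wr(dens$mass, "path_mass.csv"))
  }

  ## --- clinical (needs a multi-patient cohort with observed PFS) ---------
  if (nrow(clinicalData(screen))) {
    out$clinical <- stage("clinical", {
      endpoint <- out$states[out$states$time_h == max(out$states$time_h) &
                               out$states$role == "treatment", ]
      endpoint$patient_id <- plateLayout(screen)$patient_id[
        match(paste(endpoint$plate_id, endpoint$well),
              paste(plateLayout(screen)$plate_id, plateLayout(screen)$well))]
      fr <- classFractions(endpoint, by = "patient_id")
      corr <- correlateWithPFS(
        fr[c("patient_id", "pct_sensitive", "pct_resistant",
             "ratio_sens_res")],
        clinicalData(screen))
      list(fractions = fr, correlations = corr)
    })
    files <- c(files, wr(out$clinical$correlations, "pfs_correlations.csv"))
  }

  ## --- manifest -----------------------------------------------------------
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null",
                               digits = NA)
  cfg_file <- file.path(outDir, "config.json")
  writeLines(cfg_json, cfg_file)
  manifest <- list(
    package = "orgscreen",
    version = as.character(utils::packageVersion("orgscreen")),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    outputs = as.list(setNames(
      unname(tools::md5sum(file.path(outDir, files))), files))
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
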