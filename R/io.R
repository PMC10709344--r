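#' Read a per-organoid measurement table
#'
#' Reads the long-format table emitted by the image-analysis platform: one
#' row per organoid and timepoint, with masked brightfield area, dead-signal
#' overlap area, invasive-annulus area and its dead overlap, brightness and
#' texture. Columns may appear in any order; extra columns are dropped.
#'
#' Dead-signal overlaps physically cannot exceed their mask, but segmentation
#' noise can push them slightly over; such rows are clipped
#' (`green_area <= bf_area`, `inv_green_area <= inv_area`) and the number of
#' clipped rows is reported as a warning. Negative areas are rejected.
#'
#' @param path path to a comma-delimited text file.
#' @param clip logical, clip overlap areas to their mask area (default TRUE).
#' @return a validated measurement data.frame with the ten schema columns,
#'   well ids normalized to zero-padded form ("A01").
#' @seealso [OrganoidScreen()], [writeMeasurements()]
#' @export
readMeasurements <- function(path, clip = TRUE) {
  if (!file.exists(path)) {
    .orgscreenError(sprintf("file not found: %s", path), "orgscreen_io_error")
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  missing_cols <- setdiff(.MEASUREMENT_COLS, names(raw))
  if (length(missing_cols)) {
    .orgscreenError(
      sprintf("measurement file missing required column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "orgscreen_schema_error"
    )
  }
  m <- raw[.MEASUREMENT_COLS]
  num_cols <- setdiff(.MEASUREMENT_COLS, c("plate_id", "well"))
  for (cc in num_cols) {
    v <- m[[cc]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & trimws(v) != "")
      if (length(bad)) {
        .orgscreenError(
          sprintf("non-numeric value in column '%s' at row %d: '%s'",
                  cc, bad[1L], v[bad[1L]]),
          "orgscreen_parse_error"
        )
      }
      m[[cc]] <- conv
    }
  }
  if (anyNA(m[num_cols])) {
    .orgscreenError("missing numeric values in measurement table",
                    "orgscreen_parse_error")
  }
  areas <- c("bf_area", "green_area", "inv_area", "inv_green_area")
  for (a in areas) {
    if (any(m[[a]] < 0)) {
      .orgscreenError(sprintf("negative %s rejected", a),
                      "orgscreen_schema_error")
    }
  }
  m$plate_id <- as.character(m$plate_id)
  m$well <- .normalizeWell(m$well)
  m$organoid_id <- as.integer(m$organoid_id)
  if (clip) m <- clipOverlaps(m)
  m
}

#' Clip dead-signal overlap areas to their mask areas
#'
#' Idempotent: re-applying to an already-clipped table changes nothing.
#'
#' @param m measurement data.frame.
#' @return the table with `green_area <= bf_area` and
#'   `inv_green_area <= inv_area` enforced row-wise; warns with the count of
#'   clipped rows when any clipping occurred.
#' @export
clipOverlaps <- function(m) {
  n_clip <- sum(m$green_area > m$bf_area) + sum(m$inv_green_area > m$inv_area)
  if (n_clip > 0L) {
    m$green_area <- pmin(m$green_area, m$bf_area)
    m$inv_green_area <- pmin(m$inv_green_area, m$inv_area)
    warning(sprintf("clipped %d overlap value(s) exceeding their mask area",
                    n_clip), call. = FALSE)
  }
  m
}

#' Write a measurement table
#'
#' Inverse of [readMeasurements()]: writes comma-delimited text that
#' round-trips bit-identically for finite values (full double precision).
#'
#' @param m measurement data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMeasurements <- function(m, path) {
  out <- m[.MEASUREMENT_COLS]
  num_cols <- setdiff(.MEASUREMENT_COLS, c("plate_id", "well"))
  for (cc in num_cols) {
    out[[cc]] <- vapply(out[[cc]], format, character(1), digits = 17)
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plate layout
#'
#' Reads the well-to-condition map: one row per well and compound, with the
#' well role (`negative_control`, `positive_control`, `treatment`,
#' `baseline`), compound name, concentration (nM), technical replicate id
#' and patient id. Combination regimens list one row per component compound
#' in the same well. Wells absent from the layout are treated as empty and
#' excluded downstream.
#'
#' The NDR metric is anchored on both controls, so a plate without any
#' positive-control (staurosporine) well is rejected outright; fewer than
#' two wells of either control role draws a warning (single-well anchors are
#' fragile).
#'
#' @param path comma-delimited text file with columns `well`, `role` and
#'   optionally `plate_id` (default "P1"), `compound`, `concentration`,
#'   `replicate_id`, `patient_id`, `regimen`.
#' @return validated layout data.frame.
#' @export
readPlateLayout <- function(path) {
  if (!file.exists(path)) {
    .orgscreenError(sprintf("file not found: %s", path), "orgscreen_io_error")
  }
  l <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "role")
  missing_cols <- setdiff(need, names(l))
  if (length(missing_cols)) {
    .orgscreenError(
      sprintf("layout missing required column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "orgscreen_schema_error"
    )
  }
  if (is.null(l$plate_id)) l$plate_id <- "P1"
  if (is.null(l$compound)) l$compound <- NA_character_
  if (is.null(l$concentration)) l$concentration <- NA_real_
  if (is.null(l$replicate_id)) l$replicate_id <- 1L
  if (is.null(l$patient_id)) l$patient_id <- NA_character_
  if (is.null(l$regimen)) l$regimen <- l$compound
  l$well <- .normalizeWell(l$well)
  validatePlateLayout(l)
}

#' Validate a plate layout data.frame
#'
#' @param l layout data.frame (see [readPlateLayout()] for columns).
#' @return `l`, with roles checked, duplicate wells rejected and control
#'   coverage enforced.
#' @export
validatePlateLayout <- function(l) {
  bad_role <- setdiff(unique(l$role), .LAYOUT_ROLES)
  if (length(bad_role)) {
    .orgscreenError(sprintf("unknown role(s): %s",
                            paste(bad_role, collapse = ", ")),
                    "orgscreen_schema_error")
  }
  key <- paste(l$plate_id, l$well, ifelse(is.na(l$compound), "", l$compound))
  if (anyDuplicated(key)) {
    .orgscreenError(
      sprintf("duplicate well entry: %s", l$well[duplicated(key)][1L]),
      "orgscreen_schema_error"
    )
  }
  role_by_well <- unique(l[c("plate_id", "well", "role")])
  if (anyDuplicated(paste(role_by_well$plate_id, role_by_well$well))) {
    dup <- role_by_well$well[duplicated(paste(role_by_well$plate_id,
                                              role_by_well$well))][1L]
    .orgscreenError(sprintf("well %s assigned more than one role", dup),
                    "orgscreen_schema_error")
  }
  for (p in unique(l$plate_id)) {
    roles <- role_by_well$role[role_by_well$plate_id == p]
    if (!any(roles == "positive_control")) {
      .orgscreenError(
        sprintf("plate %s has no positive_control well: NDR requires a staurosporine anchor", p),
        "orgscreen_validation_error"
      )
    }
    if (!any(roles == "negative_control")) {
      .orgscreenError(
        sprintf("plate %s has no negative_control (vehicle) well", p),
        "orgscreen_validation_error"
      )
    }
    for (r in c("negative_control", "positive_control")) {
      if (sum(roles == r) < 2L) {
        warning(sprintf("plate %s has fewer than 2 %s wells", p, r),
                call. = FALSE)
      }
    }
  }
  trt <- l[l$role == "treatment", ]
  if (nrow(trt) &&
      (anyNA(trt$compound) || anyNA(trt$concentration) ||
       any(trt$concentration <= 0))) {
    .orgscreenError(
      "treatment wells must carry a compound with concentration > 0",
      "orgscreen_validation_error"
    )
  }
  l
}

#' Read a per-patient clinical table
#'
#' @param path comma-delimited file with columns `patient_id`, `pfs_months`,
#'   `censored` (logical/0-1), `response_category` (good/mixed/bad),
#'   `regimen`.
#' @return validated clinical data.frame.
#' @export
readClinical <- function(path) {
  if (!file.exists(path)) {
    .orgscreenError(sprintf("file not found: %s", path), "orgscreen_io_error")
  }
  cl <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "pfs_months", "censored", "response_category",
            "regimen")
  missing_cols <- setdiff(need, names(cl))
  if (length(missing_cols)) {
    .orgscreenError(sprintf("clinical table missing column(s): %s",
                            paste(missing_cols, collapse = ", ")),
                    "orgscreen_schema_error")
  }
  cl$censored <- as.logical(cl$censored)
  bad <- setdiff(unique(cl$response_category), c("good", "mixed", "bad"))
  if (length(bad)) {
    .orgscreenError(sprintf("unknown response_category: %s",
                            paste(bad, collapse = ", ")),
                    "orgscreen_schema_error")
  }
  if (any(!is.na(cl$pfs_months) & cl$pfs_months <= 0)) {
    .orgscreenError("pfs_months must be > 0", "orgscreen_schema_error")
  }
  cl
}

#' Construct an OrganoidScreen container
#'
#' @param measurements measurement data.frame (see [readMeasurements()]).
#' @param layout layout data.frame (see [readPlateLayout()]).
#' @param clinical optional clinical data.frame (see [readClinical()]).
#' @return an [OrganoidScreen-class] object, validated.
#' @examples
#' sim <- simulatePlate(defaultScenarios()[["heterogeneous"]])
#' scr <- sim$screen
#' scr
#' @export
OrganoidScreen <- function(measurements, layout, clinical = NULL) {
  if (is.null(clinical)) {
    clinical <- data.frame(patient_id = character(), pfs_months = numeric(),
                           censored = logical(),
                           response_category = character(),
                           regimen = character())
  }
  new("OrganoidScreen", measurements = measurements, layout = layout,
      clinical = clinical)
}

#' Cross-check measurements against the plate layout
#'
#' Report-only consistency audit: wells present in the layout but absent
#' from the measurements (and vice versa), and wells whose time grid differs
#' from their plate's modal grid. Inputs are never modified.
#'
#' @param screen an [OrganoidScreen-class], or a measurement data.frame if
#'   `layout` is given separately.
#' @param layout optional layout data.frame when `screen` is a data.frame.
#' @return data.frame of findings with columns `type`, `plate_id`, `well`,
#'   `message`; zero rows when fully consistent.
#' @export
validateDataset <- function(screen, layout = NULL) {
  if (is(screen, "OrganoidScreen")) {
    m <- measurements(screen)
    l <- plateLayout(screen)
  } else {
    m <- screen
    l <- layout
  }
  findings <- list()
  add <- function(type, plate, well, msg) {
    findings[[length(findings) + 1L]] <<-
      data.frame(type = type, plate_id = plate, well = well, message = msg,
                 stringsAsFactors = FALSE)
  }
  mkey <- unique(m[c("plate_id", "well")])
  lkey <- unique(l[l$role != "empty", c("plate_id", "well")])
  only_layout <- lkey[!paste(lkey$plate_id, lkey$well) %in%
                        paste(mkey$plate_id, mkey$well), ]
  only_meas <- mkey[!paste(mkey$plate_id, mkey$well) %in%
                      paste(lkey$plate_id, lkey$well), ]
  for (i in seq_len(nrow(only_layout))) {
    add("missing_measurements", only_layout$plate_id[i], only_layout$well[i],
        "well in layout but absent from measurements")
  }
  for (i in seq_len(nrow(only_meas))) {
    add("orphan_well", only_meas$plate_id[i], only_meas$well[i],
        "well measured but absent from layout")
  }
  for (p in unique(m$plate_id)) {
    mp <- m[m$plate_id == p, ]
    grids <- tapply(mp$time_h, mp$well, function(t) {
      paste(sort(unique(t)), collapse = ",")
    })
    modal <- names(sort(table(grids), decreasing = TRUE))[1L]
    off <- names(grids)[grids != modal]
    for (w in off) {
      add("ragged_time_grid", p, w,
          sprintf("time grid differs from plate mode (%s)", modal))
    }
  }
  if (!length(findings)) {
    return(data.frame(type = character(), plate_id = character(),
                      well = character(), message = character()))
  }
  do.call(rbind, findings)
}
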