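## Single-organoid response scoring: fraction affected, three response
## classes, class-fraction summaries and invasion quantification.

#' Fraction of an organoid affected by cell death
#'
#' Ratio of the dead-reporter overlap area to the masked organoid area,
#' clipped to [0, 1]. Organoids with zero masked area carry no information
#' and yield NA (callers exclude and count them).
#'
#' @param green_area dead-signal overlap area (um^2).
#' @param bf_area masked brightfield area (um^2).
#' @return fraction affected in [0, 1]; NA where `bf_area <= 0`.
#' @export
fractionAffected <- function(green_area, bf_area) {
  fa <- ifelse(bf_area > 0, pmin(green_area / bf_area, 1), NA_real_)
  pmax(fa, 0)
}

#' Classify organoids by fraction affected
#'
#' Half-open bins partitioning [0, 1]: fraction affected below the first
#' cut is `resistant`, from the first up to (excluding) the second is
#' `sensitive`, and at or above the second is `highly_sensitive`.
#'
#' @param fa fraction affected in [0, 1].
#' @param cuts numeric length-2, the resistant/sensitive and
#'   sensitive/highly-sensitive cut points (defaults 0.15 and 0.34).
#' @return factor with levels resistant < sensitive < highly_sensitive;
#'   NA input propagates.
#' @examples
#' classifyResponse(c(0.10, 0.20, 0.50))
#' @export
classifyResponse <- function(fa, cuts = c(0.15, 0.34)) {
  if (length(cuts) != 2L || cuts[1L] >= cuts[2L]) {
    .orgscreenError("cuts must be two increasing thresholds",
                    "orgscreen_config_error")
  }
  if (any(fa < 0 | fa > 1, na.rm = TRUE)) {
    .orgscreenError("fraction affected must lie in [0, 1]",
                    "orgscreen_config_error")
  }
  cut(fa, breaks = c(-Inf, cuts, Inf), right = FALSE,
      labels = c("resistant", "sensitive", "highly_sensitive"),
      ordered_result = TRUE)
}

#' Flag invasive organoids and assign response quadrants
#'
#' An organoid is invasive when its invasive fraction (annulus area over
#' organoid area) exceeds the threshold. Crossed with the fraction-affected
#' dichotomy (resistant below the resistant cut, otherwise affected) this
#' yields the four quadrant categories invasive/non-invasive x
#' resistant/sensitive.
#'
#' @param inv_fraction invasive fraction (>= 0).
#' @param fa fraction affected, for the quadrant label.
#' @param threshold invasive-fraction cut-off (default 0.2).
#' @param resistant_cut fraction-affected cut below which an organoid
#'   counts as resistant (default 0.15).
#' @return data.frame with `invasive_flag` (logical) and `quadrant`
#'   (factor: invasive_resistant, invasive_sensitive,
#'   noninvasive_resistant, noninvasive_sensitive).
#' @export
classifyInvasive <- function(inv_fraction, fa, threshold = 0.2,
                             resistant_cut = 0.15) {
  if (any(inv_fraction < 0, na.rm = TRUE)) {
    .orgscreenError("invasive fraction must be >= 0",
                    "orgscreen_config_error")
  }
  flag <- inv_fraction > threshold
  res <- fa < resistant_cut
  quadrant <- factor(
    ifelse(flag & res, "invasive_resistant",
    ifelse(flag & !res, "invasive_sensitive",
    ifelse(!flag & res, "noninvasive_resistant", "noninvasive_sensitive"))),
    levels = c("invasive_resistant", "invasive_sensitive",
               "noninvasive_resistant", "noninvasive_sensitive")
  )
  data.frame(invasive_flag = flag, quadrant = quadrant)
}

#' Per-organoid response and invasion state table
#'
#' Joins the measurement table with the layout and computes, per organoid
#' and timepoint: fraction affected, response class, invasive fraction,
#' survival invasive area (invasive area minus its dead overlap),
#' invasive flag and quadrant. Organoids with zero masked area are excluded
#' with a message reporting the count.
#'
#' @param screen an [OrganoidScreen-class].
#' @param cuts response-class cut points, see [classifyResponse()].
#' @param invasiveThreshold invasive-fraction cut-off, see
#'   [classifyInvasive()].
#' @return data.frame, one row per organoid x timepoint, carrying well
#'   metadata (role, regimen, concentration) plus the state columns.
#' @export
organoidStates <- function(screen, cuts = c(0.15, 0.34),
                           invasiveThreshold = 0.2) {
  m <- measurements(screen)
  l <- plateLayout(screen)
  lw <- unique(l[c("plate_id", "well", "role", "regimen", "replicate_id")])
  conc <- tapply(l$concentration, paste(l$plate_id, l$well),
                 function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  st <- merge(m, lw, by = c("plate_id", "well"))
  st$concentration <- unname(conc[paste(st$plate_id, st$well)])
  n_zero <- sum(st$bf_area <= 0)
  if (n_zero > 0L) {
    message(sprintf("excluding %d organoid observation(s) with zero masked area",
                    n_zero))
    st <- st[st$bf_area > 0, ]
  }
  st$fa <- fractionAffected(st$green_area, st$bf_area)
  st$response_class <- classifyResponse(st$fa, cuts = cuts)
  st$inv_fraction <- st$inv_area / st$bf_area
  st$survival_inv_area <- st$inv_area - st$inv_green_area
  inv <- classifyInvasive(st$inv_fraction, st$fa,
                          threshold = invasiveThreshold,
                          resistant_cut = cuts[1L])
  st$invasive_flag <- inv$invasive_flag
  st$quadrant <- inv$quadrant
  rownames(st) <- NULL
  st
}

#' Class fractions and sensitive:resistant ratio per group
#'
#' Tabulates the relative fraction of resistant, sensitive and highly
#' sensitive organoids per group, plus the sensitive:resistant ratio in
#' which the numerator pools sensitive and highly sensitive (treating the
#' readout as a sensitive-versus-resistant dichotomy). Groups with no
#' resistant organoid report an infinite ratio with `ratio_undefined`
#' flagged. Quadrant fractions (invasion x resistance) are appended when
#' present.
#'
#' @param states data.frame from [organoidStates()].
#' @param by character vector of grouping columns (default well identity
#'   and timepoint).
#' @return data.frame per group: `n`, `frac_resistant`, `frac_sensitive`,
#'   `frac_highly_sensitive` (summing to 1), `pct_sensitive`
#'   (100 * (1 - frac_resistant)), `pct_resistant`, `ratio_sens_res`,
#'   `ratio_undefined`, and `frac_<quadrant>` columns.
#' @export
classFractions <- function(states,
                           by = c("plate_id", "well", "regimen",
                                  "concentration", "time_h")) {
  sp <- split(states, states[by], drop = TRUE)
  rows <- lapply(sp, function(d) {
    n <- nrow(d)
    counts <- table(d$response_class)
    fr <- as.numeric(counts["resistant"]) / n
    fs <- as.numeric(counts["sensitive"]) / n
    fh <- as.numeric(counts["highly_sensitive"]) / n
    out <- d[1L, by, drop = FALSE]
    out$n <- n
    out$frac_resistant <- fr
    out$frac_sensitive <- fs
    out$frac_highly_sensitive <- fh
    out$pct_resistant <- 100 * fr
    out$pct_sensitive <- 100 * (1 - fr)
    out$ratio_sens_res <- if (counts["resistant"] == 0) Inf else
      (as.numeric(counts["sensitive"]) + as.numeric(counts["highly_sensitive"])) /
        as.numeric(counts["resistant"])
    out$ratio_undefined <- counts["resistant"] == 0
    if (!is.null(d$quadrant)) {
      qt <- table(d$quadrant) / n
      for (q in names(qt)) out[[paste0("frac_", q)]] <- as.numeric(qt[q])
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Invasion metrics per group
#'
#' Per-group sums of invasive area and survival invasive area, the mean
#' invasive fraction, and the kinetic sum invasive area normalized to the
#' group's first timepoint. When the baseline sum is zero the normalization
#' divides by a 1 um^2 pseudo-area instead and flags the group.
#'
#' @param screen an [OrganoidScreen-class] or a measurement data.frame.
#' @param by grouping columns among the measurement/layout columns
#'   (default plate and well).
#' @return data.frame per group x timepoint: `sum_inv_area`,
#'   `sum_survival_inv_area`, `mean_inv_fraction`, `kinetic_inv_norm`,
#'   `baseline_zero` flag.
#' @export
invasionMetrics <- function(screen, by = c("plate_id", "well")) {
  m <- if (is(screen, "OrganoidScreen")) measurements(screen) else screen
  m <- m[m$bf_area > 0, ]
  sp <- split(m, m[by], drop = TRUE)
  rows <- lapply(sp, function(d) {
    agg <- aggregate(
      cbind(sum_inv_area = d$inv_area,
            sum_survival_inv_area = d$inv_area - d$inv_green_area),
      by = list(time_h = d$time_h), FUN = sum
    )
    mif <- aggregate(list(mean_inv_fraction = d$inv_area / d$bf_area),
                     by = list(time_h = d$time_h), FUN = mean)
    agg <- merge(agg, mif, by = "time_h")
    agg <- agg[order(agg$time_h), ]
    base <- agg$sum_inv_area[1L]
    agg$baseline_zero <- base == 0
    agg$kinetic_inv_norm <- agg$sum_inv_area / if (base == 0) 1 else base
    meta <- d[1L, by, drop = FALSE]
    cbind(meta[rep(1L, nrow(agg)), , drop = FALSE], agg)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
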