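## Bulk (well-level) drug-response metrics anchored on plate controls.
##
## The well signal is total masked brightfield area minus total dead-reporter
## overlap area; each well is self-normalized to its first timepoint (fold
## change F). Treatment metrics compare F against the vehicle mean (GR) or
## against both vehicle and staurosporine means (percent viability, NDR).

#' Assemble the kinetic signal of one well
#'
#' Sums organoid areas per timepoint, forms the viability signal
#' `S(t) = total brightfield area - total green area`, and the per-well fold
#' change `F(t) = S(t)/S(t0)` from the first measurement.
#'
#' @param m measurement data.frame or [OrganoidScreen-class].
#' @param well well id (zero-padded, e.g. "B03").
#' @param plate plate id; defaults to the single plate present.
#' @return data.frame per timepoint: `time_h`, `signal` (um^2),
#'   `fold_change`, `cell_death` (percent of total area overlapped by the
#'   dead reporter).
#' @examples
#' sim <- simulatePlate(simConfig(organoidsPerWell = 20))
#' wellSignal(sim$screen, plateLayout(sim$screen)$well[1])
#' @export
wellSignal <- function(m, well, plate = NULL) {
  if (is(m, "OrganoidScreen")) m <- measurements(m)
  if (is.null(plate)) {
    plate <- unique(m$plate_id)
    if (length(plate) > 1L) {
      .orgscreenError("several plates present; specify `plate`",
                      "orgscreen_data_error")
    }
  }
  mw <- m[m$plate_id == plate & m$well == well, ]
  if (!nrow(mw)) {
    .orgscreenError(sprintf("well %s not found on plate %s", well, plate),
                    "orgscreen_data_error")
  }
  bf <- tapply(mw$bf_area, mw$time_h, sum)
  green <- tapply(mw$green_area, mw$time_h, sum)
  times <- as.numeric(names(bf))
  if (length(times) < 2L) {
    .orgscreenError(sprintf("well %s has a single timepoint", well),
                    "orgscreen_data_error")
  }
  S <- as.numeric(bf - green)
  if (S[1L] <= 0) {
    .orgscreenError(
      sprintf("degenerate well %s: signal at first timepoint is %g", well,
              S[1L]),
      "orgscreen_degenerate_well"
    )
  }
  data.frame(time_h = times, signal = S, fold_change = S / S[1L],
             cell_death = 100 * as.numeric(green) / as.numeric(bf))
}

#' Mean control fold changes per plate and timepoint
#'
#' @param screen an [OrganoidScreen-class].
#' @param stat "mean" (default) or "median" across control wells; the
#'   median is robust to a single failed control well.
#' @return data.frame per plate x timepoint: `plate_id`, `time_h`,
#'   `f_neg` (vehicle), `f_pos` (staurosporine).
#' @export
controlAnchors <- function(screen, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  fun <- if (stat == "mean") mean else stats::median
  l <- plateLayout(screen)
  out <- list()
  for (p in unique(l$plate_id)) {
    lw <- unique(l[l$plate_id == p, c("well", "role")])
    negs <- lw$well[lw$role == "negative_control"]
    poss <- lw$well[lw$role == "positive_control"]
    if (!length(negs) || !length(poss)) {
      .orgscreenError(
        sprintf("plate %s lacks a control role for anchoring", p),
        "orgscreen_validation_error"
      )
    }
    fc <- function(wellset) {
      per <- lapply(wellset, function(w) wellSignal(screen, w, plate = p))
      times <- per[[1L]]$time_h
      mat <- vapply(per, function(d) d$fold_change, numeric(length(times)))
      data.frame(time_h = times, f = apply(as.matrix(mat), 1L, fun))
    }
    fn <- fc(negs)
    fp <- fc(poss)
    out[[p]] <- data.frame(plate_id = p, time_h = fn$time_h,
                           f_neg = fn$f, f_pos = fp$f)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Percent viability from control-anchored fold changes
#'
#' Linear rescaling of the treated fold change so the vehicle mean maps to
#' 100% and the staurosporine mean to 0%. Without a positive control the
#' vehicle-only normalization `100 * F / F_neg` is used.
#'
#' @param f_trt treated-well fold change.
#' @param f_neg mean vehicle fold change at the same timepoint.
#' @param f_pos mean staurosporine fold change, or NULL if unavailable.
#' @return percent viability (vectorized over `f_trt`).
#' @export
percentViability <- function(f_trt, f_neg, f_pos = NULL) {
  if (is.null(f_pos)) return(100 * f_trt / f_neg)
  if (isTRUE(all.equal(f_neg, f_pos))) {
    .orgscreenError("degenerate anchors: vehicle and staurosporine fold changes coincide",
                    "orgscreen_anchor_error")
  }
  100 * (f_trt - f_pos) / (f_neg - f_pos)
}

#' Growth-rate (GR) response metric
#'
#' `GR = 2^(log2 F_trt / log2 F_neg) - 1`: the treated growth rate expressed
#' relative to the vehicle growth rate on a doubling scale. GR = 1 for
#' vehicle-like growth, 0 for complete growth inhibition (no net change),
#' negative for net killing.
#'
#' @param f_trt treated fold change (>= 0; 0 is the complete-kill limit,
#'   giving GR = -1).
#' @param f_neg mean vehicle fold change; must exceed 1 (the control
#'   population must grow for the metric to be defined). Violations raise a
#'   condition of class `orgscreen_slow_growth`.
#' @return GR value (vectorized over `f_trt`).
#' @export
grMetric <- function(f_trt, f_neg) {
  if (any(f_trt < 0)) {
    .orgscreenError("treated fold change must be >= 0", "orgscreen_metric_error")
  }
  if (f_neg <= 1) {
    .orgscreenError(
      sprintf("negative control did not grow (fold change %.3g <= 1): GR undefined",
              f_neg),
      c("orgscreen_slow_growth", "orgscreen_metric_error")
    )
  }
  ifelse(f_trt == 0, -1, 2^(log2(f_trt) / log2(f_neg)) - 1)
}

#' Normalized drug response (NDR) metric
#'
#' Control-anchored response on the scale: > 1 proliferative effect, 1
#' vehicle-like growth, 0 complete growth inhibition, -1 complete killing
#' (treated well indistinguishable from the staurosporine control):
#' \deqn{NDR = \frac{2^{\log_2 F_{trt}/\log_2 F_{neg}} - 1}{
#'             1 - 2^{\log_2 F_{pos}/\log_2 F_{neg}}}}
#' The anchors hold exactly: `f_trt = f_pos` gives -1 and `f_trt = 1` gives
#' 0 for any valid controls. `f_pos = 0` is accepted as the complete-kill
#' limit, in which the denominator is 1 and NDR coincides with GR.
#'
#' By construction NDR integrates the plate's own growth rate and seeding
#' density; note that for slow-growing cultures (`f_neg` close to 1) the
#' metric is unstable and an `orgscreen_slow_growth` error is raised at
#' `f_neg <= 1`.
#'
#' @param f_trt treated fold change (>= 0; 0, a fully killed well, maps to
#'   the numerator's complete-kill limit).
#' @param f_neg mean vehicle fold change (> 1).
#' @param f_pos mean staurosporine fold change (>= 0).
#' @return NDR value (vectorized over `f_trt`).
#' @examples
#' ndrMetric(1, 4, 0.25)     # stasis -> 0
#' ndrMetric(0.25, 4, 0.25)  # tracks the kill control -> -1
#' ndrMetric(2, 4, 0.25)     # partial inhibition -> 0.8284
#' @export
ndrMetric <- function(f_trt, f_neg, f_pos) {
  if (any(f_trt < 0)) {
    .orgscreenError("treated fold change must be >= 0", "orgscreen_metric_error")
  }
  if (f_pos < 0) {
    .orgscreenError("positive-control fold change must be >= 0",
                    "orgscreen_metric_error")
  }
  if (f_neg <= 1) {
    .orgscreenError(
      sprintf("negative control did not grow (fold change %.3g <= 1): NDR undefined",
              f_neg),
      c("orgscreen_slow_growth", "orgscreen_metric_error")
    )
  }
  denom <- if (f_pos == 0) 1 else 1 - 2^(log2(f_pos) / log2(f_neg))
  num <- ifelse(f_trt == 0, -1, 2^(log2(f_trt) / log2(f_neg)) - 1)
  num / denom
}

#' Normalized dose-response AUC
#'
#' Trapezoidal integral of the response metric over log10 concentration,
#' divided by the log10 span, so a constant response curve has AUC equal to
#' that constant and AUCs are comparable across regimens with different
#' dose ranges.
#'
#' @param concentration strictly positive, strictly increasing
#'   concentrations (>= 2 values).
#' @param response metric values (typically NDR) at those concentrations.
#' @return normalized AUC (unitless, on the metric's own scale).
#' @export
doseResponseAUC <- function(concentration, response) {
  if (length(concentration) < 2L) {
    .orgscreenError("need at least 2 concentrations", "orgscreen_metric_error")
  }
  if (any(concentration <= 0)) {
    .orgscreenError("concentrations must be strictly positive",
                    "orgscreen_metric_error")
  }
  if (is.unsorted(concentration, strictly = TRUE)) {
    .orgscreenError("concentrations must be strictly increasing (no duplicates)",
                    "orgscreen_metric_error")
  }
  if (length(response) != length(concentration)) {
    .orgscreenError("concentration and response lengths differ",
                    "orgscreen_metric_error")
  }
  lc <- log10(concentration)
  .trapz(lc, response) / diff(range(lc))
}

#' Ratio of two dose-response AUCs
#'
#' Compares a combination regimen against an alternative (e.g. reduced)
#' regimen: a ratio below 1 reads as the combination adding benefit, above
#' 1 as antagonism relative to the alternative.
#'
#' @param combo AUC of the combination regimen.
#' @param alternative AUC of the comparator regimen (non-zero).
#' @return `combo / alternative`.
#' @export
aucRatio <- function(combo, alternative) {
  if (alternative == 0) {
    .orgscreenError("alternative regimen AUC is 0: ratio undefined",
                    "orgscreen_metric_error")
  }
  combo / alternative
}

#' Classify a well's response signature
#'
#' Joint thresholding of the endpoint NDR and percent cell death:
#' \itemize{
#'   \item cytotoxic: NDR < -0.5 and cell death > 40%;
#'   \item mixed: NDR >= -0.5 and cell death > 40% (death detectable but
#'     growth not deeply suppressed);
#'   \item cytostatic: NDR >= 0 and cell death <= 40% (minimal death);
#'   \item indeterminate: everything else.
#' }
#' The rule set is total: every (NDR, cell death) pair receives a label.
#'
#' @param ndr NDR value(s).
#' @param cell_death percent cell death value(s), same length.
#' @param ndr_cut NDR threshold separating cytotoxic from mixed
#'   (default -0.5).
#' @param death_cut cell-death threshold in percent (default 40).
#' @return data.frame with `label`, `ndr`, `cell_death`.
#' @export
classifySignature <- function(ndr, cell_death, ndr_cut = -0.5,
                              death_cut = 40) {
  label <- ifelse(ndr < ndr_cut & cell_death > death_cut, "cytotoxic",
           ifelse(ndr >= ndr_cut & cell_death > death_cut, "mixed",
           ifelse(ndr >= 0 & cell_death <= death_cut, "cytostatic",
                  "indeterminate")))
  data.frame(label = label, ndr = ndr, cell_death = cell_death,
             stringsAsFactors = FALSE)
}

#' Well-level response metrics for a whole screen
#'
#' Computes, for every non-empty well at the requested timepoint(s), the
#' fold change, percent viability, GR, NDR, percent cell death, the
#' response-signature label, and a `proliferative` flag (NDR > 1).
#'
#' @param screen an [OrganoidScreen-class].
#' @param timepoints hours at which to evaluate; default the final
#'   timepoint. The baseline timepoint is excluded (fold change is 1 by
#'   construction there).
#' @param anchorStat "mean" or "median" control averaging.
#' @return data.frame, one row per well x timepoint.
#' @export
wellMetrics <- function(screen, timepoints = NULL,
                        anchorStat = c("mean", "median")) {
  anchorStat <- match.arg(anchorStat)
  anchors <- controlAnchors(screen, stat = anchorStat)
  l <- plateLayout(screen)
  lw <- unique(l[c("plate_id", "well", "role", "regimen", "replicate_id",
                   "patient_id")])
  conc <- tapply(l$concentration, paste(l$plate_id, l$well),
                 function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  rows <- list()
  for (i in seq_len(nrow(lw))) {
    if (lw$role[i] == "empty") next
    ws <- wellSignal(screen, lw$well[i], plate = lw$plate_id[i])
    tps <- if (is.null(timepoints)) max(ws$time_h) else timepoints
    tps <- setdiff(tps, ws$time_h[1L])
    for (tp in tps) {
      j <- which(ws$time_h == tp)
      if (!length(j)) next
      a <- anchors[anchors$plate_id == lw$plate_id[i] &
                     anchors$time_h == tp, ]
      f <- ws$fold_change[j]
      ndr <- ndrMetric(f, a$f_neg, a$f_pos)
      cd <- ws$cell_death[j]
      rows[[length(rows) + 1L]] <- data.frame(
        plate_id = lw$plate_id[i], well = lw$well[i], role = lw$role[i],
        regimen = lw$regimen[i],
        concentration = unname(conc[paste(lw$plate_id[i], lw$well[i])]),
        replicate_id = lw$replicate_id[i], patient_id = lw$patient_id[i],
        time_h = tp, fold_change = f,
        viability = percentViability(f, a$f_neg, a$f_pos),
        gr = grMetric(f, a$f_neg), ndr = ndr, cell_death = cd,
        signature = classifySignature(ndr, cd)$label,
        proliferative = ndr > 1,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-regimen dose-response profiles with normalized AUC
#'
#' Averages the endpoint NDR (and viability) across replicate wells per
#' regimen and concentration, and integrates the NDR curve into the
#' normalized dose-response AUC per regimen.
#'
#' @param screen an [OrganoidScreen-class].
#' @param timepoint endpoint hour; default the final timepoint.
#' @param anchorStat control averaging, "mean" or "median".
#' @return list with `profile` (regimen x concentration table of mean NDR,
#'   GR, viability, cell death) and `auc` (one NDR AUC per regimen).
#' @export
doseResponse <- function(screen, timepoint = NULL,
                         anchorStat = c("mean", "median")) {
  wm <- wellMetrics(screen, timepoints = timepoint,
                    anchorStat = match.arg(anchorStat))
  trt <- wm[wm$role == "treatment", ]
  if (!nrow(trt)) {
    .orgscreenError("no treatment wells in screen", "orgscreen_data_error")
  }
  agg <- aggregate(
    trt[c("ndr", "gr", "viability", "cell_death")],
    by = list(regimen = trt$regimen, concentration = trt$concentration),
    FUN = mean
  )
  agg <- agg[order(agg$regimen, agg$concentration), ]
  rownames(agg) <- NULL
  aucs <- do.call(rbind, lapply(split(agg, agg$regimen), function(d) {
    data.frame(regimen = d$regimen[1L],
               auc = doseResponseAUC(d$concentration, d$ndr),
               stringsAsFactors = FALSE)
  }))
  rownames(aucs) <- NULL
  list(profile = agg, auc = aucs)
}
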