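## Exact small-sample Spearman correlation and clinical concordance.

#' Spearman rank correlation with exact permutation p-value
#'
#' For untied ranks, `rho = 1 - 6 * sum(d^2) / (n^3 - n)`. The two-sided
#' p-value is computed by full enumeration of all n! rank permutations when
#' `n <= n_exact_max` and the ranks are untied:
#' `p = #{permutations with |rho*| >= |rho|} / n!`. With ties, average
#' ranks and the moment (product-moment-of-ranks) coefficient are used with
#' a seeded Monte-Carlo permutation p-value, since the untied null no
#' longer applies. Beyond the exact cap the t approximation is used and the
#' method flagged.
#'
#' Designed for the cohort sizes of clinical organoid screens (n around
#' 7-8), where the exact null matters: asymptotic p-values are unreliable
#' at that scale.
#'
#' @param x,y numeric vectors of equal length n >= 3.
#' @param n_exact_max largest n for full enumeration (default 8, i.e. at
#'   most 40320 permutations).
#' @param n_mc Monte-Carlo permutations for the tied case.
#' @param seed RNG seed for the Monte-Carlo path.
#' @return data.frame with `rho`, `p_two_sided`, `n`, `method`
#'   ("exact", "montecarlo" or "approximate").
#' @examples
#' spearmanExact(1:7, c(1, 2, 3, 4, 5, 7, 6))  # rho 0.9643, p 14/5040
#' @export
spearmanExact <- function(x, y, n_exact_max = 8L, n_mc = 10000L,
                          seed = 1L) {
  if (length(x) != length(y)) {
    .orgscreenError("x and y must have equal length", "orgscreen_data_error")
  }
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    .orgscreenError("need at least 3 pairs", "orgscreen_data_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    .orgscreenError("constant input: rho undefined", "orgscreen_data_error")
  }
  rx <- rank(x); ry <- rank(y)
  tied <- anyDuplicated(rx) || anyDuplicated(ry)
  rho <- cor(rx, ry)
  if (!tied && n <= n_exact_max) {
    perms <- .allPermutations(n)
    d2 <- colSums((t(perms) - ry[order(rx)])^2)
    rho_null <- 1 - 6 * d2 / (n^3 - n)
    p <- sum(abs(rho_null) >= abs(rho) - 1e-12) / nrow(perms)
    method <- "exact"
  } else if (tied && n <= 2L * n_exact_max) {
    set.seed(seed)
    rho_null <- replicate(n_mc, cor(rx, sample(ry)))
    p <- (1 + sum(abs(rho_null) >= abs(rho) - 1e-12)) / (1 + n_mc)
    method <- "montecarlo"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    method <- "approximate"
  }
  data.frame(rho = rho, p_two_sided = min(p, 1), n = n, method = method,
             stringsAsFactors = FALSE)
}

# all permutations of 1..n as a matrix (n! rows); n <= 8 keeps this instant
#' @noRd
.allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .allPermutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(n)) {
    rows <- (r + 1L):(r + nrow(sub))
    out[rows, 1L] <- i
    out[rows, -1L] <- ifelse(sub >= i, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

#' Correlate organoid-derived class fractions with PFS
#'
#' Spearman correlation (exact for small cohorts, see [spearmanExact()]) of
#' percent sensitive, percent resistant and the sensitive:resistant ratio
#' against progression-free survival, across patients. Censored patients
#' are excluded (their PFS is not observed) and the exclusion count
#' reported.
#'
#' @param fractions data.frame with one row per patient: `patient_id`,
#'   `pct_sensitive`, `pct_resistant`, `ratio_sens_res` (e.g. aggregated
#'   from [classFractions()]).
#' @param clinical data.frame from [readClinical()].
#' @return data.frame of three rows (readout, rho, p_two_sided, n, method)
#'   with attribute `n_censored`.
#' @export
correlateWithPFS <- function(fractions, clinical) {
  merged <- merge(fractions, clinical, by = "patient_id")
  n_cens <- sum(merged$censored)
  if (n_cens > 0L) {
    message(sprintf("excluding %d censored patient(s) from PFS correlation",
                    n_cens))
  }
  merged <- merged[!merged$censored, ]
  if (nrow(merged) < 3L) {
    .orgscreenError("fewer than 3 patients with observed PFS",
                    "orgscreen_data_error")
  }
  readouts <- c(pct_sensitive = "pct_sensitive",
                pct_resistant = "pct_resistant",
                ratio_sens_res = "ratio_sens_res")
  rows <- lapply(names(readouts), function(r) {
    res <- spearmanExact(merged[[readouts[[r]]]], merged$pfs_months)
    cbind(data.frame(readout = r, stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_censored") <- n_cens
  out
}

#' Concordance of response signatures with clinical response
#'
#' Maps each patient's ex vivo response-signature label to the expected
#' clinical category (default cytotoxic -> good, mixed -> mixed,
#' cytostatic -> bad) and reports per-patient match/mismatch plus the
#' overall concordant fraction. Patients present in only one table are
#' listed and excluded.
#'
#' @param signatures data.frame: `patient_id`, `label` (cytotoxic, mixed,
#'   cytostatic, indeterminate).
#' @param clinical data.frame from [readClinical()].
#' @param map named character vector mapping signature labels to clinical
#'   response categories.
#' @return list with `table` (per-patient signature, expected and observed
#'   category, match), `fraction` (concordant fraction), `unmatched`
#'   (patient ids excluded).
#' @export
signatureConcordance <- function(signatures, clinical,
                                 map = c(cytotoxic = "good",
                                         mixed = "mixed",
                                         cytostatic = "bad")) {
  common <- intersect(signatures$patient_id, clinical$patient_id)
  unmatched <- union(setdiff(signatures$patient_id, common),
                     setdiff(clinical$patient_id, common))
  if (!length(common)) {
    .orgscreenError(
      sprintf("no shared patient ids; unmatched: %s",
              paste(unmatched, collapse = ", ")),
      "orgscreen_data_error"
    )
  }
  s <- signatures[match(common, signatures$patient_id), ]
  cl <- clinical[match(common, clinical$patient_id), ]
  expected <- unname(map[s$label])
  tab <- data.frame(
    patient_id = common, signature = s$label,
    expected_category = expected,
    observed_category = cl$response_category,
    match = !is.na(expected) & expected == cl$response_category,
    stringsAsFactors = FALSE
  )
  list(table = tab, fraction = mean(tab$match), unmatched = unmatched)
}
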