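# internal helpers shared across modules

#' @keywords internal
#' @noRd
.orgscreenError <- function(msg, class, call. = FALSE, ...) {
  stop(structure(
    class = c(class, "orgscreen_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL, ...)
  ))
}

# normalize well ids to zero-padded "A01" form; rejects malformed ids
#' @noRd
.normalizeWell <- function(well) {
  well <- toupper(trimws(as.character(well)))
  ok <- grepl("^[A-P][0-9]{1,2}$", well)
  if (!all(ok)) {
    .orgscreenError(
      sprintf("malformed well id(s): %s",
              paste(unique(well[!ok]), collapse = ", ")),
      "orgscreen_schema_error"
    )
  }
  row <- substr(well, 1L, 1L)
  col <- as.integer(substr(well, 2L, nchar(well)))
  if (any(col < 1L | col > 24L)) {
    .orgscreenError("well column out of range 1-24", "orgscreen_schema_error")
  }
  sprintf("%s%02d", row, col)
}

# trapezoid integral of y over x
#' @noRd
.trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# stable column-wise standardization, returning scaling parameters
#' @noRd
.scaleColumns <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  list(X = sweep(sweep(X, 2L, ctr), 2L, scl, "/"), center = ctr, scale = scl)
}
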