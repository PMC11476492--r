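#' Write / read cohort tables as delimited text
#'
#' Cohorts round-trip through plain CSV with a header row and empty fields as
#' the missing-value token. `write_cohort()` drops generator-only attributes
#' and records the generating spec and seed in a JSON sidecar
#' (`<path>.json`) when the table carries one.
#'
#' @param table a cohort `data.frame`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  spec <- attr(table, "spec")
  if (!is.null(spec)) {
    jsonlite::write_json(unclass(spec), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  if ("ethnicity" %in% names(out))
    out$ethnicity <- factor(out$ethnicity, levels = ETHNICITY_LEVELS)
  if ("platform" %in% names(out))
    out$platform <- factor(out$platform, levels = PLATFORM_LEVELS)
  if ("label" %in% names(out))
    out$label <- factor(out$label, levels = c("control", "case"))
  class(out) <- c("perisk_cohort", "data.frame")
  out
}

#' Write / read a paired calibration set as two-column CSV
#' @param pairs a `perisk_calpairs` data frame.
#' @param path CSV path.
#' @export
write_calibration_set <- function(pairs, path) {
  write.csv(as.data.frame(pairs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_set
#' @export
read_calibration_set <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("simoa", "elecsys") %in% names(out)))
    stopf("calibration CSV needs columns 'simoa' and 'elecsys'")
  if (anyNA(out) || any(out$simoa <= 0) || any(out$elecsys <= 0))
    stopf("calibration pairs must be complete and positive")
  structure(out, class = c("perisk_calpairs", "data.frame"))
}
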