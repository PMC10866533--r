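#' Timestamped glucose series
#'
#' The central container of the package: a univariate continuous glucose
#' monitoring (CGM) trace with a nominal 5-minute sampling interval. Values
#' are interstitial glucose in mg/dL; `NA` marks a missing sensor reading
#' (allowed only before gap filling). The `role` distinguishes training from
#' test data because several operations (gap filling, normalization) must
#' treat the two differently to avoid using future or held-out information.
#'
#' @param patient_id Character scalar identifying the trace.
#' @param timestamps `POSIXct` vector, strictly increasing.
#' @param values Numeric glucose values in mg/dL; `NA` = missing.
#' @param role `"train"` or `"test"`.
#'
#' @return An object of class `glucose_series`: a list with fields
#'   `patient_id`, `role`, `timestamps`, `values`, plus a `provenance`
#'   attribute recording which preprocessing stages have been applied.
#' @export
glucose_series <- function(patient_id, timestamps, values,
                           role = c("train", "test")) {
  role <- match.arg(role)
  if (!inherits(timestamps, "POSIXct"))
    gs_data_error("'timestamps' must be POSIXct")
  if (length(timestamps) != length(values))
    gs_data_error("'timestamps' and 'values' must have equal length")
  if (is.unsorted(as.numeric(timestamps), strictly = TRUE))
    gs_data_error("'timestamps' must be strictly increasing")
  if (any(!is.na(values) & (!is.finite(values) | values <= 0)))
    gs_data_error("observed glucose values must be finite and > 0")
  structure(
    list(patient_id = as.character(patient_id)[1], role = role,
         timestamps = timestamps, values = as.numeric(values)),
    class = "glucose_series",
    provenance = character(0))
}

#' @export
print.glucose_series <- function(x, ...) {
  n <- length(x$values)
  miss <- sum(is.na(x$values))
  cat(sprintf("<glucose_series> patient %s (%s), %d points", x$patient_id,
              x$role, n))
  if (n) cat(sprintf(", %s to %s", format(x$timestamps[1], usetz = FALSE),
                     format(x$timestamps[n], usetz = FALSE)))
  cat(sprintf("\n  missing: %d; stages applied: %s\n", miss,
              if (length(attr(x, "provenance")))
                paste(attr(x, "provenance"), collapse = " -> ")
              else "none"))
  invisible(x)
}

#' @export
length.glucose_series <- function(x) length(x$values)

#' @export
as.data.frame.glucose_series <- function(x, ...) {
  data.frame(timestamp = x$timestamps, glucose_mg_dl = x$values)
}

#' Provenance stamps
#'
#' Each preprocessing stage appends its tag to the series' `provenance`
#' attribute. In strict mode a stage refuses to run unless its predecessor
#' in the fixed pipeline order (gap_fill -> kalman -> smooth -> normalize)
#' has been applied.
#'
#' @param series A `glucose_series`.
#' @return Character vector of stage tags applied so far.
#' @export
provenance <- function(series) attr(series, "provenance")

stamp_stage <- function(series, stage) {
  attr(series, "provenance") <- c(attr(series, "provenance"), stage)
  series
}

require_stage <- function(series, needed, this, strict) {
  if (strict && !(needed %in% attr(series, "provenance")))
    gs_order_error(sprintf(
      "strict pipeline order: '%s' requires '%s' to have been applied first",
      this, needed))
  invisible(series)
}

# replace values, keeping metadata/provenance
with_values <- function(series, values) {
  series$values <- values
  series
}
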