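#' Read and write CGM series as CSV
#'
#' The on-disk format is a two-column UTF-8 CSV with header
#' `timestamp,glucose_mg_dl`. Timestamps are ISO-8601
#' (`YYYY-MM-DDTHH:MM:SSZ`, UTC); a blank value field marks a missing
#' reading. `write_cgm_csv()` followed by `read_cgm_csv()` reproduces the
#' series exactly.
#'
#' @param path File path.
#' @param patient_id,role Metadata attached to the series on read.
#' @return `read_cgm_csv()` returns a [glucose_series()];
#'   `write_cgm_csv()` returns `path` invisibly.
#' @export
read_cgm_csv <- function(path, patient_id = basename(path), role = "train") {
  if (!file.exists(path)) gs_format_error(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1 || !grepl("^timestamp\\s*,\\s*glucose_mg_dl", lines[1]))
    gs_format_error("CSV must start with a 'timestamp,glucose_mg_dl' header")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  n <- length(body)
  ts <- rep(NA_real_, n); val <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    parts <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    if (length(parts) < 1 || length(parts) > 2)
      gs_format_error(sprintf("line %d: expected 2 comma-separated fields", i + 1))
    tsi <- parse_iso8601(trimws(parts[1]))
    if (is.na(tsi))
      gs_format_error(sprintf("line %d: unparseable timestamp '%s'",
                              i + 1, parts[1]))
    ts[i] <- tsi
    vfield <- if (length(parts) == 2) trimws(parts[2]) else ""
    if (nzchar(vfield)) {
      v <- suppressWarnings(as.numeric(vfield))
      if (is.na(v))
        gs_format_error(sprintf("line %d: non-numeric glucose value '%s'",
                                i + 1, vfield))
      val[i] <- v
    }
  }
  glucose_series(patient_id, as.POSIXct(ts, tz = "UTC",
                                        origin = "1970-01-01"),
                 val, role = role)
}

#' @param series A [glucose_series()].
#' @rdname read_cgm_csv
#' @export
write_cgm_csv <- function(series, path) {
  if (!inherits(series, "glucose_series"))
    gs_data_error("'series' must be a glucose_series")
  ts <- format(series$timestamps, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  val <- ifelse(is.na(series$values), "",
                formatC(series$values, digits = 17, format = "g"))
  writeLines(c("timestamp,glucose_mg_dl", paste(ts, val, sep = ",")),
             path, useBytes = TRUE)
  invisible(path)
}

parse_iso8601 <- function(x) {
  # accept "2024-01-01T00:05:00Z", with offsetless "T" or space separators
  x <- sub("Z$", "", x)
  x <- sub("T", " ", x, fixed = TRUE)
  as.numeric(as.POSIXct(x, tz = "UTC",
                        tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M")))
}

#' Read an OhioT1DM-style XML glucose trace
#'
#' Parses the `glucose_level` element of the public OhioT1DM XML dialect:
#' `event` children carrying `ts` ("dd-mm-yyyy hh:mm:ss") and `value`
#' (mg/dL) attributes. Events are returned in timestamp order; duplicated
#' timestamps keep the first occurrence, with a warning naming how many
#' were dropped.
#'
#' @inheritParams read_cgm_csv
#' @return A [glucose_series()].
#' @export
read_ohio_xml <- function(path, patient_id = NULL, role = "train") {
  if (!file.exists(path)) gs_format_error(sprintf("file not found: %s", path))
  doc <- xml2::read_xml(path)
  node <- if (xml2::xml_name(doc) == "glucose_level") doc
          else xml2::xml_find_first(doc, ".//glucose_level")
  if (inherits(node, "xml_missing") || is.na(xml2::xml_name(node)))
    gs_format_error("no <glucose_level> element found")
  if (is.null(patient_id)) {
    pid <- xml2::xml_attr(doc, "id")
    patient_id <- if (!is.na(pid)) pid else basename(path)
  }
  events <- xml2::xml_find_all(node, ".//event")
  if (length(events) == 0) gs_format_error("<glucose_level> has no <event> children")
  ts <- as.POSIXct(xml2::xml_attr(events, "ts"),
                   format = "%d-%m-%Y %H:%M:%S", tz = "UTC")
  val <- as.numeric(xml2::xml_attr(events, "value"))
  if (anyNA(ts)) gs_format_error("unparseable 'ts' attribute (expected dd-mm-yyyy hh:mm:ss)")
  ord <- order(as.numeric(ts))
  ts <- ts[ord]; val <- val[ord]
  dup <- duplicated(as.numeric(ts))
  if (any(dup)) {
    warning(sprintf("read_ohio_xml: dropped %d duplicate timestamp(s), keeping first occurrence",
                    sum(dup)))
    ts <- ts[!dup]; val <- val[!dup]
  }
  glucose_series(patient_id, ts, val, role = role)
}
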