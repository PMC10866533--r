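#' Root-mean-square and mean absolute error
#'
#' @param y,yhat Equal-length numeric vectors (mg/dL).
#' @return Scalar error in mg/dL.
#' @export
rmse <- function(y, yhat) {
  check_pairs(y, yhat)
  sqrt(mean((y - yhat)^2))
}

#' @rdname rmse
#' @export
mae <- function(y, yhat) {
  check_pairs(y, yhat)
  mean(abs(y - yhat))
}

check_pairs <- function(y, yhat) {
  if (length(y) == 0) gs_data_error("empty input")
  if (length(y) != length(yhat)) gs_data_error("length mismatch")
  invisible(NULL)
}

#' Glycemic band classification
#'
#' IDF bands: low (< 70 mg/dL), normal (70 to < 126 mg/dL), high
#' (>= 126 mg/dL). Low and high constitute the adverse class used by the
#' Matthews correlation coefficient.
#'
#' @param values Positive glucose values, mg/dL.
#' @return Factor with levels `low`, `normal`, `high`, same length/order.
#' @export
classify_bands <- function(values) {
  if (any(values <= 0)) gs_data_error("glucose values must be positive")
  cut(values, breaks = c(0, 70, 126, Inf), labels = c("low", "normal", "high"),
      right = FALSE)
}

#' Matthews correlation coefficient over glycemic bands
#'
#' Both vectors are band-classified and mapped to binary adverse
#' (low or high) versus normal; the MCC is computed from the 2x2 confusion
#' counts with adverse as the positive class. When any denominator factor
#' is zero (a degenerate single-class case) the MCC is defined as 0, the
#' standard convention.
#'
#' @param y,yhat Reference and predicted glucose, mg/dL.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(y, yhat) {
  check_pairs(y, yhat)
  adv_y <- classify_bands(y) != "normal"
  adv_p <- classify_bands(yhat) != "normal"
  mcc_from_counts(tp = sum(adv_y & adv_p), tn = sum(!adv_y & !adv_p),
                  fp = sum(!adv_y & adv_p), fn = sum(adv_y & !adv_p))
}

mcc_from_counts <- function(tp, tn, fp, fn) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Clarke error-grid analysis
#'
#' Assigns each (reference, predicted) pair to exactly one of the clinical
#' risk zones A-E of the Clarke grid. Zone A is clinically accurate
#' (within 20% of the reference, or both values hypoglycemic), E is the
#' dangerous confusion of hypo- and hyperglycemia; B/C/D grade the risk in
#' between. The boundary geometry ships as a rule table
#' (`inst/extdata/clarke_zones.json`): an ordered list of zones, each a
#' disjunction of conjunctions of half-plane predicates
#' `a*ref + b*pred + c (op) 0`, evaluated in fixed precedence
#' A -> E -> C -> D with B as the remainder. Supplying a different table
#' swaps the geometry.
#'
#' @param reference,predicted Paired positive glucose values, mg/dL.
#' @param rules Optional parsed rule table (as from
#'   `jsonlite::read_json(clarke_rules_path())`).
#' @return List with `zones` (factor A-E per pair) and `fractions`
#'   (named proportions over A-E, summing to 1).
#' @export
clarke_ega <- function(reference, predicted, rules = NULL) {
  check_pairs(reference, predicted)
  if (any(reference <= 0) || any(predicted <= 0))
    gs_data_error("glucose values must be positive")
  if (is.null(rules)) rules <- clarke_rules()
  n <- length(reference)
  zone <- rep(NA_character_, n)
  for (z in rules$zones) {
    hit <- rep(FALSE, n)
    for (clause in z$clauses) {
      ok <- rep(TRUE, n)
      for (pr in clause) {
        lhs <- pr$a * reference + pr$b * predicted + pr$c
        ok <- ok & switch(pr$op,
                          le = lhs <= 0, ge = lhs >= 0,
                          lt = lhs < 0,  gt = lhs > 0,
                          gs_format_error(sprintf("unknown op '%s'", pr$op)))
      }
      hit <- hit | ok
    }
    zone[is.na(zone) & hit] <- z$name
  }
  zone[is.na(zone)] <- rules$fallback
  zones <- factor(zone, levels = c("A", "B", "C", "D", "E"))
  fractions <- as.numeric(table(zones)) / n
  names(fractions) <- levels(zones)
  list(zones = zones, fractions = fractions)
}

#' @rdname clarke_ega
#' @export
clarke_rules_path <- function() {
  system.file("extdata", "clarke_zones.json", package = "glucostack",
              mustWork = TRUE)
}

clarke_rules_cache <- new.env(parent = emptyenv())

clarke_rules <- function() {
  if (is.null(clarke_rules_cache$rules))
    clarke_rules_cache$rules <- jsonlite::read_json(clarke_rules_path(),
                                                    simplifyVector = FALSE)
  clarke_rules_cache$rules
}

#' Relative error-band fraction
#'
#' Fraction of pairs whose absolute error is within `pct` percent of the
#' reference; the 10% band marks excellent and the 20% band good clinical
#' prediction quality.
#'
#' @param reference,predicted Paired glucose values, mg/dL.
#' @param pct Band half-width in percent (> 0).
#' @return Fraction in `[0, 1]`.
#' @export
error_band_fraction <- function(reference, predicted, pct) {
  check_pairs(reference, predicted)
  check_scalar(pct, "pct", 0, strict_lower = TRUE)
  mean(abs(predicted - reference) <= pct / 100 * reference)
}

metric_numeric_fields <- function() {
  c("rmse", "mae", "mcc", "zone_a", "zone_b", "zone_c", "zone_d", "zone_e",
    "band10", "band20")
}

#' Full clinical metrics report
#'
#' Bundles RMSE, MAE, glycemic-band MCC, Clarke zone fractions and the
#' 10%/20% error-band fractions for one prediction set (mg/dL scale).
#'
#' @param reference,predicted Paired glucose values, mg/dL.
#' @return A `metrics_report` list.
#' @export
metrics_report <- function(reference, predicted) {
  ega <- clarke_ega(reference, predicted)
  structure(list(rmse = rmse(reference, predicted),
                 mae = mae(reference, predicted),
                 mcc = mcc(reference, predicted),
                 zone_a = unname(ega$fractions["A"]),
                 zone_b = unname(ega$fractions["B"]),
                 zone_c = unname(ega$fractions["C"]),
                 zone_d = unname(ega$fractions["D"]),
                 zone_e = unname(ega$fractions["E"]),
                 band10 = error_band_fraction(reference, predicted, 10),
                 band20 = error_band_fraction(reference, predicted, 20),
                 n = length(reference)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d  rmse %.3f  mae %.3f  mcc %.3f mg/dL\n",
              x$n, x$rmse, x$mae, x$mcc))
  cat(sprintf("  EGA zones: A %.1f%%  B %.1f%%  C %.1f%%  D %.1f%%  E %.1f%%\n",
              100 * x$zone_a, 100 * x$zone_b, 100 * x$zone_c, 100 * x$zone_d,
              100 * x$zone_e))
  cat(sprintf("  within 10%%: %.1f%%   within 20%%: %.1f%%\n",
              100 * x$band10, 100 * x$band20))
  invisible(x)
}
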