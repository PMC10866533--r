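#' Sliding-window specification
#'
#' Supervised framing of the 5-minute series: `history_points` lagged
#' observations are the inputs and the next `horizon_points` observations
#' are the targets. Histories of 6/9/12/18 points correspond to 30/45/60/90
#' minutes; horizons of 6/9/12 points to prediction horizons (PH) of
#' 30/45/60 minutes. Stride is fixed at 1.
#'
#' @param history_points One of 6, 9, 12, 18.
#' @param horizon_points One of 6, 9, 12.
#' @return A `window_spec` list.
#' @export
window_spec <- function(history_points, horizon_points) {
  if (!history_points %in% c(6L, 9L, 12L, 18L))
    gs_config_error("'history_points' must be one of 6, 9, 12, 18")
  if (!horizon_points %in% c(6L, 9L, 12L))
    gs_config_error("'horizon_points' must be one of 6, 9, 12")
  structure(list(history_points = as.integer(history_points),
                 horizon_points = as.integer(horizon_points),
                 step_minutes = 5L, stride = 1L),
            class = "window_spec")
}

#' All history windows for a prediction horizon
#'
#' @param ph_minutes Prediction horizon in minutes: 30, 45 or 60.
#' @return List of four [window_spec()]s (histories 6, 9, 12, 18) with the
#'   horizon matching `ph_minutes`.
#' @export
enumerate_window_specs <- function(ph_minutes) {
  horizon <- switch(as.character(ph_minutes),
                    "30" = 6L, "45" = 9L, "60" = 12L,
                    gs_config_error(sprintf(
                      "unsupported prediction horizon %s; supported: 30, 45, 60",
                      ph_minutes)))
  lapply(c(6L, 9L, 12L, 18L), window_spec, horizon_points = horizon)
}

#' Convert a preprocessed series into supervised samples
#'
#' Builds the `n = L - h - p + 1` stride-1 windows: row `i` of `X` is
#' `v[i..i+h-1]` and row `i` of `Y` is the immediately following
#' `v[i+h..i+h+p-1]`. No resampling or aggregation happens here, so the
#' original series is recoverable from the windows.
#'
#' @param series Gap-free, preprocessed [glucose_series()].
#' @param spec A [window_spec()].
#' @return A `supervised_dataset`: list with matrices `X` (n x h), `Y`
#'   (n x p), the `spec`, a `scale` flag (`"normalized"` if the series was
#'   normalized, else `"mg_dl"`), and `origin` metadata.
#' @export
make_supervised <- function(series, spec) {
  if (!inherits(spec, "window_spec"))
    gs_config_error("'spec' must be a window_spec")
  v <- series$values
  if (anyNA(v)) gs_data_error("make_supervised requires a gap-free series")
  h <- spec$history_points; p <- spec$horizon_points
  L <- length(v)
  n <- L - h - p + 1L
  if (n < 1L)
    gs_data_error(sprintf(
      "series too short: length %d, need at least %d for history %d + horizon %d",
      L, h + p, h, p))
  X <- matrix(0, n, h); Y <- matrix(0, n, p)
  for (j in seq_len(h)) X[, j] <- v[(j):(j + n - 1L)]
  for (j in seq_len(p)) Y[, j] <- v[(h + j):(h + j + n - 1L)]
  structure(list(X = X, Y = Y, spec = spec,
                 scale = if ("normalize" %in% attr(series, "provenance"))
                   "normalized" else "mg_dl",
                 origin = list(patient_id = series$patient_id,
                               role = series$role)),
            class = "supervised_dataset")
}

#' @export
print.supervised_dataset <- function(x, ...) {
  cat(sprintf("<supervised_dataset> %d samples, history %d -> horizon %d (%s, %s)\n",
              nrow(x$X), x$spec$history_points, x$spec$horizon_points,
              x$scale, x$origin$role))
  invisible(x)
}

# row subset keeping class/metadata
subset_dataset <- function(ds, idx) {
  ds$X <- ds$X[idx, , drop = FALSE]
  ds$Y <- ds$Y[idx, , drop = FALSE]
  ds
}

#' Chronological train/validation split of a windowed dataset
#'
#' The chronologically last `val_fraction` of samples (floor rule) becomes
#' the validation set; the earlier samples form the training subset. A
#' chronological rather than random split avoids temporal leakage.
#'
#' @param dataset A `supervised_dataset` with at least 10 samples.
#' @param val_fraction Validation fraction, default 0.2.
#' @return List with `train` and `val` supervised datasets.
#' @export
split_train_val <- function(dataset, val_fraction = 0.2) {
  if (!inherits(dataset, "supervised_dataset"))
    gs_data_error("'dataset' must be a supervised_dataset")
  n <- nrow(dataset$X)
  if (n < 10) gs_data_error("split_train_val needs at least 10 samples")
  n_val <- floor(val_fraction * n + 1e-9)  # guard 0.2 * 100 = 19.999...
  list(train = subset_dataset(dataset, seq_len(n - n_val)),
       val = subset_dataset(dataset, (n - n_val + 1L):n))
}
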