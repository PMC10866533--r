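#' Fill sensor gaps onto an exact 5-minute grid
#'
#' Rebuilds the exact 5-minute grid anchored at the first observation and
#' fills missing points. Training series use linear interpolation between
#' the nearest observed neighbours; test series use causal linear
#' extrapolation from the two most recent observed-or-filled points, so no
#' future value is ever consulted. Timestamps that jitter off the grid are
#' snapped to the nearest grid slot (first occurrence wins on collision).
#'
#' @param series A [glucose_series()] with at least 2 observed points.
#' @return A gap-free `glucose_series` on an exact 5-minute grid, stamped
#'   with the `gap_fill` provenance tag.
#' @export
fill_gaps <- function(series) {
  if (!inherits(series, "glucose_series"))
    gs_data_error("'series' must be a glucose_series")
  obs <- !is.na(series$values)
  if (sum(obs) < 2)
    gs_data_error("fill_gaps needs at least 2 observed points")
  t0 <- series$timestamps[which(obs)[1]]
  # a training series cannot interpolate beyond its last observation, but a
  # test series extrapolates forward through trailing gaps
  tn <- if (series$role == "train") series$timestamps[max(which(obs))]
        else max(series$timestamps)
  slot <- as.integer(round(as.numeric(series$timestamps - t0, units = "secs") / 300))
  n_grid <- as.integer(round(as.numeric(tn - t0, units = "secs") / 300)) + 1L
  vals <- rep(NA_real_, n_grid)
  for (i in seq_along(slot)) {
    s <- slot[i] + 1L
    if (s >= 1L && s <= n_grid && is.na(vals[s]) && !is.na(series$values[i]))
      vals[s] <- series$values[i]
  }
  filled <- if (series$role == "train") {
    idx <- which(!is.na(vals))
    stats::approx(idx, vals[idx], xout = seq_len(n_grid), rule = 2)$y
  } else {
    v <- vals
    for (i in seq_len(n_grid)) {
      if (is.na(v[i])) {
        v[i] <- if (i >= 3) v[i - 1] + (v[i - 1] - v[i - 2]) else v[i - 1]
      }
    }
    v
  }
  filled <- pmax(filled, 1e-6)  # glucose stays positive after extrapolation
  out <- glucose_series(series$patient_id, t0 + 300 * (seq_len(n_grid) - 1),
                        filled, role = series$role)
  attr(out, "provenance") <- attr(series, "provenance")
  stamp_stage(out, "gap_fill")
}

#' Scalar Kalman filter configuration
#'
#' Configuration of the forward scalar Kalman filter used to attenuate CGM
#' sensor noise. The state is the (scalar) latent glucose level; the
#' defaults assume a random-walk state (`A = 1`), direct observation
#' (`H = 1`), no control input, a small process noise `Q = 0.1` (mg/dL)^2
#' and observation noise `R = 4` (mg/dL)^2, i.e. roughly a 2 mg/dL sensor
#' noise standard deviation. `x0` defaults to the first observation and
#' `P0` to `R`.
#'
#' @param A,B,u,H Scalar state transition, control matrix, control input
#'   and observation map.
#' @param Q,R Process / observation noise variances, must be nonnegative.
#' @param x0,P0 Initial state (mg/dL) and covariance; `NULL` x0 means
#'   "first observation".
#' @return A `kalman_config` list.
#' @export
kalman_config <- function(A = 1, B = 0, u = 0, H = 1, Q = 0.1, R = 4,
                          x0 = NULL, P0 = R) {
  check_scalar(A, "A"); check_scalar(B, "B"); check_scalar(u, "u")
  check_scalar(H, "H")
  check_scalar(Q, "Q", lower = 0)
  check_scalar(R, "R", lower = 0)
  if (!is.null(x0)) check_scalar(x0, "x0")
  check_scalar(P0, "P0", lower = 0, strict_lower = TRUE)
  structure(list(A = A, B = B, u = u, H = H, Q = Q, R = R, x0 = x0, P0 = P0),
            class = "kalman_config")
}

#' Forward scalar Kalman filter
#'
#' Runs the two-phase predict/update recursion over a gap-free series:
#' predict `x_bar = A x + B u`, `P_bar = A P A + Q`; gain
#' `K = P_bar H / (H P_bar H + R)`; update `x = x_bar + K (z - H x_bar)`,
#' `P = (1 - K H) P_bar`. Forward filter only (no backward smoothing pass).
#'
#' @param series Gap-free [glucose_series()].
#' @param config A [kalman_config()].
#' @param strict Enforce that gap filling has already been applied.
#' @return Filtered series of the same length, stamped `kalman`.
#' @export
kalman_smooth <- function(series, config = kalman_config(), strict = FALSE) {
  if (!inherits(config, "kalman_config"))
    gs_config_error("'config' must be a kalman_config")
  require_stage(series, "gap_fill", "kalman", strict)
  z <- series$values
  if (anyNA(z)) gs_data_error("kalman_smooth requires a gap-free series")
  x <- if (is.null(config$x0)) z[1] else config$x0
  P <- config$P0
  out <- numeric(length(z))
  A <- config$A; B <- config$B; u <- config$u; H <- config$H
  Q <- config$Q; R <- config$R
  for (k in seq_along(z)) {
    xbar <- A * x + B * u
    Pbar <- A * P * A + Q
    K <- (Pbar * H) / (H * Pbar * H + R)
    x <- xbar + K * (z[k] - H * xbar)
    P <- (1 - K * H) * Pbar
    out[k] <- x
  }
  stamp_stage(with_values(series, out), "kalman")
}

#' Holt double exponential smoothing configuration
#'
#' @param level_alpha Level smoothing coefficient, strictly in (0, 1);
#'   default 0.1.
#' @param trend_beta Trend smoothing coefficient, strictly in (0, 1);
#'   default 0.5.
#' @return A `smoothing_config` list.
#' @export
smoothing_config <- function(level_alpha = 0.1, trend_beta = 0.5) {
  check_scalar(level_alpha, "level_alpha", 0, 1, TRUE, TRUE)
  check_scalar(trend_beta, "trend_beta", 0, 1, TRUE, TRUE)
  structure(list(level_alpha = level_alpha, trend_beta = trend_beta,
                 init_policy = "first_two_points"),
            class = "smoothing_config")
}

#' Holt double exponential smoothing
#'
#' Level/trend recursion `L_t = a Y_t + (1-a)(L_{t-1} + T_{t-1})`,
#' `T_t = b (L_t - L_{t-1}) + (1-b) T_{t-1}`, output `Y'_t = L_t + T_t`.
#' Initialization is `L_1 = Y_1`, `T_1 = Y_2 - Y_1`, which makes exactly
#' linear series invariant up to the one-step-ahead shift implied by the
#' output form (a ramp `Y_t = c t` maps to `c t + c`). The output is applied
#' as written, with no re-alignment.
#'
#' @param series Gap-free [glucose_series()] of length >= 2.
#' @param config A [smoothing_config()].
#' @param strict Enforce that Kalman filtering has already been applied.
#' @return Smoothed series of equal length, stamped `smooth`.
#' @export
double_exp_smooth <- function(series, config = smoothing_config(),
                              strict = FALSE) {
  if (!inherits(config, "smoothing_config"))
    gs_config_error("'config' must be a smoothing_config")
  require_stage(series, "kalman", "smooth", strict)
  y <- series$values
  if (anyNA(y)) gs_data_error("double_exp_smooth requires a gap-free series")
  if (length(y) < 2) gs_data_error("double_exp_smooth needs length >= 2")
  a <- config$level_alpha; b <- config$trend_beta
  n <- length(y)
  L <- y[1]; Tr <- y[2] - y[1]
  out <- numeric(n)
  out[1] <- L + Tr
  for (t in 2:n) {
    Lprev <- L
    L <- a * y[t] + (1 - a) * (L + Tr)
    Tr <- b * (L - Lprev) + (1 - b) * Tr
    out[t] <- L + Tr
  }
  stamp_stage(with_values(series, out), "smooth")
}

#' Min-max normalization fitted on training data
#'
#' `fit_normalizer()` learns the (min, max) bounds from a training series
#' only; `normalize_values()` maps `v -> (v - vmin) / (vmax - vmin)` and
#' `denormalize_values()` inverts it. Test values outside the training range
#' map outside `[0, 1]` and are deliberately not clipped.
#'
#' @param train A training-role [glucose_series()].
#' @return A `normalization_params` list with `vmin`, `vmax`.
#' @export
fit_normalizer <- function(train) {
  if (!inherits(train, "glucose_series"))
    gs_data_error("'train' must be a glucose_series")
  if (train$role != "train")
    gs_data_error("normalization bounds must be fitted on training data only")
  v <- train$values[!is.na(train$values)]
  vmin <- min(v); vmax <- max(v)
  if (vmax <= vmin)
    gs_data_error("degenerate range: vmax must exceed vmin")
  structure(list(vmin = vmin, vmax = vmax), class = "normalization_params")
}

#' @param values Numeric vector or matrix.
#' @param params A `normalization_params` object.
#' @rdname fit_normalizer
#' @export
normalize_values <- function(values, params) {
  (values - params$vmin) / (params$vmax - params$vmin)
}

#' @rdname fit_normalizer
#' @export
denormalize_values <- function(values, params) {
  values * (params$vmax - params$vmin) + params$vmin
}

#' @param series A [glucose_series()] to rescale.
#' @param strict Enforce that smoothing has already been applied.
#' @rdname fit_normalizer
#' @export
normalize_series <- function(series, params, strict = FALSE) {
  require_stage(series, "smooth", "normalize", strict)
  out <- with_values(series, normalize_values(series$values, params))
  stamp_stage(out, "normalize")
}

#' Run the fixed preprocessing pipeline on a series
#'
#' Convenience wrapper applying the stages in their fixed order:
#' gap filling, Kalman filtering, then double exponential smoothing
#' (normalization is separate because its bounds must come from training
#' data).
#'
#' @param series A [glucose_series()].
#' @param kalman A [kalman_config()].
#' @param smoothing A [smoothing_config()].
#' @return Preprocessed series carrying provenance
#'   `gap_fill -> kalman -> smooth`.
#' @export
preprocess_series <- function(series, kalman = kalman_config(),
                              smoothing = smoothing_config()) {
  double_exp_smooth(kalman_smooth(fill_gaps(series), kalman, strict = TRUE),
                    smoothing, strict = TRUE)
}
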