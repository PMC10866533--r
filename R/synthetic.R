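#' Synthetic CGM generator configuration
#'
#' Parameters of the seeded synthetic continuous glucose monitoring trace.
#' The generated signal is a baseline plus a circadian sinusoid, plus meal
#' excursions (difference-of-exponentials impulses at Poisson-distributed
#' meal times), plus AR(1) sensor noise; a random fraction of grid points is
#' then dropped to emulate sensor gaps, and values are clipped to the
#' 40-400 mg/dL CGM dynamic range.
#'
#' Defaults describe a plausible adult trace: one week of data, 140 mg/dL
#' baseline, 15 mg/dL circadian swing, three meals a day peaking 80 mg/dL
#' above baseline with a 20-minute rise and 90-minute decay, 2 mg/dL AR(1)
#' sensor noise, and 2% missing readings.
#'
#' @param duration_days Whole days of data (288 points/day at 5 minutes).
#' @param baseline Baseline glucose, mg/dL.
#' @param circadian_amplitude Amplitude of the 24-hour sinusoid, mg/dL.
#' @param meal_rate Expected meals per day (homogeneous Poisson process).
#' @param meal_peak Peak excursion height above baseline, mg/dL.
#' @param meal_rise_tau,meal_decay_tau Rise/decay time constants, minutes.
#' @param noise_sd Stationary standard deviation of the AR(1) noise, mg/dL.
#' @param noise_ar1 AR(1) coefficient in `[0, 1)`.
#' @param missing_fraction Probability that a grid point is dropped.
#' @param seed Integer seed; generation is bitwise reproducible per seed.
#'
#' @return A `synth_config` list.
#' @export
synth_config <- function(duration_days = 7, baseline = 140,
                         circadian_amplitude = 15, meal_rate = 3,
                         meal_peak = 80, meal_rise_tau = 20,
                         meal_decay_tau = 90, noise_sd = 2,
                         noise_ar1 = 0.5, missing_fraction = 0.02,
                         seed = 1L) {
  check_scalar(duration_days, "duration_days", lower = 1)
  check_scalar(baseline, "baseline", lower = 0)
  check_scalar(circadian_amplitude, "circadian_amplitude", lower = 0)
  check_scalar(meal_rate, "meal_rate", lower = 0)
  check_scalar(meal_peak, "meal_peak", lower = 0)
  check_scalar(meal_rise_tau, "meal_rise_tau", lower = 0, strict_lower = TRUE)
  check_scalar(meal_decay_tau, "meal_decay_tau", lower = 0, strict_lower = TRUE)
  if (meal_decay_tau <= meal_rise_tau)
    gs_config_error("'meal_decay_tau' must exceed 'meal_rise_tau'")
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(noise_ar1, "noise_ar1", lower = 0, upper = 1, strict_upper = TRUE)
  check_scalar(missing_fraction, "missing_fraction", lower = 0, upper = 1,
               strict_upper = TRUE)
  check_scalar(seed, "seed")
  structure(list(duration_days = duration_days, baseline = baseline,
                 circadian_amplitude = circadian_amplitude,
                 meal_rate = meal_rate, meal_peak = meal_peak,
                 meal_rise_tau = meal_rise_tau,
                 meal_decay_tau = meal_decay_tau, noise_sd = noise_sd,
                 noise_ar1 = noise_ar1, missing_fraction = missing_fraction,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# unit-peak meal impulse: difference of exponentials, normalized so the
# maximum (at t* = log(d/r) * r*d/(d-r)) equals 1
meal_impulse <- function(t_min, rise, decay) {
  tstar <- log(decay / rise) * rise * decay / (decay - rise)
  peak <- exp(-tstar / decay) - exp(-tstar / rise)
  out <- numeric(length(t_min))
  pos <- t_min >= 0
  out[pos] <- (exp(-t_min[pos] / decay) - exp(-t_min[pos] / rise)) / peak
  out
}

#' Generate a synthetic CGM series
#'
#' @param config A [synth_config()].
#' @param patient_id Identifier for the generated trace.
#' @param role Series role, `"train"` or `"test"`.
#' @param start Start time of the 5-minute grid.
#'
#' @return A [glucose_series()] on a 5-minute grid with `missing_fraction`
#'   of the grid points dropped (gaps), clipped to 40-400 mg/dL.
#' @export
#' @examples
#' s <- generate_cgm(synth_config(duration_days = 2, seed = 42))
#' range(s$values)
generate_cgm <- function(config, patient_id = "synthetic", role = "train",
                         start = as.POSIXct("2024-01-01 00:00:00", tz = "UTC")) {
  if (!inherits(config, "synth_config"))
    gs_config_error("'config' must be a synth_config")
  n <- as.integer(round(config$duration_days * 288))
  t_min <- (seq_len(n) - 1) * 5                       # minutes since start
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  hours <- (t_min / 60) %% 24
  circadian <- config$circadian_amplitude * sin(2 * pi * (hours - 10) / 24)

  meals <- numeric(n)
  n_meals <- stats::rpois(1, config$meal_rate * config$duration_days)
  if (n_meals > 0 && config$meal_peak > 0) {
    meal_times <- sort(stats::runif(n_meals, 0, max(t_min)))
    for (mt in meal_times)
      meals <- meals + config$meal_peak *
        meal_impulse(t_min - mt, config$meal_rise_tau, config$meal_decay_tau)
  }

  noise <- numeric(n)
  if (config$noise_sd > 0) {
    innov_sd <- config$noise_sd * sqrt(1 - config$noise_ar1^2)
    eps <- stats::rnorm(n, 0, innov_sd)
    noise[1] <- stats::rnorm(1, 0, config$noise_sd)
    if (n > 1) for (i in 2:n) noise[i] <- config$noise_ar1 * noise[i - 1] + eps[i]
  }

  values <- pmin(400, pmax(40, config$baseline + circadian + meals + noise))
  keep <- stats::runif(n) >= config$missing_fraction
  if (sum(keep) < 2) gs_data_error("missing_fraction left fewer than 2 points")
  glucose_series(patient_id,
                 start + (t_min[keep] * 60),
                 values[keep], role = role)
}

# preserve the caller's RNG stream across seeded generation
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
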