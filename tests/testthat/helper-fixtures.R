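# Shared fixtures and independent oracles. Every oracle here is coded
# directly from the defining recursion/rule set, independently of the
# package implementation it checks.

t0_utc <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")

`%||%` <- function(a, b) if (is.null(a)) b else a

series_from_values <- function(values, role = "train", start = t0_utc,
                               step_sec = 300) {
  glucose_series("fixture", start + step_sec * (seq_along(values) - 1),
                 values, role = role)
}

# plain scalar Kalman recursion, straight from the predict/update equations
kalman_oracle <- function(z, A = 1, B = 0, u = 0, H = 1, Q = 0.1, R = 4,
                          x0 = z[1], P0 = R) {
  x <- x0; P <- P0
  xs <- numeric(length(z)); Ps <- numeric(length(z))
  for (k in seq_along(z)) {
    xbar <- A * x + B * u
    Pbar <- A * P * A + Q
    K <- Pbar * H / (H * Pbar * H + R)
    x <- xbar + K * (z[k] - H * xbar)
    P <- (1 - K * H) * Pbar
    xs[k] <- x; Ps[k] <- P
  }
  list(x = xs, P = Ps)
}

# direct Holt level/trend recursion with L1 = Y1, T1 = Y2 - Y1
holt_oracle <- function(y, a, b) {
  L <- y[1]; Tr <- y[2] - y[1]
  out <- numeric(length(y))
  out[1] <- L + Tr
  for (t in 2:length(y)) {
    Lp <- L
    L <- a * y[t] + (1 - a) * (L + Tr)
    Tr <- b * (L - Lp) + (1 - b) * Tr
    out[t] <- L + Tr
  }
  out
}

# exhaustive exemplar-subset search maximizing net similarity (n <= 8)
ap_brute_force <- function(S) {
  n <- nrow(S)
  best <- -Inf; best_set <- NULL
  for (mask in 1:(2^n - 1)) {
    ex <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    val <- net_similarity(S, ex)
    if (val > best) { best <- val; best_set <- ex }
  }
  list(value = best, exemplars = best_set)
}

# independently coded canonical Clarke grid (nested conditions, not the
# package's rule table)
clarke_oracle <- function(r, p) {
  if ((r <= 70 && p <= 70) || (p <= 1.2 * r && p >= 0.8 * r)) "A"
  else if ((r >= 180 && p <= 70) || (r <= 70 && p >= 180)) "E"
  else if ((r >= 70 && r <= 290 && p >= r + 110) ||
           (r >= 130 && r <= 180 && p <= (7 / 5) * r - 182)) "C"
  else if ((r >= 240 && p >= 70 && p <= 180) ||
           (r <= 175 / 3 && p >= 70 && p <= 180) ||
           (r >= 175 / 3 && r <= 70 && p >= (6 / 5) * r)) "D"
  else "B"
}

# tiny supervised dataset on the normalized scale with exactly n samples
toy_dataset <- function(n = 20, h = 6, p = 6, seed = 1, fun = NULL) {
  set.seed(seed)
  len <- n + h + p - 1
  v <- if (is.null(fun)) 0.5 + 0.3 * sin(seq_len(len) / 5) else fun(len)
  s <- series_from_values(v * 100 + 100)
  s$values <- v  # already-normalized toy values
  attr(s, "provenance") <- c("gap_fill", "kalman", "smooth", "normalize")
  make_supervised(s, window_spec(h, p))
}

# a micro synthetic train/test pair for pipeline-level tests
micro_series_pair <- function(seed = 1, days = 2) {
  s <- generate_cgm(synth_config(duration_days = days, seed = seed,
                                 missing_fraction = 0.01))
  split_series(s, 0.2)
}

# micro plan: tiny epoch budget, cheap architectures
micro_plan <- function(seed = 1, archs = c("vlstm", "stacklstm"),
                       max_epochs = 2) {
  stacking_plan(ph_minutes = 30, architectures = archs,
                max_epochs = max_epochs, early_stop_patience = Inf,
                seed = seed)
}
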