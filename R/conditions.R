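# Structured conditions so callers (and the CLI) can branch on failure class
# without parsing messages.

gs_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "gs_error"), call = call))
}

gs_config_error <- function(msg) gs_stop(msg, "gs_config_error", sys.call(-1))
gs_data_error   <- function(msg) gs_stop(msg, "gs_data_error",   sys.call(-1))
gs_format_error <- function(msg) gs_stop(msg, "gs_format_error", sys.call(-1))
gs_order_error  <- function(msg) gs_stop(msg, "gs_order_error",  sys.call(-1))

# scalar finite numeric check used by the config constructors
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE,
                         allow_inf = FALSE) {
  ok_value <- is.numeric(x) && length(x) == 1L &&
    (is.finite(x) || (allow_inf && is.infinite(x) && x > 0))
  if (!ok_value)
    gs_config_error(sprintf("'%s' must be a single finite number", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    gs_config_error(sprintf(
      "'%s' = %g is outside its allowed range %s%g, %g%s", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"))
  invisible(x)
}
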