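# Internal helpers: classed error conditions and scoped RNG.

stop_reg <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "regpoincare_error"),
                      call = call))
}

config_error <- function(msg) stop_reg("regpoincare_config_error", msg)
too_short_error <- function(msg) stop_reg("regpoincare_too_short_error", msg)
insufficient_pulses_error <- function(msg)
  stop_reg("regpoincare_insufficient_pulses_error", msg)
lag_error <- function(msg) stop_reg("regpoincare_lag_error", msg)
degenerate_plot_error <- function(msg)
  stop_reg("regpoincare_degenerate_plot_error", msg)
no_period_error <- function(msg) stop_reg("regpoincare_no_period_error", msg)
criterion_error <- function(msg) stop_reg("regpoincare_criterion_error", msg)
class_error <- function(msg) stop_reg("regpoincare_class_error", msg)
insufficient_data_error <- function(msg)
  stop_reg("regpoincare_insufficient_data_error", msg)

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# With seed = NULL the global RNG stream is used untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Extract a numeric sample vector and sampling rate from a reg_record,
# reg_segment or plain numeric vector (then `fs` must be supplied).
as_samples <- function(x, fs = NULL) {
  if (inherits(x, c("reg_record", "reg_segment")))
    return(list(samples = x$samples, fs = x$sampling_rate,
                label = x$label %||% "unknown"))
  if (is.numeric(x)) {
    if (is.null(fs)) config_error("sampling rate `fs` required for a bare numeric signal")
    return(list(samples = as.numeric(x), fs = fs, label = "unknown"))
  }
  config_error("expected a reg_record, reg_segment or numeric vector")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
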