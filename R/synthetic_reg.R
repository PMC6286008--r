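#' Configuration for the synthetic REG generator
#'
#' Builds and validates the parameter set used by [generate_record()].
#' Defaults emulate a resting adult: pulse period 0.99 s (between-segment
#' SD 0.12 s), per-pulse amplitude range just under 0.1 ohm, sampled at
#' 250 Hz in 16-s segments.
#'
#' The two regimes differ in their beat-to-beat variability structure:
#' in the `"apnea"` regime a correlated AR(1) modulation (coefficient
#' `ar_coefficient`, realized strength `regime_modulation`) is
#' superimposed on beat amplitudes (factor `1 + m`) and beat periods
#' (factor `1 - m`), so that pulse slopes - and with them the short-term
#' Poincare descriptors at small lags - become more variable than at
#' baseline. The modulation path is standardized per record, so
#' `regime_modulation` is the realized SD of the multiplicative
#' modulation.
#'
#' @param sampling_rate sampling frequency in Hz.
#' @param duration record length in seconds.
#' @param period_mean mean pulse period in seconds.
#' @param period_sd between-segment SD of the period (seconds); used by
#'   [generate_dataset()] when drawing per-segment configurations.
#' @param period_jitter_sd beat-to-beat period jitter SD (seconds).
#' @param pulse_range_mean mean per-pulse amplitude range (max - min) in
#'   ohms; `NULL` selects the regime default (0.092 apnea, 0.099
#'   baseline), while an explicit value also overrides the per-regime
#'   centers used by [generate_dataset()].
#' @param pulse_range_sd between-segment SD of the pulse range (ohms).
#' @param rise_fraction anacrotic (rising) phase as a fraction of the
#'   period, in (0, 1).
#' @param regime `"baseline"` or `"apnea"`.
#' @param regime_modulation strength (realized SD) of the correlated
#'   beat-to-beat modulation applied in the apnea regime; >= 0.
#' @param amplitude_jitter_sd relative SD of independent beat-to-beat
#'   amplitude jitter (both regimes).
#' @param drift_amplitude amplitude of a slow sinusoidal baseline drift
#'   (ohms).
#' @param drift_frequency drift frequency in Hz (< 0.1 so the band
#'   limiting removes it).
#' @param noise_sd additive white noise SD (ohms).
#' @param ar_coefficient AR(1) coefficient of the apnea modulation path.
#' @param seed integer seed making [generate_record()] deterministic;
#'   `NULL` uses the current RNG stream.
#'
#' @return An object of class `synth_config` (a named list).
#' @export
#' @examples
#' cfg <- synth_config(duration = 4, regime = "apnea", seed = 1)
#' rec <- generate_record(cfg)
synth_config <- function(sampling_rate = 250,
                         duration = 16,
                         period_mean = 0.99,
                         period_sd = 0.12,
                         period_jitter_sd = 0.02,
                         pulse_range_mean = NULL,
                         pulse_range_sd = 0.015,
                         rise_fraction = 0.22,
                         regime = c("baseline", "apnea"),
                         regime_modulation = 0.3,
                         amplitude_jitter_sd = 0.02,
                         drift_amplitude = 0.005,
                         drift_frequency = 0.05,
                         noise_sd = 0.002,
                         ar_coefficient = 0.9,
                         seed = NULL) {
  regime <- match.arg(regime)
  pulse_range_explicit <- !is.null(pulse_range_mean)
  if (is.null(pulse_range_mean))
    pulse_range_mean <- if (regime == "apnea") 0.092 else 0.099
  cfg <- list(sampling_rate = sampling_rate, duration = duration,
              period_mean = period_mean, period_sd = period_sd,
              period_jitter_sd = period_jitter_sd,
              pulse_range_mean = pulse_range_mean,
              pulse_range_explicit = pulse_range_explicit,
              pulse_range_sd = pulse_range_sd,
              rise_fraction = rise_fraction, regime = regime,
              regime_modulation = regime_modulation,
              amplitude_jitter_sd = amplitude_jitter_sd,
              drift_amplitude = drift_amplitude,
              drift_frequency = drift_frequency,
              noise_sd = noise_sd, ar_coefficient = ar_coefficient,
              seed = seed)
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!num1(cfg$sampling_rate) || cfg$sampling_rate <= 0)
    config_error("sampling_rate must be a positive number")
  if (!num1(cfg$duration) || cfg$duration <= 0)
    config_error("duration must be a positive number")
  if (!num1(cfg$period_mean) || cfg$period_mean <= 0)
    config_error("period_mean must be a positive number")
  if (!num1(cfg$rise_fraction) ||
      cfg$rise_fraction <= 0 || cfg$rise_fraction >= 1)
    config_error("rise_fraction must lie strictly between 0 and 1")
  if (!num1(cfg$pulse_range_mean) || cfg$pulse_range_mean <= 0)
    config_error("pulse_range_mean must be a positive number")
  for (f in c("period_sd", "period_jitter_sd", "pulse_range_sd",
              "regime_modulation", "amplitude_jitter_sd",
              "drift_amplitude", "noise_sd")) {
    if (!num1(cfg[[f]]) || cfg[[f]] < 0)
      config_error(sprintf("%s must be a non-negative number", f))
  }
  if (!num1(cfg$drift_frequency) || cfg$drift_frequency < 0)
    config_error("drift_frequency must be non-negative")
  if (!num1(cfg$ar_coefficient) || abs(cfg$ar_coefficient) >= 1)
    config_error("ar_coefficient must lie in (-1, 1)")
  invisible(cfg)
}

# Asymmetric pulse template on n samples in [0, 1]: half-cosine rise over
# the first `rise_fraction` of the beat, then exponential-like decay back
# to the foot. Starts and ends at 0, peak 1.
pulse_template <- function(n, rise_fraction, decay_rate = 3) {
  s <- (seq_len(n) - 1) / n
  y <- numeric(n)
  r <- s < rise_fraction
  y[r] <- 0.5 * (1 - cos(pi * s[r] / rise_fraction))
  sd_ <- (s[!r] - rise_fraction) / (1 - rise_fraction)
  y[!r] <- (exp(-decay_rate * sd_) - exp(-decay_rate)) /
    (1 - exp(-decay_rate))
  y
}

#' Generate one synthetic REG record
#'
#' Concatenates per-beat pulse templates (fast anacrotic rise, slower
#' decay), each rescaled so the beat's max - min equals its drawn pulse
#' range exactly, then adds sinusoidal baseline drift and white noise.
#' In the apnea regime a standardized AR(1) modulation is applied to
#' beat amplitudes and (with opposite sign) beat periods.
#'
#' @param config a [synth_config()].
#' @return An object of class `reg_record`: list with `samples` (ohms),
#'   `sampling_rate` (Hz), `label` and `meta` (the config and seed).
#' @export
#' @examples
#' rec <- generate_record(synth_config(duration = 4, seed = 7))
#' length(rec$samples)  # 4 s x 250 Hz = 1000
generate_record <- function(config) {
  validate_synth_config(config)
  with_seed(config$seed, {
    fs <- config$sampling_rate
    n_total <- round(config$duration * fs)
    if (n_total < 2) config_error("duration x sampling_rate must be >= 2 samples")
    n_beats <- ceiling(config$duration / (config$period_mean * 0.4)) + 4

    m <- rep(0, n_beats)
    if (config$regime == "apnea" && config$regime_modulation > 0 &&
        n_beats >= 3) {
      phi <- config$ar_coefficient
      z <- numeric(n_beats)
      z[1] <- rnorm(1)
      innov <- rnorm(n_beats - 1, sd = sqrt(1 - phi^2))
      for (i in 2:n_beats) z[i] <- phi * z[i - 1] + innov[i - 1]
      if (sd(z) > 0)
        m <- config$regime_modulation * (z - mean(z)) / sd(z)
    }

    periods <- (config$period_mean +
                  rnorm(n_beats, 0, config$period_jitter_sd)) *
      pmin(1.75, pmax(0.25, 1 - m))
    periods <- pmax(periods, 0.25 * config$period_mean)
    ranges <- config$pulse_range_mean *
      (1 + rnorm(n_beats, 0, config$amplitude_jitter_sd)) *
      pmax(0.1, 1 + m)

    x <- numeric(0)
    for (i in seq_len(n_beats)) {
      nb <- max(4L, as.integer(round(periods[i] * fs)))
      beat <- pulse_template(nb, config$rise_fraction)
      beat <- beat * (ranges[i] / (max(beat) - min(beat)))
      x <- c(x, beat)
      if (length(x) >= n_total) break
    }
    if (length(x) < n_total)
      x <- c(x, rep(0, n_total - length(x)))
    x <- x[seq_len(n_total)]

    t <- (seq_len(n_total) - 1) / fs
    if (config$drift_amplitude > 0)
      x <- x + config$drift_amplitude *
        sin(2 * pi * config$drift_frequency * t)
    if (config$noise_sd > 0)
      x <- x + rnorm(n_total, 0, config$noise_sd)

    structure(list(samples = x, sampling_rate = fs,
                   label = config$regime,
                   meta = list(config = config, seed = config$seed)),
              class = "reg_record")
  })
}

#' Generate a labeled dataset of synthetic REG segments
#'
#' Draws one configuration per segment - its mean period from
#' `N(period_mean, period_sd)` and its mean pulse range from the regime
#' default with SD `pulse_range_sd` (both truncated away from zero) -
#' and generates each segment with an independent sub-seed derived from
#' `seed`, so the whole dataset is reproducible.
#'
#' @param n_apnea,n_baseline number of segments per regime.
#' @param segment_seconds segment length in seconds.
#' @param base_config template [synth_config()] supplying everything but
#'   the per-segment draws.
#' @param seed integer master seed; `NULL` uses the current RNG stream.
#' @return A list of `reg_segment` objects (see [as_segment()]), apnea
#'   segments first.
#' @export
#' @examples
#' segs <- generate_dataset(2, 2, segment_seconds = 8, seed = 1)
#' sapply(segs, function(s) s$label)
generate_dataset <- function(n_apnea = 29, n_baseline = 24,
                             segment_seconds = 16,
                             base_config = synth_config(),
                             seed = NULL) {
  if (n_apnea < 0 || n_baseline < 0)
    config_error("segment counts must be non-negative")
  n <- n_apnea + n_baseline
  if (n == 0) return(list())
  with_seed(seed, {
    labels <- c(rep("apnea", n_apnea), rep("baseline", n_baseline))
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      cfg <- base_config
      cfg$regime <- labels[i]
      cfg$duration <- segment_seconds
      cfg$period_mean <- max(0.4, rnorm(1, base_config$period_mean,
                                        base_config$period_sd))
      range_center <- if (isTRUE(base_config$pulse_range_explicit))
        base_config$pulse_range_mean
      else if (labels[i] == "apnea") 0.092 else 0.099
      cfg$pulse_range_mean <- max(0.02, rnorm(1, range_center,
                                              base_config$pulse_range_sd))
      cfg$seed <- sub_seeds[i]
      as_segment(generate_record(cfg), source_offset = 0L)
    })
  })
}

#' Coerce a record to a segment
#'
#' @param record a `reg_record`.
#' @param source_offset 0-based sample offset of the segment within its
#'   parent record.
#' @return A `reg_segment`: list with `samples`, `sampling_rate`,
#'   `label`, `source_offset`.
#' @export
as_segment <- function(record, source_offset = 0L) {
  structure(list(samples = record$samples,
                 sampling_rate = record$sampling_rate,
                 label = record$label %||% "unknown",
                 source_offset = as.integer(source_offset)),
            class = "reg_segment")
}

#' @export
print.reg_record <- function(x, ...) {
  cat(sprintf("<reg_record> %d samples @ %g Hz (%.1f s), label = %s\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, x$label))
  invisible(x)
}

#' @export
print.reg_segment <- function(x, ...) {
  cat(sprintf("<reg_segment> %d samples @ %g Hz, label = %s, offset = %d\n",
              length(x$samples), x$sampling_rate, x$label,
              x$source_offset))
  invisible(x)
}

#' Write / read one segment as a plain-text CSV
#'
#' The dialect is one sample (ohms) per row, preceded by comment headers
#' `# fs_hz=<rate>` and `# label=<label>`.
#'
#' @param segment a `reg_segment` or `reg_record`.
#' @param path file path.
#' @return `write_segment_csv` returns `path` invisibly;
#'   `read_segment_csv` returns a `reg_segment`.
#' @export
write_segment_csv <- function(segment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs_hz=%g", segment$sampling_rate),
               sprintf("# label=%s", segment$label %||% "unknown"),
               "ohms",
               format(segment$samples, digits = 15, scientific = FALSE,
                      trim = TRUE)),
             con)
  invisible(path)
}

#' @rdname write_segment_csv
#' @export
read_segment_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  fs <- as.numeric(sub("^# fs_hz=", "", hdr[1]))
  label <- sub("^# label=", "", hdr[2])
  if (!is.finite(fs) || fs <= 0)
    config_error(sprintf("missing or invalid fs_hz header in %s", path))
  x <- read.csv(path, comment.char = "#")[[1]]
  structure(list(samples = as.numeric(x), sampling_rate = fs,
                 label = label, source_offset = 0L),
            class = "reg_segment")
}
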