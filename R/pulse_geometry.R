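# Per-pulse landmark detection and classical time-domain pulse-wave
# geometry features, summarized per segment by the median.

#' Detect pulse minima and maxima
#'
#' Finds pulse feet (minima) by local-extremum search with a minimum
#' inter-peak distance of `min_period_s` (default 0.4 s, i.e. a maximum
#' heart rate of 150 bpm), then places one maximum between each pair of
#' consecutive minima (the most extreme sample strictly inside the
#' beat), which enforces strict alternation by construction.
#'
#' @param segment a `reg_segment` (band-limited) or numeric vector.
#' @param fs sampling rate in Hz for numeric input.
#' @param min_period_s minimum admissible beat period in seconds.
#' @return A `pulse_landmarks` object: list with integer vectors
#'   `minima` (length k) and `maxima` (length k - 1), 1-based indices.
#' @export
detect_landmarks <- function(segment, fs = NULL, min_period_s = 0.4) {
  s <- as_samples(segment, fs)
  x <- s$samples
  mpd <- max(1L, round(min_period_s * s$fs))
  # sortstr is required for minpeakdistance to prune correctly
  pk <- pracma::findpeaks(-x, minpeakdistance = mpd, sortstr = TRUE)
  if (is.null(pk) || nrow(pk) < 4)
    insufficient_pulses_error("fewer than 3 complete pulses detected")
  minima <- sort(pk[, 2])
  maxima <- vapply(seq_len(length(minima) - 1), function(i) {
    lo <- minima[i]
    hi <- minima[i + 1]
    lo + which.max(x[(lo + 1):(hi - 1)])
  }, numeric(1))
  structure(list(minima = as.integer(minima),
                 maxima = as.integer(maxima)),
            class = "pulse_landmarks")
}

#' Compute pulse-wave geometry features
#'
#' For each complete pulse (foot-to-foot) the ten classical descriptors
#' are computed, then summarized over pulses by the median:
#' \describe{
#'   \item{Max, Min}{signed amplitudes at the pulse maximum / foot (ohm)}
#'   \item{Range}{Max - Min per pulse (ohm)}
#'   \item{dt_max, dt_min}{spacing of consecutive maxima / minima (samples)}
#'   \item{dt_min_max}{foot-to-peak (anacrotic) duration (samples)}
#'   \item{alpha}{Range / dt_min_max, the anacrotic slope (ohm/sample)}
#'   \item{Area}{trapezoidal integral over the beat of signal minus the
#'     beat minimum (ohm x samples)}
#'   \item{d_max, d_range}{maximum and max - min of the per-sample
#'     forward difference within the beat (ohm/sample)}
#' }
#'
#' @param segment a `reg_segment` or numeric vector.
#' @param landmarks optional [detect_landmarks()] result; computed if
#'   missing.
#' @param fs sampling rate in Hz for numeric input.
#' @return A one-row data.frame with columns Max, Min, Range, dt_max,
#'   dt_min, dt_min_max, alpha, Area, d_max, d_range, n_pulses.
#' @export
compute_geometry <- function(segment, landmarks = NULL, fs = NULL) {
  s <- as_samples(segment, fs)
  x <- s$samples
  if (is.null(landmarks)) landmarks <- detect_landmarks(segment, fs)
  mn <- landmarks$minima
  mx <- landmarks$maxima
  k <- length(mx)
  if (k < 3) insufficient_pulses_error("fewer than 3 complete pulses")

  max_amp <- x[mx]
  min_amp <- x[mn[seq_len(k)]]
  rng <- max_amp - min_amp
  dt_min_max <- mx - mn[seq_len(k)]
  alpha <- rng / dt_min_max
  beat_stats <- vapply(seq_len(k), function(i) {
    lo <- mn[i]
    hi <- mn[i + 1]
    seg <- x[lo:hi]
    d <- diff(seg)
    c(area = pracma::trapz(seq_along(seg) - 1, seg - min(seg)),
      d_max = max(d), d_range = max(d) - min(d))
  }, numeric(3))

  data.frame(Max = median(max_amp), Min = median(min_amp),
             Range = median(rng),
             dt_max = median(diff(mx)), dt_min = median(diff(mn)),
             dt_min_max = median(dt_min_max), alpha = median(alpha),
             Area = median(beat_stats["area", ]),
             d_max = median(beat_stats["d_max", ]),
             d_range = median(beat_stats["d_range", ]),
             n_pulses = k)
}

#' Compare geometry features between apnea and baseline groups
#'
#' Per feature, reports group means and SDs and a two-sample p-value
#' from the normality-gated test of [compare_groups()] (Welch t when
#' both groups pass the Lilliefors-corrected KS normality check at 0.05,
#' Mann-Whitney otherwise).
#'
#' @param features_apnea,features_baseline data.frames of
#'   [compute_geometry()] rows (one per segment).
#' @return A data.frame with one row per feature: feature, mean_apnea,
#'   sd_apnea, mean_baseline, sd_baseline, p_value, test_used.
#' @export
compare_geometry <- function(features_apnea, features_baseline) {
  if (nrow(features_apnea) < 2 || nrow(features_baseline) < 2)
    insufficient_data_error("need at least 2 segments per group")
  feats <- c("Max", "Min", "Range", "dt_max", "dt_min", "dt_min_max",
             "alpha", "Area", "d_max", "d_range")
  rows <- lapply(feats, function(f) {
    a <- features_apnea[[f]]
    b <- features_baseline[[f]]
    cmp <- compare_groups(a, b)
    data.frame(feature = f,
               mean_apnea = mean(a), sd_apnea = sd(a),
               mean_baseline = mean(b), sd_baseline = sd(b),
               p_value = cmp$p_value, test_used = cmp$test_used)
  })
  do.call(rbind, rows)
}
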