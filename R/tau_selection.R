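# Embedding-lag (tau) selection criteria: dominant-period fractions,
# autocorrelation-based rules, the first minimum of the auto-mutual
# information function, and a knee detector on the CCM-vs-tau curve.

# Biased-normalized autocorrelation, rho(0) = 1, lags 0..max_lag.
acf_rho <- function(x, max_lag) {
  as.numeric(acf(x, lag.max = max_lag, plot = FALSE,
                 demean = TRUE)$acf)
}

#' Dominant pulse period of a segment
#'
#' The lag of the highest autocorrelation peak within the physiological
#' band (default 0.33-2.0 s, i.e. 30-180 bpm). A peak must be a local
#' maximum of the ACF with correlation above `min_rho`; a featureless
#' ACF (e.g. white noise) raises a no-period error.
#'
#' @param segment a band-limited `reg_segment` or numeric vector.
#' @param fs sampling rate in Hz for numeric input.
#' @param band admissible period range in seconds.
#' @param min_rho minimum ACF value for an acceptable peak.
#' @return Period in samples.
#' @export
dominant_period <- function(segment, fs = NULL, band = c(0.33, 2),
                            min_rho = 0.1) {
  s <- as_samples(segment, fs)
  x <- s$samples
  lo <- max(2L, round(band[1] * s$fs))
  hi <- min(length(x) - 2L, round(band[2] * s$fs))
  if (hi <= lo) no_period_error("segment too short for the period band")
  rho <- acf_rho(x, hi + 1)
  lag <- lo:hi
  r <- rho[lag + 1]
  is_peak <- r > rho[lag] & r > rho[lag + 2] & r > min_rho
  if (!any(is_peak))
    no_period_error("no autocorrelation peak in the physiological band")
  lag[is_peak][which.max(r[is_peak])]
}

#' Autocorrelation-based lag criteria
#'
#' From the biased-normalized ACF `rho(tau)`:
#' \describe{
#'   \item{first_zero}{smallest tau with `rho(tau) <= 0`}
#'   \item{one_over_e}{smallest tau with `rho(tau) <= 1/e`}
#'   \item{second_deriv_sign_change}{smallest tau at which the central
#'     second difference of rho changes sign relative to its initial
#'     sign}
#'   \item{first_local_min}{smallest tau with
#'     `rho(tau-1) > rho(tau) < rho(tau+1)`}
#' }
#' Criteria not reached within `max_lag` are returned as `NA`.
#'
#' @param segment a `reg_segment` or numeric vector.
#' @param max_lag largest lag examined (must be < half the segment
#'   length).
#' @param fs sampling rate in Hz for numeric input.
#' @return Named list: first_zero, one_over_e,
#'   second_deriv_sign_change, first_local_min (samples or `NA`).
#' @export
acf_criteria <- function(segment, max_lag = 250, fs = NULL) {
  s <- as_samples(segment, fs)
  x <- s$samples
  if (max_lag >= length(x) / 2)
    config_error("max_lag must be below half the segment length")
  rho <- acf_rho(x, max_lag + 1)
  first_at <- function(cond) {
    idx <- which(cond)
    if (length(idx) == 0) NA_integer_ else idx[1]
  }
  tau_seq <- seq_len(max_lag)
  first_zero <- first_at(rho[tau_seq + 1] <= 0)
  one_over_e <- first_at(rho[tau_seq + 1] <= exp(-1))
  # central second difference over tau = 1..max_lag-1
  inner <- seq_len(max_lag - 1)
  d2 <- rho[inner + 2] - 2 * rho[inner + 1] + rho[inner]
  s0 <- sign(d2[1])
  flip <- first_at(sign(d2) != s0 & sign(d2) != 0)
  second_deriv <- if (is.na(flip)) NA_integer_ else inner[flip]
  lm_tau <- seq(2, max_lag)
  is_min <- rho[lm_tau] > rho[lm_tau + 1] &
    rho[lm_tau + 1] < rho[lm_tau + 2]
  first_local_min <- if (any(is_min)) lm_tau[which(is_min)[1]]
                     else NA_integer_
  list(first_zero = first_zero, one_over_e = one_over_e,
       second_deriv_sign_change = second_deriv,
       first_local_min = first_local_min)
}

# Auto-mutual information (nats) at one lag from a 2-D equal-width
# histogram over the full-series range.
mutual_information_lag <- function(x, tau, bins = 16) {
  n <- length(x)
  a <- x[seq_len(n - tau)]
  b <- x[(tau + 1):n]
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  cut_idx <- function(v) {
    i <- floor((v - rng[1]) / (rng[2] - rng[1]) * bins) + 1
    pmin(pmax(i, 1L), bins)
  }
  joint <- table(factor(cut_idx(a), levels = seq_len(bins)),
                 factor(cut_idx(b), levels = seq_len(bins)))
  p <- joint / sum(joint)
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / (outer(px, py)[nz])))
}

#' First local minimum of the auto-mutual information function
#'
#' Estimates the mutual information I(tau) between the series and its
#' tau-shifted copy from a `bins x bins` equal-width histogram (default
#' 16) and returns the first strict local minimum over tau. The raw
#' I(tau) curve carries binning ripple, so it is smoothed with a short
#' centered moving average before the minimum search; the histogram
#' estimator localizes the minimum only to roughly that window.
#'
#' @param segment a `reg_segment` or numeric vector.
#' @param max_lag largest lag examined.
#' @param bins histogram bins per axis.
#' @param smooth_window moving-average window applied to I(tau) before
#'   the local-minimum search (odd; 1 disables smoothing).
#' @param fs sampling rate in Hz for numeric input.
#' @return Lag in samples; raises a criterion-not-found error when no
#'   local minimum exists within `max_lag`.
#' @export
amif_first_min <- function(segment, max_lag = 250, bins = 16,
                           smooth_window = 5, fs = NULL) {
  s <- as_samples(segment, fs)
  x <- s$samples
  if (max_lag >= length(x) / 2)
    config_error("max_lag must be below half the segment length")
  mi <- vapply(0:max_lag, function(tau)
    mutual_information_lag(x, tau, bins), numeric(1))
  if (smooth_window > 1) {
    sm <- as.numeric(stats::filter(
      mi, rep(1 / smooth_window, smooth_window), sides = 2))
  } else sm <- mi
  # sm[tau + 1]; strict local minima over lags where sm is defined
  tau_seq <- seq_len(max_lag - 1)
  ok <- !is.na(sm[tau_seq]) & !is.na(sm[tau_seq + 2])
  is_min <- ok & sm[tau_seq + 1] < sm[tau_seq] &
    sm[tau_seq + 1] < sm[tau_seq + 2]
  if (!any(is_min))
    criterion_error("no local minimum of the auto-mutual information within max_lag")
  tau_seq[which(is_min)[1]]
}

#' All lag-selection criteria for one segment
#'
#' @param segment a band-limited `reg_segment`.
#' @param max_lag largest lag examined for the ACF/AMIF criteria.
#' @param fs sampling rate in Hz for numeric input.
#' @return One-row data.frame: quarter_period, fifth_period,
#'   amif_first_min, acf_first_zero, acf_1_over_e,
#'   acf_second_deriv_sign_change, acf_first_min_over_10,
#'   acf_first_min_over_20 (samples; `NA` where a criterion was not
#'   reached).
#' @export
tau_criteria <- function(segment, max_lag = 250, fs = NULL) {
  period <- tryCatch(dominant_period(segment, fs),
                     regpoincare_no_period_error = function(e) NA_real_)
  ac <- acf_criteria(segment, max_lag, fs)
  amif <- tryCatch(amif_first_min(segment, max_lag, fs = fs),
                   regpoincare_criterion_error = function(e) NA_real_)
  flm <- ac$first_local_min
  data.frame(quarter_period = period / 4,
             fifth_period = period / 5,
             amif_first_min = as.numeric(amif),
             acf_first_zero = as.numeric(ac$first_zero),
             acf_1_over_e = as.numeric(ac$one_over_e),
             acf_second_deriv_sign_change =
               as.numeric(ac$second_deriv_sign_change),
             acf_first_min_over_10 = flm / 10,
             acf_first_min_over_20 = flm / 20)
}

#' Aggregate lag criteria over segments
#'
#' @param segments list of band-limited `reg_segment` objects.
#' @param max_lag largest lag examined per segment.
#' @return A list with `table` (data.frame, rows mean/sd/min/max,
#'   criteria as columns, missing values skipped; an all-missing
#'   criterion is `NaN`/`NA` flagged), `n_missing` (per criterion) and
#'   `recommended_max_tau` (ceiling of the largest criterion mean).
#' @export
criteria_table <- function(segments, max_lag = 250) {
  if (length(segments) == 0)
    insufficient_data_error("need at least one segment")
  per_seg <- do.call(rbind, lapply(segments, tau_criteria,
                                   max_lag = max_lag))
  agg <- function(f) vapply(per_seg, function(col)
    if (all(is.na(col))) NA_real_ else f(col[!is.na(col)]), numeric(1))
  tab <- rbind(mean = agg(mean), sd = agg(sd),
               min = agg(min), max = agg(max))
  list(table = as.data.frame(tab),
       n_missing = vapply(per_seg, function(col) sum(is.na(col)),
                          integer(1)),
       recommended_max_tau =
         as.integer(ceiling(max(tab["mean", ], na.rm = TRUE))))
}

#' Convert a lag in samples to seconds
#'
#' @param tau lag in samples.
#' @param fs sampling rate in Hz.
#' @return Lag in seconds.
#' @export
tau_to_seconds <- function(tau, fs) tau / fs

#' Knee (inflection) of a CCM-versus-tau curve
#'
#' On synthetic and physiological pulse signals the CCM curve falls
#' monotonically at small lags and then flattens; the knee separating
#' decrease from plateau is a natural upper bound for useful lags. The
#' curve is smoothed with a centered moving average
#' (`smooth_window` points), its per-lag slope is computed, and the
#' knee is the smallest tau past the steepest point at which the slope
#' rises to at least `plateau_frac` of the steepest (most negative)
#' slope, i.e. the decline has lost `1 - plateau_frac` of its peak
#' speed. Empirical CCM curves keep a long shallow tail after the
#' physiological knee, so the default threshold is a deliberately loose
#' 20% of the peak rate; on synthetic REG data this places the knee
#' where the ACF second-derivative criterion places its lag.
#'
#' @param ccm_values CCM values on contiguous lags.
#' @param taus the lags, by default `1:length(ccm_values)`.
#' @param smooth_window moving-average window (odd, default 5).
#' @param plateau_frac plateau threshold as a fraction of the steepest
#'   slope (default 0.2).
#' @return Knee lag in samples; a criterion-not-found error when the
#'   curve never flattens (or does not initially decrease).
#' @export
#' @examples
#' curve <- c(seq(1, 0.2, length.out = 20), rep(0.2, 30))
#' ccm_inflection(curve)
ccm_inflection <- function(ccm_values, taus = seq_along(ccm_values),
                           smooth_window = 5, plateau_frac = 0.2) {
  n <- length(ccm_values)
  if (n < 10)
    config_error("need a CCM curve over at least 10 contiguous lags")
  half <- smooth_window %/% 2
  sm <- stats::filter(ccm_values, rep(1 / smooth_window, smooth_window),
                      sides = 2)
  sm <- as.numeric(sm)
  # forward slope on the smoothed curve, defined where both ends are
  slope <- rep(NA_real_, n)
  inner <- (half + 1):(n - half - 1)
  slope[inner] <- sm[inner + 1] - sm[inner]
  steepest <- inner[which.min(slope[inner])]
  s0 <- slope[steepest]
  if (!is.finite(s0) || s0 >= 0)
    criterion_error("CCM curve does not decrease initially")
  cand <- inner[inner > steepest]
  hit <- cand[slope[cand] >= plateau_frac * s0]
  if (length(hit) == 0)
    criterion_error("no plateau found: CCM decreases over the whole range")
  taus[hit[1]]
}
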