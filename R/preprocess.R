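# Band limiting and artifact-screened segment extraction.

# Cascade design: order-4 Chebyshev type II high-pass (stopband edge
# 0.1 Hz, removes DC drift) followed by an order-8 Chebyshev type II
# low-pass (stopband edge 20 Hz, removes mains/electrical noise).
# 40 dB stopband attenuation fixes both designs uniquely.
reg_filters <- function(fs, hp_stop_hz = 0.1, lp_stop_hz = 20,
                        hp_order = 4, lp_order = 8, atten_db = 40) {
  if (fs <= 2 * lp_stop_hz)
    config_error("sampling rate must exceed twice the low-pass stopband edge (40 Hz)")
  list(hp = signal::cheby2(hp_order, atten_db, hp_stop_hz / (fs / 2),
                           type = "high"),
       lp = signal::cheby2(lp_order, atten_db, lp_stop_hz / (fs / 2),
                           type = "low"),
       fs = fs)
}

# Samples until the filter's impulse response decays below `frac` of
# its peak; used for the too-short check (frac 1e-3) and the filtfilt
# pad length (frac 1e-4, generous because the 0.1 Hz high-pass poles
# sit very close to the unit circle).
settle_length <- function(flt, frac = 1e-3, n_probe = 8192) {
  h <- as.numeric(signal::filter(flt$b, flt$a,
                                 c(1, numeric(n_probe - 1))))
  idx <- which(abs(h) > frac * max(abs(h)))
  max(idx)
}

# Single forward IIR pass with steady-state edge initialization: virtual
# prior inputs equal to x[1] and prior outputs equal to the DC-gain
# response, so a constant input is in steady state from sample one.
filter_ss <- function(flt, x) {
  b <- flt$b
  a <- flt$a
  g <- sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], length(b) - 1),
                            init.y = rep(g * x[1], length(a) - 1)))
}

# Zero-phase (forward-backward) filtering with reflective padding.
# Even (mirror) reflection is value-continuous, so no spurious level
# step enters the filter - right for the low-pass, where a point
# reflection would fold fast oscillations about the edge sample into a
# DC offset. Odd (point) reflection continues the local trend - right
# for the slow high-pass, whose near-unit-circle poles ring for
# seconds when the trend breaks.
zero_phase <- function(flt, x, pad, reflect = c("even", "odd")) {
  reflect <- match.arg(reflect)
  n <- length(x)
  pad <- min(pad, n - 1)
  xp <- if (reflect == "even")
    c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
  else
    c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- filter_ss(flt, xp)
  y <- rev(filter_ss(flt, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Band-limit a REG record
#'
#' Applies, zero-phase (forward-backward, so pulse landmark timing is
#' not skewed), a cascade of an order-4 Chebyshev type II high-pass with
#' 0.1 Hz stopband edge and an order-8 Chebyshev type II low-pass with
#' 20 Hz stopband edge (40 dB stopband attenuation each). The signal
#' mean is subtracted first: Chebyshev II leaves a -40 dB ripple rather
#' than a true null at DC, and REG analysis is invariant to the offset.
#'
#' @param record a `reg_record`, `reg_segment` or numeric vector.
#' @param fs sampling rate in Hz, required when `record` is numeric.
#' @return Same type as the input, with `samples` replaced by the
#'   filtered signal (equal length).
#' @export
#' @examples
#' rec <- generate_record(synth_config(duration = 16, seed = 1))
#' filt <- bandlimit(rec)
bandlimit <- function(record, fs = NULL) {
  s <- as_samples(record, fs)
  flt <- reg_filters(s$fs)
  n_settle <- settle_length(flt$hp)
  if (length(s$samples) < 3 * n_settle)
    too_short_error(sprintf(
      "record has %d samples but band limiting needs at least %d (3x the high-pass settling length)",
      length(s$samples), 3 * n_settle))
  y <- s$samples - mean(s$samples)
  # low-pass first: it settles quickly and hands the slow high-pass a
  # smooth signal, which keeps the high-pass edge transients small.
  # Pads are twice the 1e-4 settling length so backward-pass ringing
  # dies inside the discarded padding.
  y <- zero_phase(flt$lp, y, pad = 2 * settle_length(flt$lp, frac = 1e-4),
                  reflect = "even")
  y <- zero_phase(flt$hp, y, pad = 2 * settle_length(flt$hp, frac = 1e-4),
                  reflect = "odd")
  if (is.numeric(record) && !inherits(record, "reg_record")) return(y)
  out <- record
  out$samples <- y
  out
}

#' Frequency response of the band-limiting cascade
#'
#' Magnitude response of the designed high-pass/low-pass cascade as
#' applied by [bandlimit()] (forward-backward, hence the squared
#' single-pass magnitude).
#'
#' @param freq frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @return Magnitude gain at each frequency.
#' @export
#' @examples
#' bandlimit_response(c(0.05, 1, 30), fs = 250)
bandlimit_response <- function(freq, fs = 250) {
  flt <- reg_filters(fs)
  mag1 <- function(f, w) {
    z <- exp(-1i * 2 * pi * w / fs)
    abs(sum(f$b * z^(seq_along(f$b) - 1)) /
        sum(f$a * z^(seq_along(f$a) - 1)))
  }
  vapply(freq, function(w)
    (mag1(flt$hp, w) * mag1(flt$lp, w))^2, numeric(1))
}

#' Extract artifact-free fixed-length segments
#'
#' Scans non-overlapping windows of `segment_seconds` left to right and
#' keeps those that pass an automatic artifact screen (a reproducible
#' stand-in for visual inspection): a window is rejected if any sample
#' deviates from the record median by more than 5x the record's median
#' absolute deviation, or if any of its per-second amplitude ranges
#' exceeds 3x the record's median per-second range.
#'
#' @param record a band-limited `reg_record` (or numeric vector + `fs`).
#' @param segment_seconds window length in seconds (default 16).
#' @return A list of `reg_segment` objects (possibly empty), each with
#'   `source_offset` giving its 0-based start sample.
#' @export
select_segments <- function(record, segment_seconds = 16, fs = NULL) {
  s <- as_samples(record, fs)
  x <- s$samples
  win <- round(segment_seconds * s$fs)
  n_win <- length(x) %/% win
  if (n_win == 0) return(list())

  med <- median(x)
  scale <- mad(x)
  sec <- s$fs
  n_sec <- length(x) %/% sec
  sec_range <- vapply(seq_len(n_sec), function(k) {
    seg <- x[((k - 1) * sec + 1):(k * sec)]
    max(seg) - min(seg)
  }, numeric(1))
  med_range <- median(sec_range)

  out <- list()
  for (w in seq_len(n_win)) {
    i0 <- (w - 1) * win
    xi <- x[(i0 + 1):(i0 + win)]
    if (scale > 0 && any(abs(xi - med) > 5 * scale)) next
    secs <- (i0 %/% sec + 1):((i0 + win) %/% sec)
    secs <- secs[secs <= n_sec]
    if (med_range > 0 && any(sec_range[secs] > 3 * med_range)) next
    out[[length(out) + 1]] <- structure(
      list(samples = xi, sampling_rate = s$fs, label = s$label,
           source_offset = as.integer(i0)),
      class = "reg_segment")
  }
  out
}
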