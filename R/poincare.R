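# Lagged two-dimensional Poincare plots and their descriptors:
# SD1/SD2 (ellipse axes), SDarea, SDratio, lag correlation R and the
# Complex Correlation Measure (CCM).

#' Construct a Poincare plot from explicit coordinates
#'
#' @param x,y equal-length numeric vectors (signal and lagged signal).
#' @param tau the lag in samples that relates `y` to `x`.
#' @return A `poincare_plot`: list with `x`, `y`, `tau`, `n_points`.
#' @export
poincare_plot <- function(x, y, tau) {
  if (length(x) != length(y))
    lag_error("x and y must have equal length")
  if (length(x) < 3)
    lag_error("a Poincare plot needs at least 3 points")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 tau = as.integer(tau), n_points = length(x)),
            class = "poincare_plot")
}

#' Time-delay embed a segment into a Poincare plot
#'
#' Pairs the signal with its `tau`-sample delayed copy: with `N` samples
#' the plot holds the `N - tau` points `(x[t], x[t + tau])`.
#'
#' @param segment a `reg_segment`, `reg_record` or numeric vector.
#' @param tau lag in samples, `1 <= tau <= N - 3`.
#' @return A `poincare_plot`.
#' @export
#' @examples
#' p <- poincare_embed(c(1, 2, 3, 4), 1)
#' cbind(p$x, p$y)  # pairs (1,2), (2,3), (3,4)
poincare_embed <- function(segment, tau) {
  x <- if (is.numeric(segment)) as.numeric(segment) else segment$samples
  n <- length(x)
  if (!is.numeric(tau) || length(tau) != 1 || tau != round(tau))
    lag_error("tau must be a single integer")
  if (tau < 1 || tau > n - 3)
    lag_error(sprintf("tau = %d out of range [1, %d] for a series of length %d",
                      as.integer(tau), n - 3, n))
  poincare_plot(x[seq_len(n - tau)], x[(tau + 1):n], tau)
}

#' Ellipse descriptors SD1, SD2, SDarea, SDratio
#'
#' Rotating the plot by 45 degrees, SD1 is the standard deviation
#' perpendicular to the identity line, `sd((x - y) / sqrt(2))`, and SD2
#' along it, `sd((x + y) / sqrt(2))` (sample SD, denominator n - 1).
#' SDarea is the fitted-ellipse area `pi * SD1 * SD2` and SDratio the
#' dimensionless regularity index SD1/SD2.
#'
#' @param plot a `poincare_plot`.
#' @param components which descriptors to return; `sd_ratio` raises a
#'   degenerate-plot error when SD2 = 0.
#' @return Named list with the requested components.
#' @export
#' @examples
#' p <- poincare_embed(sin(2 * pi * (0:999) / 250), 5)
#' sd_features(p)
sd_features <- function(plot,
                        components = c("sd1", "sd2", "sd_area", "sd_ratio")) {
  components <- match.arg(components, several.ok = TRUE)
  sd1 <- sqrt(var((plot$x - plot$y) / sqrt(2)))
  sd2 <- sqrt(var((plot$x + plot$y) / sqrt(2)))
  out <- list(sd1 = sd1, sd2 = sd2, sd_area = pi * sd1 * sd2)
  if ("sd_ratio" %in% components) {
    if (sd2 == 0)
      degenerate_plot_error("SD2 = 0 (constant x + y): SDratio undefined")
    out$sd_ratio <- sd1 / sd2
  }
  out[components]
}

#' Lag correlation R
#'
#' Pearson product-moment correlation between the plot coordinates,
#' i.e. between the signal and its lagged copy, each window using its
#' own mean and variance.
#'
#' @param plot a `poincare_plot`.
#' @return Correlation in \[-1, 1\].
#' @export
correlation_r <- function(plot) {
  if (var(plot$x) == 0 || var(plot$y) == 0)
    degenerate_plot_error("zero variance in a plot coordinate: R undefined")
  cor(plot$x, plot$y)
}

#' Complex Correlation Measure (CCM)
#'
#' For every set of three consecutive plot points the unsigned triangle
#' area is accumulated (zero when the points are collinear) and the sum
#' is normalized by the ellipse area `pi * SD1 * SD2` times the number
#' of triplets (`n_points - 2`). The triangle area is |determinant|/2
#' (the standard shoelace area); the 1/2 scales CCM uniformly and is
#' applied consistently. CCM is invariant to affine amplitude
#' transforms of the signal and captures temporal structure that the
#' variance descriptors miss.
#'
#' @param segment a `reg_segment`/numeric vector, or a `poincare_plot`
#'   (then `tau` is ignored).
#' @param tau lag in samples used to embed a segment.
#' @return CCM, a non-negative dimensionless number.
#' @export
#' @examples
#' ccm(rnorm(100), tau = 1)
ccm <- function(segment, tau = NULL) {
  plot <- if (inherits(segment, "poincare_plot")) segment
          else poincare_embed(segment, tau)
  sdf <- sd_features(plot, components = c("sd1", "sd2", "sd_area"))
  if (sdf$sd_area == 0)
    degenerate_plot_error("ellipse area is zero: CCM undefined")
  x <- plot$x
  y <- plot$y
  m <- plot$n_points
  i <- seq_len(m - 2)
  area <- abs(x[i] * (y[i + 1] - y[i + 2]) +
              x[i + 1] * (y[i + 2] - y[i]) +
              x[i + 2] * (y[i] - y[i + 1])) / 2
  sum(area) / (sdf$sd_area * (m - 2))
}

#' Poincare descriptors for one segment at one lag
#'
#' @param segment a `reg_segment` or numeric vector.
#' @param tau lag in samples.
#' @return One-row data.frame: tau, SD1, SD2, SDarea, SDratio, R, CCM.
#' @export
poincare_features <- function(segment, tau) {
  plot <- poincare_embed(segment, tau)
  sdf <- sd_features(plot)
  data.frame(tau = tau, SD1 = sdf$sd1, SD2 = sdf$sd2,
             SDarea = sdf$sd_area, SDratio = sdf$sd_ratio,
             R = correlation_r(plot), CCM = ccm(plot))
}

#' Sweep the Poincare descriptors over segments and lags
#'
#' Computes [poincare_features()] for every (segment, tau) combination.
#' Degenerate plots (zero variance) yield `NA` descriptors with a
#' warning rather than aborting the sweep.
#'
#' @param segments list of `reg_segment` objects.
#' @param tau_values integer vector of lags.
#' @return A long data.frame: segment_id, label, tau, SD1, SD2, SDarea,
#'   SDratio, R, CCM; `length(segments) * length(tau_values)` rows.
#' @export
#' @examples
#' segs <- generate_dataset(2, 2, segment_seconds = 8, seed = 1)
#' sweep <- feature_sweep(segs, 1:5)
#' nrow(sweep)  # 4 segments x 5 lags = 20
feature_sweep <- function(segments, tau_values) {
  empty <- data.frame(segment_id = integer(), label = character(),
                      tau = integer(), SD1 = numeric(), SD2 = numeric(),
                      SDarea = numeric(), SDratio = numeric(),
                      R = numeric(), CCM = numeric())
  if (length(segments) == 0 || length(tau_values) == 0) return(empty)
  rows <- vector("list", length(segments) * length(tau_values))
  k <- 0
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    label <- if (is.numeric(seg)) "unknown" else seg$label %||% "unknown"
    for (tau in tau_values) {
      k <- k + 1
      feat <- tryCatch(poincare_features(seg, tau),
        regpoincare_degenerate_plot_error = function(e) {
          warning(sprintf("segment %d, tau %d: %s (recorded as NA)",
                          i, tau, conditionMessage(e)), call. = FALSE)
          data.frame(tau = tau, SD1 = NA_real_, SD2 = NA_real_,
                     SDarea = NA_real_, SDratio = NA_real_,
                     R = NA_real_, CCM = NA_real_)
        })
      rows[[k]] <- cbind(data.frame(segment_id = i, label = label),
                         feat)
    }
  }
  do.call(rbind, rows)
}
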