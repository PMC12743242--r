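# Bout profiling: vertical/AP axis identification and the a-priori mean
# step time / step frequency that drives all dynamic downstream parameters.

#' Identify the vertical axis
#'
#' The vertical axis is the channel with the largest absolute mean
#' acceleration (gravity dominated). The sign is chosen so that the signed
#' channel mean is negative, i.e. the sensor measures -g at rest.
#'
#' @param rec An [accel_recording()].
#' @return List with `index` (1-3) and `sign` (+1/-1).
#' @export
identify_vertical_axis <- function(rec) {
  m <- colMeans(rec$a)
  am <- abs(m)
  ord <- order(am, decreasing = TRUE)
  if (am[ord[2]] > 0.99 * am[ord[1]]) {
    stop("ambiguous orientation: two channels have nearly equal mean ",
         "acceleration magnitude")
  }
  idx <- ord[1]
  list(index = idx, sign = if (m[idx] <= 0) 1 else -1)
}

#' Identify the anterior-posterior axis
#'
#' Among the two non-vertical channels (band-passed to the walking band),
#' the AP axis is the one with the larger maximum absolute normalized
#' cross-correlation with the band-passed vertical channel. The sign is
#' flipped when the peak correlation is negative so that downstream contact
#' morphology is consistent.
#'
#' @param rec An [accel_recording()].
#' @param vertical Result of [identify_vertical_axis()].
#' @param cfg A [gait_config()] (band-pass settings).
#' @return List with `index`, `sign`, and the two candidate peak
#'   correlations.
#' @export
identify_ap_axis <- function(rec, vertical, cfg = gait_config()) {
  bp <- function(x) butterworth_filter(x, rec$fs, "bandpass",
                                       cfg$bandpass, cfg$filter_order)
  v <- bp(vertical$sign * rec$a[, vertical$index])
  cand <- setdiff(1:3, vertical$index)
  max_lag <- round(rec$fs)                 # +-1 s is ample at gait cadence
  peak_cc <- vapply(cand, function(j) {
    x <- bp(rec$a[, j])
    cc <- stats::ccf(x, v, lag.max = max_lag, plot = FALSE,
                     demean = TRUE)$acf
    cc[which.max(abs(cc))]
  }, numeric(1))
  if (all(abs(peak_cc) < 0.1)) {
    warning("weak gait signal: low vertical/AP cross-correlation")
  }
  best <- which.max(abs(peak_cc))
  list(index = cand[best], sign = if (peak_cc[best] >= 0) 1 else -1,
       correlations = stats::setNames(peak_cc, paste0("ch", cand)))
}

# lower-midpoint median: for an even count, take the lower of the two
# central order statistics, so the estimate equals an observed value
median_lower <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

#' Estimate the bout mean step time and step frequency
#'
#' Computes the CWT of the band-passed AP acceleration at 10 scales whose
#' target frequencies span 0.5-5.0 Hz, combines them sample-wise into a
#' "CWT power" signal, and extracts the first peak of the windowed (5 s,
#' 50% overlap) autocovariance in each window. The median of the per-window
#' first-peak lags is the mean step time; its inverse is the mean step
#' frequency.
#'
#' @param ap Band-passed AP acceleration (signed per the identified axis).
#' @param fs Sampling rate in Hz.
#' @param cfg A [gait_config()].
#' @return List with `step_time` (s), `step_freq` (Hz) and the per-window
#'   `window_lags` (s).
#' @export
estimate_mean_step_time <- function(ap, fs, cfg = gait_config()) {
  freqs <- seq(cfg$step_freq_band[1], cfg$step_freq_band[2],
               length.out = cfg$n_scales)
  scales <- frequency_to_scale(freqs, fs)
  power <- numeric(length(ap))
  for (s in scales) {
    w <- cwt_gaus1(ap, s)
    power <- power + if (cfg$cwt_power == "abs") abs(w) else w
  }
  n <- length(ap)
  win <- round(cfg$acv_window * fs)
  hop <- max(1L, round(win * (1 - cfg$acv_overlap)))
  if (n < win) {
    starts <- 1L                          # single whole-bout window
    win <- n
  } else {
    starts <- seq(1L, n - win + 1L, by = hop)
  }
  min_lag <- max(2L, round(cfg$acv_min_lag * fs))
  max_lag <- min(win - 2L, round(cfg$acv_max_lag * fs))
  lags <- vapply(starts, function(s0) {
    seg <- power[seq(s0, s0 + win - 1L)]
    acv <- as.numeric(stats::acf(seg, lag.max = max_lag, type = "covariance",
                                 demean = TRUE, plot = FALSE)$acf)
    pk <- find_peaks(acv, prominence = cfg$acv_prominence * acv[1],
                     refine = TRUE)
    pk <- pk[pk$index - 1 >= min_lag, , drop = FALSE]   # acv[1] is lag 0
    if (!nrow(pk)) return(NA_real_)
    (pk$index[1] - 1) / fs                # first (smallest-lag) peak
  }, numeric(1))
  lags <- lags[!is.na(lags)]
  if (!length(lags)) {
    stop("no gait detected: no autocovariance peak in the step-time range")
  }
  t_step <- median_lower(lags)
  list(step_time = t_step, step_freq = 1 / t_step, window_lags = lags)
}

#' Profile a walking bout
#'
#' Runs axis identification, tilt correction and mean step-time estimation;
#' the result carries everything downstream stages need.
#'
#' @param rec An [accel_recording()].
#' @param cfg A [gait_config()].
#' @return List of class `"bout_profile"`: axis indices and signs, the
#'   tilt-corrected recording, band-passed signed AP signal, mean step
#'   time/frequency and per-window lags.
#' @export
bout_profile <- function(rec, cfg = gait_config()) {
  vert <- identify_vertical_axis(rec)
  ap <- identify_ap_axis(rec, vert, cfg)
  # orient channels per the identified signs, then level the frame
  a <- rec$a
  a[, vert$index] <- vert$sign * a[, vert$index]
  a[, ap$index] <- ap$sign * a[, ap$index]
  a <- tilt_correct(a, vert$index, ap$index)
  rec_c <- rec
  rec_c$a <- a
  ap_bp <- butterworth_filter(a[, ap$index], rec$fs, "bandpass",
                              cfg$bandpass, cfg$filter_order)
  est <- estimate_mean_step_time(ap_bp, rec$fs, cfg)
  structure(list(vertical = vert$index, vertical_sign = vert$sign,
                 ap = ap$index, ap_sign = ap$sign,
                 correlations = ap$correlations,
                 recording = rec_c, ap_bandpassed = ap_bp,
                 step_time = est$step_time, step_freq = est$step_freq,
                 window_lags = est$window_lags),
            class = "bout_profile")
}

#' @export
print.bout_profile <- function(x, ...) {
  cat(sprintf(
    "<bout_profile> vertical: ch%d (sign %+d), AP: ch%d (sign %+d)\n",
    x$vertical, x$vertical_sign, x$ap, x$ap_sign))
  cat(sprintf("  mean step time %.3f s (%.2f Hz) from %d windows\n",
              x$step_time, x$step_freq, length(x$window_lags)))
  invisible(x)
}
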