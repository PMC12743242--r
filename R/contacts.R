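# Initial-contact (IC) and final-contact (FC) event detection: the adaptive
# AP-signal method with step-frequency-tuned wavelet scales, and the legacy
# vertical-signal comparator.

#' Construct a contact-event set
#'
#' @param ic,fc Sorted IC and FC event times in seconds from bout start.
#' @param detector Detector tag (`"adaptive"`, `"legacy"`, or `"file"`).
#' @param info Optional provenance list (scales and sigma_Wn used).
#' @return Object of class `"contact_events"`.
#' @export
contact_events <- function(ic, fc, detector = "adaptive", info = list()) {
  stopifnot(!is.unsorted(ic), !is.unsorted(fc))
  structure(list(ic = as.numeric(ic), fc = as.numeric(fc),
                 detector = detector, info = info),
            class = "contact_events")
}

#' @export
print.contact_events <- function(x, ...) {
  cat(sprintf("<contact_events> %s detector: %d IC, %d FC\n",
              x$detector, length(x$ic), length(x$fc)))
  invisible(x)
}

# evaluate an affine step-frequency -> wavelet-frequency relation, capped
# to keep the resulting central frequency positive and below Nyquist
relation_freq <- function(rel, f_step, fs) {
  f <- rel[[1]] * f_step + rel[[2]]
  max(0.05, min(f, 0.45 * fs))
}

#' Detect final-contact events (adaptive detector)
#'
#' Integrates the low-pass-filtered AP acceleration to AP velocity and
#' applies the Gaussian first-derivative CWT at the scale given by the
#' step-frequency relation; peaks of the coefficient series with prominence
#' above `0.6 * sigma_Wn` (sigma_Wn = SD of the whole coefficient series)
#' and pairwise distance above half the mean step time are the FC events.
#' Peaks within the CWT edge margin are discarded.
#'
#' @param ap Low-pass-filtered AP acceleration (signed per the bout
#'   profile).
#' @param fs Sampling rate in Hz.
#' @param step_time Bout mean step time in s.
#' @param cfg A [gait_config()].
#' @return List with `fc` (times in s), `scale`, `sigma` and the
#'   coefficient series (`w`).
#' @export
detect_fc <- function(ap, fs, step_time, cfg = gait_config()) {
  f_cwt <- relation_freq(cfg$scale_relation$fc, 1 / step_time, fs)
  scale <- frequency_to_scale(f_cwt, fs)
  vel <- integrate_trapz(ap - mean(ap), fs)
  w <- cwt_gaus1(vel, scale)
  sigma <- stats::sd(w)
  if (sigma == 0) {                       # constant input: no gait, no events
    return(list(fc = numeric(0), scale = scale, sigma = sigma, w = w))
  }
  pk <- find_peaks(w, prominence = cfg$prominence_factor * sigma,
                   distance = cfg$distance_factor * step_time * fs,
                   refine = TRUE)
  margin <- cwt_edge_margin(scale)
  pk <- pk[pk$index > margin & pk$index <= length(ap) - margin, ,
           drop = FALSE]
  if (nrow(pk) < 2) {
    stop("insufficient contact events detected in the bout")
  }
  list(fc = (pk$index - 1) / fs, scale = scale, sigma = sigma, w = w)
}

#' Detect initial-contact events by backward search (adaptive detector)
#'
#' Applies the CWT to the low-pass-filtered AP acceleration at the
#' IC-relation scale, producing a smoothed AP jerk signal. For each FC
#' event the algorithm scans backward (bounded by the previous FC or the
#' bout start, and excluding a small margin just before the FC, which
#' carries the FC's own jerk zero-crossing) for the latest
#' positive-to-negative zero-crossing of the jerk and the latest prominent
#' local jerk minimum preceding that crossing; the IC is the midpoint of
#' those two times. This midpoint rule tolerates the flattened AP peaks of
#' slow walking. FC events with no valid (crossing, minimum) pair yield no
#' IC and are dropped from pairing.
#'
#' @param ap Low-pass-filtered AP acceleration.
#' @param fs Sampling rate in Hz.
#' @param step_time Bout mean step time in s.
#' @param fc FC times from [detect_fc()].
#' @param cfg A [gait_config()].
#' @return List with `ic`, `fc_paired` (FCs that produced an IC), `scale`,
#'   `sigma`.
#' @export
detect_ic <- function(ap, fs, step_time, fc, cfg = gait_config()) {
  stopifnot(length(fc) >= 1)
  f_cwt <- relation_freq(cfg$scale_relation$ic, 1 / step_time, fs)
  scale <- frequency_to_scale(f_cwt, fs)
  jerk <- cwt_gaus1(ap, scale)
  sigma <- stats::sd(jerk)
  mins <- find_peaks(-jerk, prominence = cfg$prominence_factor * sigma,
                     distance = cfg$distance_factor * step_time * fs,
                     refine = TRUE)
  min_t <- (mins$index - 1) / fs
  # sub-sample positive-to-negative zero crossings of the jerk
  s <- sign(jerk)
  ci <- which(s[-length(s)] > 0 & s[-1] <= 0)
  cross_t <- (ci - 1 + jerk[ci] / (jerk[ci] - jerk[ci + 1])) / fs
  margin <- cfg$ic_search_margin * step_time
  ic <- rep(NA_real_, length(fc))
  for (k in seq_along(fc)) {
    lo <- if (k > 1) fc[k - 1] else 0
    cr <- cross_t[cross_t > lo & cross_t < fc[k] - margin]
    if (!length(cr)) next
    cr <- max(cr)
    mn <- min_t[min_t > lo & min_t < cr]
    if (!length(mn)) next
    ic[k] <- (max(mn) + cr) / 2
  }
  ok <- !is.na(ic)
  if (!any(ok)) stop("no initial contacts could be paired with final contacts")
  list(ic = ic[ok], fc_paired = fc[ok], scale = scale, sigma = sigma)
}

#' Run the adaptive contact detector on a profiled bout
#'
#' Low-pass filters the AP channel, then runs [detect_fc()] and
#' [detect_ic()].
#'
#' @param profile A [bout_profile()].
#' @param cfg A [gait_config()].
#' @return A [contact_events()] with detector tag `"adaptive"`.
#' @export
detect_contacts <- function(profile, cfg = gait_config()) {
  rec <- profile$recording
  ap <- butterworth_filter(rec$a[, profile$ap], rec$fs, "lowpass",
                           cfg$lowpass, cfg$filter_order)
  fcr <- detect_fc(ap, rec$fs, profile$step_time, cfg)
  icr <- detect_ic(ap, rec$fs, profile$step_time, fcr$fc, cfg)
  contact_events(icr$ic, fcr$fc, detector = "adaptive",
                 info = list(fc_scale = fcr$scale, ic_scale = icr$scale,
                             fc_sigma = fcr$sigma, ic_sigma = icr$sigma,
                             step_time = profile$step_time))
}

#' Legacy vertical-axis contact detector
#'
#' The comparator method: the vertical acceleration is decimated to 50 Hz,
#' integrated with the cumulative trapezoid rule and smoothed with the
#' Gaussian first-derivative CWT (default scale 8, i.e. a 1.25 Hz central
#' frequency at 50 Hz); peaks with height above 50% of the SD of the
#' smoothed signal are the IC estimates. A second CWT pass gives the
#' smoothed jerk, whose peaks (same height rule) are the FC estimates.
#' The vertical channel follows the package sign convention (mean near -g)
#' and is flipped internally so that upward acceleration is positive before
#' integration.
#'
#' @param vert Vertical acceleration in m/s^2 (mean near -9.81), at the
#'   native sampling rate.
#' @param fs Native sampling rate in Hz.
#' @param cfg A [gait_config()] (legacy block parameters).
#' @param scale Optional CWT scale override (dimensionless, at the
#'   decimated rate).
#' @return A [contact_events()] with detector tag `"legacy"`.
#' @export
detect_contacts_legacy <- function(vert, fs, cfg = gait_config(),
                                   scale = NULL) {
  fs2 <- cfg$legacy_fs
  if (is.null(scale)) scale <- frequency_to_scale(cfg$legacy_scale_freq, fs2)
  up <- -(vert)                            # upward-positive
  if (fs > fs2) {
    # antialias, then cubic interpolation onto the 50 Hz grid
    up <- butterworth_filter(up, fs, "lowpass", 0.4 * fs2, cfg$filter_order)
    t_old <- (seq_along(up) - 1) / fs
    t_new <- seq(0, t_old[length(t_old)], by = 1 / fs2)
    up <- stats::spline(t_old, up, xout = t_new)$y
  } else {
    fs2 <- fs
    t_new <- (seq_along(up) - 1) / fs
  }
  sm <- cwt_gaus1(integrate_trapz(up - mean(up), fs2), scale)
  if (stats::sd(sm) == 0) {
    return(contact_events(numeric(0), numeric(0), detector = "legacy",
                          info = list(scale = scale, fs = fs2)))
  }
  pk_ic <- find_peaks(sm, height = cfg$legacy_height_factor * stats::sd(sm),
                      refine = TRUE)
  jerk <- cwt_gaus1(sm, scale)
  pk_fc <- find_peaks(jerk,
                      height = cfg$legacy_height_factor * stats::sd(jerk),
                      refine = TRUE)
  margin <- cwt_edge_margin(scale)
  keep <- function(pk) {
    pk <- pk[pk$index > margin & pk$index <= length(up) - margin, ,
             drop = FALSE]
    (pk$index - 1) / fs2
  }
  ic <- keep(pk_ic)
  fc <- keep(pk_fc)
  if (length(ic) < 2 && length(fc) < 2) {
    stop("insufficient contact events detected in the bout")
  }
  contact_events(ic, fc, detector = "legacy",
                 info = list(scale = scale, fs = fs2))
}

#' Calibrate the step-frequency to wavelet-frequency relations
#'
#' Sweeps candidate wavelet central frequencies over labeled bouts and, for
#' each bout, picks the frequency minimizing `(1 - F1) + lambda * RMSE`
#' against the reference events (0.3 s matching window); an affine relation
#' `f_CWT = a * f_step + b` is then fitted across bouts by least squares,
#' separately for the FC (velocity CWT) and IC (jerk CWT) stages. The FC
#' stage is calibrated first; the IC sweep runs with each bout's optimal FC
#' events held fixed.
#'
#' @param bouts List of `list(recording, ic, fc)` with reference event
#'   times; at least 3 bouts spanning at least 3 distinct step frequencies.
#' @param grid Candidate wavelet central frequencies in Hz (applied as
#'   multiples of each bout's estimated step frequency when
#'   `grid_relative = TRUE`, the default, so bouts of different cadence
#'   sweep comparable bands).
#' @param lambda Weight of the RMSE term in the cost (per second).
#' @param cfg Base [gait_config()].
#' @param grid_relative Interpret `grid` as multiples of the bout step
#'   frequency.
#' @return List with `ic = c(a, b)`, `fc = c(a, b)` and per-bout
#'   diagnostics.
#' @export
calibrate_scale_relation <- function(bouts, grid = seq(0.4, 3, by = 0.1),
                                     lambda = 1, cfg = gait_config(),
                                     grid_relative = TRUE) {
  stopifnot(length(bouts) >= 3)
  rows <- lapply(bouts, function(b) {
    prof <- bout_profile(b$recording, cfg)
    rec <- prof$recording
    ap <- butterworth_filter(rec$a[, prof$ap], rec$fs, "lowpass",
                             cfg$lowpass, cfg$filter_order)
    region <- c(1, rec$t[length(rec$t)] - 1)
    fgrid <- if (grid_relative) grid * prof$step_freq else grid
    fgrid <- fgrid[fgrid > 0.1 & fgrid < 0.45 * rec$fs]
    score <- function(det, ref) {
      ev <- match_events(det, ref, window = cfg$match_window,
                         region = region)
      rmse <- if (length(ev$errors)) sqrt(mean(ev$errors^2)) else Inf
      f1 <- if (is.na(ev$f1)) 0 else ev$f1
      (1 - f1) + lambda * rmse
    }
    cost_fc <- vapply(fgrid, function(f) {
      cfg2 <- cfg
      cfg2$scale_relation$fc <- c(a = 0, b = f)
      out <- try(detect_fc(ap, rec$fs, prof$step_time, cfg2), silent = TRUE)
      if (inherits(out, "try-error")) return(Inf)
      score(out$fc, b$fc)
    }, numeric(1))
    f_fc <- fgrid[which.min(cost_fc)]
    cfg_fc <- cfg
    cfg_fc$scale_relation$fc <- c(a = 0, b = f_fc)
    fc_det <- detect_fc(ap, rec$fs, prof$step_time, cfg_fc)$fc
    cost_ic <- vapply(fgrid, function(f) {
      cfg2 <- cfg_fc
      cfg2$scale_relation$ic <- c(a = 0, b = f)
      out <- try(detect_ic(ap, rec$fs, prof$step_time, fc_det, cfg2),
                 silent = TRUE)
      if (inherits(out, "try-error")) return(Inf)
      score(out$ic, b$ic)
    }, numeric(1))
    f_ic <- fgrid[which.min(cost_ic)]
    c(f_step = prof$step_freq, f_fc = f_fc, f_ic = f_ic,
      cost_fc = min(cost_fc), cost_ic = min(cost_ic))
  })
  d <- as.data.frame(do.call(rbind, rows))
  if (length(unique(round(d$f_step, 3))) < 2) {
    stop("degenerate calibration: all bouts share one step frequency")
  }
  fit <- function(y) {
    cf <- stats::coef(stats::lm(y ~ f_step, data = d))
    c(a = unname(cf[2]), b = unname(cf[1]))
  }
  list(ic = fit(d$f_ic), fc = fit(d$f_fc), diagnostics = d)
}
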