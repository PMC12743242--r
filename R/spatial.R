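# Spatial gait modeling: center-of-mass height change by double integration
# and step length via one- and two-phase inverted pendulum models.

#' Center-of-mass height trace and excursion over a window
#'
#' Removes the window mean from the vertical acceleration (gravity plus
#' slow drift), double-integrates with the cumulative trapezoid rule,
#' linearly detrends the resulting position trace over the window, and
#' reports the upward CoM position trace and its total excursion
#' (max - min). The vertical channel follows the package convention (mean
#' near -g); the trace is sign-flipped so that it is upward-positive.
#'
#' @param vert Vertical acceleration in m/s^2 for the whole bout.
#' @param fs Sampling rate in Hz.
#' @param window Numeric length-2 window `[t0, t1]` in s from bout start.
#' @return List with `t` (times), `pos` (detrended upward position, m) and
#'   `delta_h` (max - min, m).
#' @export
com_height_change <- function(vert, fs, window) {
  i0 <- max(1L, floor(window[1] * fs) + 1L)
  i1 <- min(length(vert), ceiling(window[2] * fs) + 1L)
  if (i1 - i0 + 1L < 3L) stop("window shorter than 3 samples")
  seg <- -(vert[i0:i1])                    # upward-positive
  seg <- seg - mean(seg)
  vel <- integrate_trapz(seg, fs)
  pos <- integrate_trapz(vel, fs)
  tt <- (seq(i0, i1) - 1) / fs
  # linear detrend through the window endpoints: over one step the CoM
  # height is near-periodic, so the endpoint line captures exactly the
  # drift ramp introduced by double integration without tilting the
  # intra-step shape (a least-squares line would, the height curve being
  # asymmetric in time)
  n <- length(pos)
  slope <- (pos[n] - pos[1]) / (tt[n] - tt[1])
  pos <- pos - pos[1] - slope * (tt - tt[1])
  list(t = tt, pos = pos, delta_h = max(pos) - min(pos))
}

#' Step length from the single inverted pendulum (model 1)
#'
#' The chord of a circular arc of radius `l_leg` subtending a CoM height
#' change `delta_h`: `S = 2 * sqrt(2 * l_leg * delta_h - delta_h^2)`.
#'
#' @param l_leg Leg length in m.
#' @param delta_h CoM height change in m, within `[0, l_leg]`.
#' @return Step length in m.
#' @export
step_length_model1 <- function(l_leg, delta_h) {
  stopifnot(l_leg > 0)
  if (any(delta_h < 0) || any(delta_h > l_leg)) {
    stop("invalid geometry: delta_h outside [0, l_leg]")
  }
  2 * sqrt(2 * l_leg * delta_h - delta_h^2)
}

#' Double-support pendulum length from the phase time ratio
#'
#' `l_2 = C * l_leg * (t_bip / t_sup)`, evaluated with the median phase
#' durations of the bout to curb per-step variability. `C = 1.1` relates
#' the length ratio of the two pendulum phases to their time ratio.
#'
#' @param l_leg Leg length in m.
#' @param t_bip_med,t_sup_med Median initial-double-support and
#'   single-support durations in s.
#' @param C Dimensionless length-ratio constant.
#' @return Effective double-support pendulum length in m.
#' @export
l2_from_time_ratio <- function(l_leg, t_bip_med, t_sup_med, C = 1.1) {
  if (t_sup_med <= 0) stop("single-support duration must be positive")
  stopifnot(t_bip_med >= 0, l_leg > 0)
  C * l_leg * (t_bip_med / t_sup_med)
}

#' Step length from the two-phase pendulum (model 2)
#'
#' A normal pendulum of length `l_2` during initial double support and an
#' inverted pendulum of leg length during single support, each contributing
#' the chord of its arc:
#' `S_bip = 2 * sqrt(2 * l_2 * delta_bip - delta_bip^2)`,
#' `S_sup = 2 * sqrt(2 * l_leg * delta_sup - delta_sup^2)`,
#' `S_step = S_bip + S_sup`. A height excursion exceeding its pendulum
#' length (a numerical artifact in noisy bouts) is clamped to 0.95 times
#' the length with a warning.
#'
#' @param l_leg Leg length in m.
#' @param l2 Double-support pendulum length in m.
#' @param delta_bip,delta_sup Height excursions during initial double
#'   support and single support, m.
#' @return List with `s_bip`, `s_sup`, `s_step` (m) and `clamped`.
#' @export
step_length_model2 <- function(l_leg, l2, delta_bip, delta_sup) {
  stopifnot(l_leg > 0, l2 >= 0, delta_bip >= 0, delta_sup >= 0)
  clamped <- FALSE
  if (delta_sup > l_leg) {
    warning("single-support height change exceeds leg length; clamping")
    delta_sup <- 0.95 * l_leg
    clamped <- TRUE
  }
  if (l2 > 0 && delta_bip > l2) {
    warning("double-support height change exceeds l2; clamping")
    delta_bip <- 0.95 * l2
    clamped <- TRUE
  }
  s_bip <- if (l2 > 0) 2 * sqrt(2 * l2 * delta_bip - delta_bip^2) else 0
  s_sup <- 2 * sqrt(2 * l_leg * delta_sup - delta_sup^2)
  list(s_bip = s_bip, s_sup = s_sup, s_step = s_bip + s_sup,
       clamped = clamped)
}

#' Add spatial quantities to an assembled stride table
#'
#' For each step with a full phase decomposition, extracts the detrended
#' CoM position trace over `[IC, IC_next]`, measures the total excursion
#' and the per-phase excursions (`[IC, FC_opp]` for double support,
#' `[FC_opp, IC_next]` for single support), and converts them to a step
#' length with the configured pendulum model. Stride length is the sum of
#' two consecutive step lengths within a run; gait speed is stride length
#' over stride time.
#'
#' @param strides Data frame from [assemble_strides()].
#' @param vert Vertical acceleration for the bout (package sign
#'   convention).
#' @param fs Sampling rate in Hz.
#' @param height Participant height in m.
#' @param cfg A [gait_config()].
#' @return The stride data frame with `delta_h`, `delta_bip`, `delta_sup`,
#'   `step_length`, `stride_length`, `gait_speed` columns added, and
#'   attributes `l_leg` and `l2`.
#' @export
add_spatial_metrics <- function(strides, vert, fs, height,
                                cfg = gait_config()) {
  df <- strides
  n <- nrow(df)
  df$delta_h <- df$delta_bip <- df$delta_sup <- NA_real_
  df$step_length <- df$stride_length <- df$gait_speed <- NA_real_
  if (!n) return(df)
  if (is.na(height) || height <= 0) {
    stop("participant height is required for spatial metrics")
  }
  l_leg <- cfg$leg_length_factor * height
  full <- !is.na(df$ic_next) & !is.na(df$t_sup)
  l2 <- if (any(full)) {
    l2_from_time_ratio(l_leg, stats::median(df$t_bip[full]),
                       stats::median(df$t_sup[full]), cfg$length_ratio_C)
  } else {
    NA_real_
  }
  for (i in which(full)) {
    tr <- com_height_change(vert, fs, c(df$ic[i], df$ic_next[i]))
    sub_range <- function(t0, t1) {
      p <- tr$pos[tr$t >= t0 - 0.5 / fs & tr$t <= t1 + 0.5 / fs]
      if (length(p) < 2) return(NA_real_)
      max(p) - min(p)
    }
    df$delta_h[i] <- tr$delta_h
    df$delta_bip[i] <- sub_range(df$ic[i], df$fc_opp[i])
    df$delta_sup[i] <- sub_range(df$fc_opp[i], df$ic_next[i])
    if (cfg$pendulum_model == 1L) {
      dh <- min(df$delta_h[i], l_leg)
      df$step_length[i] <- step_length_model1(l_leg, dh)
    } else {
      m2 <- suppressWarnings(
        step_length_model2(l_leg, l2, df$delta_bip[i], df$delta_sup[i]))
      df$step_length[i] <- m2$s_step
    }
  }
  if (n >= 2) {
    sl <- df$step_length[-n] + df$step_length[-1]
    ok <- !is.na(df$stride_time[-n]) & !is.na(sl)
    df$stride_length[c(ok, FALSE)] <- sl[ok]
    df$gait_speed <- df$stride_length / df$stride_time
  }
  attr(df, "l_leg") <- l_leg
  attr(df, "l2") <- l2
  attr(df, "rejections") <- attr(strides, "rejections")
  df
}
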