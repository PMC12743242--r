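# Kinematic gait-signal simulator: prescribed two-phase pendulum CoM
# trajectories with exact ground-truth contact events, phase durations,
# height excursions and step lengths. The generator is kinematic, not
# dynamic: trajectories are prescribed so ground truth is exact and the
# detectors only ever see accelerations.

# Design constants of the anterior-posterior waveform (see the methods
# vignette). The initial-contact complex is a first-derivative-of-Gaussian
# (trough-then-peak) transient whose smoothed-jerk landmarks straddle the
# true IC; the final contact is marked by a broad Gaussian push-off peak
# whose symmetric shape keeps the velocity-CWT maximum at the true FC.
AP_FC_AMP <- 4.0          # push-off peak amplitude, m/s^2
AP_FC_WIDTH_FRAC <- 0.06  # push-off Gaussian SD as a fraction of step time
AP_IC_AMP <- 3.5          # IC complex amplitude parameter, m/s^2
AP_IC_WIDTH_FRAC <- 0.04  # IC complex SD as a fraction of step time
AP_SYNC_AMP <- 0.8        # step-frequency AP component phase-locked to the
                          # vertical oscillation (anchors the axis-sign rule)
AP_FC_FUND_TRIM <- 0.4    # fraction of the push-off bump's fundamental
                          # removed (symmetric about the FC, so it adds no
                          # timing bias but strengthens the sign anchor)
AP_FC_H2_TRIM <- 0.65     # fraction of the bump's second harmonic removed
                          # (keeps the step period unambiguous in the
                          # wavelet-power autocovariance)
ML_SWAY_AMP <- 0.3        # medio-lateral sway at stride frequency, m/s^2
# nominal step-frequency -> wavelet-frequency relations assumed when
# placing the contact features (the detector's calibrated defaults mirror
# them): the IC complex is positioned so the smoothed-jerk midpoint rule
# lands on the true IC, and the push-off bump is positioned by a fixed
# point so the smoothed-velocity maximum lands on the true FC
IC_DESIGN_RELATION <- c(a = 3.0, b = 0.0)
FC_DESIGN_RELATION <- c(a = 3.0, b = 0.0)

#' Specify a simulated walker
#'
#' Parameters of one steady walking bout. The two-phase pendulum geometry
#' (double-support arc of effective length `C * leg_length * t_bip/t_sup`,
#' single-support inverted pendulum of `leg_length`) together with
#' `step_length` and `duty` fixes the per-phase forward travel and
#' center-of-mass height excursions; they are reported in the ground truth
#' rather than chosen independently, so the planted step lengths are
#' geometrically consistent with the planted height excursions.
#'
#' @param f_step Step frequency in Hz (0.5-5).
#' @param duty Fraction of the step time spent in initial double support
#'   (`t_bip / t_step`), in (0, 0.5).
#' @param leg_length Leg length in m.
#' @param step_length Step length in m (must be feasible for the geometry).
#' @param duration Bout duration in s.
#' @param fs Sampling rate in Hz.
#' @param tilt_deg Sensor tilt in degrees, length 2: rotation about the ML
#'   axis (vertical-AP mixing) and about the AP axis (vertical-ML mixing).
#' @param noise_sd SD of additive white Gaussian noise per channel, m/s^2.
#' @param seed Integer RNG seed (noise is reproducible; the RNG state of the
#'   session is restored afterwards).
#' @param length_ratio_C Pendulum length-ratio constant (default 1.1,
#'   matching the spatial model).
#' @return A list of class `"walker_spec"`.
#' @export
walker_spec <- function(f_step = 1.8, duty = 0.25, leg_length = 0.9,
                        step_length = 0.4 + 0.15 * f_step, duration = 30,
                        fs = 128, tilt_deg = c(0, 0), noise_sd = 0,
                        seed = 1L, length_ratio_C = 1.1) {
  stopifnot(f_step >= 0.5, f_step <= 5, duty > 0, duty < 0.5,
            leg_length > 0, step_length > 0, duration > 1, fs > 0,
            length(tilt_deg) == 2, noise_sd >= 0)
  if (step_length > 2 * leg_length) {
    stop("infeasible geometry: step length exceeds twice the leg length")
  }
  structure(list(f_step = f_step, duty = duty, leg_length = leg_length,
                 step_length = step_length, duration = duration, fs = fs,
                 tilt_deg = tilt_deg, noise_sd = noise_sd,
                 seed = as.integer(seed), length_ratio_C = length_ratio_C),
            class = "walker_spec")
}

#' Simulate a lumbar acceleration bout with exact ground truth
#'
#' Generates tri-axial acceleration for a steady walking bout. The vertical
#' channel is the second derivative of a center-of-mass height trajectory
#' built from circular pendulum arcs (normal pendulum during double
#' support, inverted pendulum during single support, with matched arc
#' slopes at the transitions and a short periodic smoothing that removes
#' the residual curvature jumps), plus gravity, stored in the package
#' convention (channel mean approximately -9.80665 m/s^2). The AP channel
#' carries a push-off peak at each final contact and a sharp
#' derivative-of-Gaussian complex at each initial contact, placed so the
#' detector's landmark definitions land on the true events under nominal
#' smoothing; the complex's low harmonics are removed so the
#' step-frequency band stays unambiguous. The third channel is
#' stride-frequency sway. A known tilt is applied as a rotation and seeded
#' Gaussian noise is added per the walker specification.
#'
#' @param spec A [walker_spec()].
#' @return List with elements `recording` (an [accel_recording()], channels
#'   ordered AP, ML, vertical before tilt) and `truth` (ground-truth event
#'   times, phase durations, height excursions, step lengths and the planted
#'   CoM trajectories).
#' @export
simulate_bout <- function(spec) {
  stopifnot(inherits(spec, "walker_spec"))
  g <- STANDARD_GRAVITY
  T_step <- 1 / spec$f_step
  t_bip <- spec$duty * T_step
  t_sup <- T_step - t_bip
  l_leg <- spec$leg_length
  l2 <- spec$length_ratio_C * l_leg * (t_bip / t_sup)
  S <- spec$step_length
  sin_g <- S / (2 * (l2 + l_leg))
  if (sin_g >= 0.999) stop("infeasible geometry: step too long for the arcs")
  gam <- asin(sin_g)
  S_bip <- S * l2 / (l2 + l_leg)
  S_sup <- S - S_bip
  delta_bip <- l2 * (1 - cos(gam))
  delta_sup <- l_leg * (1 - cos(gam))

  t <- seq(0, spec$duration, by = 1 / spec$fs)
  t0 <- 0.5 * T_step                      # first initial contact
  u <- (t - t0) %% T_step                 # time within the gait cycle

  # smooth periodic forward velocity whose phase integrals match the
  # per-phase travel (S_bip over double support, S_sup over single support)
  vbar <- S / T_step
  eps <- (S_bip - vbar * t_bip) /
    ((T_step / pi) * sin(pi * t_bip / T_step))
  ph <- 2 * pi * (u - t_bip / 2) / T_step
  xdot <- vbar + eps * cos(ph)
  xddot <- -eps * (2 * pi / T_step) * sin(ph)
  x <- vbar * u + eps * (T_step / (2 * pi)) *
    (sin(ph) + sin(pi * t_bip / T_step))

  # Height from the circular arcs as a function of forward position,
  # built on a dense periodic cycle grid. The raw arc profile is C1 at the
  # phase transitions (matched slopes) but its curvature jumps there; a
  # short periodic Gaussian smoothing makes it C-infinity so that the
  # sampled acceleration double-integrates back to the height trace, and
  # the vertical acceleration is obtained by spectral differentiation.
  nf <- 8192L
  uf <- (seq_len(nf) - 1) / nf * T_step
  phf <- 2 * pi * (uf - t_bip / 2) / T_step
  xf <- vbar * uf + eps * (T_step / (2 * pi)) *
    (sin(phf) + sin(pi * t_bip / T_step))
  hf <- numeric(nf)
  inb <- uf < t_bip
  hf[inb] <- l2 * cos(gam) - sqrt(l2^2 - (xf[inb] - S_bip / 2)^2)
  hf[!inb] <- sqrt(l_leg^2 - (xf[!inb] - S_bip - S_sup / 2)^2) -
    l_leg * cos(gam)
  sig_s <- 0.02 * T_step                  # smoothing SD, s
  gks <- exp(-(pmin(uf, T_step - uf)^2) / (2 * sig_s^2))
  hf_s <- Re(stats::fft(stats::fft(hf) * stats::fft(gks / sum(gks)),
                        inverse = TRUE)) / nf
  om <- 2 * pi / T_step *
    c(seq(0, nf / 2), seq(-nf / 2 + 1, -1))
  hddf <- Re(stats::fft(stats::fft(hf_s) * (-om^2), inverse = TRUE)) / nf
  interp_cyc <- function(yf, uu) {
    stats::approx(c(uf, T_step), c(yf, yf[1]), xout = uu)$y
  }
  h <- interp_cyc(hf_s, u)
  hdd <- interp_cyc(hddf, u)
  vert <- -(hdd + g)                      # sensor reads -g at rest

  # anterior-posterior waveform
  sig_c <- AP_IC_WIDTH_FRAC * T_step
  sig_fc <- AP_FC_WIDTH_FRAC * T_step
  f_ic_nom <- IC_DESIGN_RELATION[["a"]] * spec$f_step +
    IC_DESIGN_RELATION[["b"]]
  sig_k <- GAUS1_CENTRAL_FREQ / (sqrt(2) * f_ic_nom)
  sig_t <- sqrt(sig_c^2 + sig_k^2)
  cc <- (sqrt(3) - 1) / 2 * sig_t         # complex center offset past IC
  ic_complex <- function(uu) {
    AP_IC_AMP * ((uu - cc) / sig_c) * exp(-(uu - cc)^2 / (2 * sig_c^2))
  }
  wrap_sum <- function(uu, f) f(uu - T_step) + f(uu) + f(uu + T_step)
  # Step-frequency AP component phase-locked to the vertical channel's
  # fundamental (measured from the generated trajectory), so that the
  # cross-correlation sign rule for the AP axis is anchored positive by
  # construction. Any slope it adds at the FC is compensated below.
  a1 <- 2 * mean(-hdd * cos(2 * pi * u / T_step))
  b1 <- 2 * mean(-hdd * sin(2 * pi * u / T_step))
  phi_v <- atan2(b1, a1)
  # Place the push-off bump so that the maximum of the smoothed cycle
  # falls exactly on the true FC at the nominal FC-detection scale. On a
  # dense periodic cycle grid, the smoothed bump-free background bg adds a
  # slope at the FC that would displace the peak of the smoothed bump B;
  # the bump is shifted by -x where x solves B'(x) = -bg'(t_fc).
  f_fc_nom <- FC_DESIGN_RELATION[["a"]] * spec$f_step +
    FC_DESIGN_RELATION[["b"]]
  sig_kfc <- GAUS1_CENTRAL_FREQ / f_fc_nom   # e^{-(tau/sig)^2} width
  nd <- 4096L
  ug <- (seq_len(nd) - 1) / nd * T_step
  du <- T_step / nd
  gk <- exp(-(pmin(ug, T_step - ug) / sig_kfc)^2)
  gk_f <- stats::fft(gk / sum(gk))
  smooth_cycle <- function(x) {
    Re(stats::fft(stats::fft(x) * gk_f, inverse = TRUE)) / nd
  }
  bg <- AP_SYNC_AMP * cos(2 * pi * ug / T_step - phi_v) +
    wrap_sum(ug, ic_complex)
  cdd <- wrap_sum(ug, ic_complex)
  for (m in 1:2) {
    am <- 2 * mean(cdd * cos(2 * pi * m * ug / T_step))
    bm <- 2 * mean(cdd * sin(2 * pi * m * ug / T_step))
    bg <- bg - am * cos(2 * pi * m * ug / T_step) -
      bm * sin(2 * pi * m * ug / T_step)
  }
  bg_s <- smooth_cycle(bg)
  i_fc <- which.min(abs(ug - t_bip))
  ip <- if (i_fc == nd) 1L else i_fc + 1L
  im <- if (i_fc == 1L) nd else i_fc - 1L
  bg_slope <- (bg_s[ip] - bg_s[im]) / (2 * du)
  # smoothed bump alone, centered mid-grid to avoid wrap effects
  bump0 <- AP_FC_AMP * exp(-(ug - T_step / 2)^2 / (2 * sig_fc^2))
  b_s <- smooth_cycle(bump0)
  b_p <- (c(b_s[-1], b_s[1]) - c(b_s[nd], b_s[-nd])) / (2 * du)
  ctr <- which.min(abs(ug - T_step / 2))
  win <- ctr + seq(-nd %/% 8, nd %/% 8)
  xr <- ug[win] - T_step / 2
  off <- -xr[which.min(abs(b_p[win] + bg_slope))]
  fc_peak <- function(uu) {
    AP_FC_AMP * exp(-(uu - t_bip - off)^2 / (2 * sig_fc^2))
  }
  sync <- AP_SYNC_AMP * cos(2 * pi * u / T_step - phi_v)
  ap <- sync + wrap_sum(u, ic_complex) + wrap_sum(u, fc_peak)
  # remove the IC complex's first two harmonics (computed on a dense cycle
  # grid) plus the overall cycle mean, so the step-frequency band is not
  # biased by the sharp transient
  ud <- seq(0, T_step, length.out = 4097)[-1]
  cd <- wrap_sum(ud, ic_complex)
  fd <- wrap_sum(ud, fc_peak)
  drop_harmonic <- function(ap, train, m) {
    am <- 2 * mean(train * cos(2 * pi * m * ud / T_step))
    bm <- 2 * mean(train * sin(2 * pi * m * ud / T_step))
    ap - am * cos(2 * pi * m * u / T_step) -
      bm * sin(2 * pi * m * u / T_step)
  }
  ap <- drop_harmonic(drop_harmonic(ap, cd, 1), cd, 2)
  ap <- drop_harmonic(ap, AP_FC_FUND_TRIM * fd, 1)
  ap <- drop_harmonic(ap, AP_FC_H2_TRIM * fd, 2)
  ap <- ap - mean(fd + cd)

  ml <- ML_SWAY_AMP * sin(pi * spec$f_step * (t - t0))

  a <- cbind(ap, ml, vert)
  if (any(spec$tilt_deg != 0)) {
    th <- spec$tilt_deg * pi / 180
    # rotation about the ML axis (mixes AP and vertical), then about the
    # AP axis (mixes ML and vertical)
    R1 <- matrix(c(cos(th[1]), 0, sin(th[1]),
                   0, 1, 0,
                   -sin(th[1]), 0, cos(th[1])), 3, 3, byrow = TRUE)
    R2 <- matrix(c(1, 0, 0,
                   0, cos(th[2]), sin(th[2]),
                   0, -sin(th[2]), cos(th[2])), 3, 3, byrow = TRUE)
    a <- a %*% t(R2 %*% R1)
  }
  if (spec$noise_sd > 0) {
    a <- a + with_local_seed(spec$seed, {
      matrix(stats::rnorm(length(a), sd = spec$noise_sd), nrow(a), 3)
    })
  }
  colnames(a) <- NULL

  ic <- seq(t0, spec$duration, by = T_step)
  fc <- ic + t_bip
  fc <- fc[fc <= spec$duration]
  # phase-wise excursions of the (smoothed) generated height profile
  delta_bip_gen <- max(hf_s[inb]) - min(hf_s[inb])
  delta_sup_gen <- max(hf_s[!inb]) - min(hf_s[!inb])
  truth <- list(
    ic = ic, fc = fc, step_time = T_step, f_step = spec$f_step,
    t_bip = t_bip, t_sup = t_sup,
    delta_bip = delta_bip_gen, delta_sup = delta_sup_gen,
    delta_h = max(hf_s) - min(hf_s),
    delta_bip_arc = delta_bip, delta_sup_arc = delta_sup,
    step_length = S, s_bip = S_bip, s_sup = S_sup,
    l2 = l2, leg_length = l_leg,
    speed = S / T_step,
    com_height = h, com_forward = x + vbar * T_step *
      floor((t - t0) / T_step), t = t)
  list(recording = accel_recording(t, a, spec$fs,
                                   meta = list(source = "simulate_bout",
                                               spec = unclass(spec))),
       truth = truth)
}

# evaluate an expression with a temporary RNG seed, restoring session state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Noise level for a target signal-to-noise ratio
#'
#' Computes the white-noise SD giving a requested SNR (in dB) relative to
#' the RMS of the noiseless AP waveform of a walker specification.
#'
#' @param spec A [walker_spec()].
#' @param snr_db Target SNR in dB.
#' @return Noise SD in m/s^2.
#' @export
noise_sd_for_snr <- function(spec, snr_db) {
  clean <- spec
  clean$noise_sd <- 0
  clean$tilt_deg <- c(0, 0)
  sim <- simulate_bout(clean)
  ap <- sim$recording$a[, 1]
  sqrt(mean(ap^2)) / 10^(snr_db / 20)
}

#' Build the standard simulated fixture grid
#'
#' Twelve fixtures spanning slow/normal/fast step frequencies (1.2, 1.7,
#' 2.2 Hz), clean and moderate-noise conditions (SNR 10 dB on the AP
#' channel), and upright versus 5-degree-tilted sensors, with a manifest of
#' the planted parameters.
#'
#' @param f_step Step frequencies in Hz.
#' @param noise `"clean"`/`"moderate"` subset to include.
#' @param tilt Tilt magnitudes in degrees.
#' @param duration Bout duration in s.
#' @param seed Base RNG seed; each fixture uses `seed + index`.
#' @return List with `fixtures` (list of `list(name, spec, recording,
#'   truth)`) and `manifest` (data frame).
#' @export
make_test_suite <- function(f_step = c(1.2, 1.7, 2.2),
                            noise = c("clean", "moderate"),
                            tilt = c(0, 5), duration = 30, seed = 20L) {
  grid <- expand.grid(f_step = f_step, noise = noise, tilt = tilt,
                      stringsAsFactors = FALSE)
  fixtures <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    spec <- walker_spec(f_step = grid$f_step[i], duration = duration,
                        tilt_deg = c(grid$tilt[i], grid$tilt[i] / 2),
                        seed = seed + i)
    if (grid$noise[i] == "moderate") {
      spec$noise_sd <- noise_sd_for_snr(spec, 10)
    }
    sim <- simulate_bout(spec)
    nm <- sprintf("f%.1f_%s_tilt%g", grid$f_step[i], grid$noise[i],
                  grid$tilt[i])
    fixtures[[i]] <- list(name = nm, spec = spec,
                          recording = sim$recording, truth = sim$truth)
  }
  manifest <- cbind(grid,
                    noise_sd = vapply(fixtures,
                                      function(f) f$spec$noise_sd,
                                      numeric(1)),
                    name = vapply(fixtures, `[[`, character(1), "name"))
  list(fixtures = fixtures, manifest = manifest)
}
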