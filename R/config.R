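# Run configuration: every tunable parameter of the pipeline with its
# default, serializable to/from a plain-text YAML file so a run's effective
# configuration can be echoed into output metadata.

#' Pipeline run configuration
#'
#' Builds the full configuration object for [estimate_gait()] and the
#' lower-level stages. Every argument has a default; pass only what you want
#' to override. Defaults follow the published values of the algorithm where
#' one exists (filter bands and orders, the 0.6 sigma prominence unit, the
#' dynamic quality-control formulas, the 0.3 s matching window); remaining
#' constants are package choices documented in the methods vignette.
#'
#' @param units Units of the raw acceleration file: `"m/s^2"` or `"g"`.
#'   Inputs in g are multiplied by the standard gravity 9.80665.
#' @param time_col,accel_cols Column names (or 1-based indices) of the time
#'   column and the three acceleration channels in input files.
#' @param height Participant height in m (required for spatial metrics).
#' @param detector `"adaptive"` (AP-axis, dynamic scales; the v3 method) or
#'   `"legacy"` (vertical-axis comparator; the v2 method).
#' @param bandpass Axis-identification band-pass cutoffs in Hz.
#' @param lowpass Contact-detection low-pass cutoff in Hz.
#' @param filter_order Butterworth design order for the one-pass filter.
#' @param step_freq_band Frequency band in Hz searched for the mean step
#'   frequency (10 CWT scales span it).
#' @param n_scales Number of CWT scales spanning `step_freq_band`.
#' @param cwt_power `"signed"` (default) or `"abs"`: how the per-scale
#'   coefficients are combined into the CWT power signal. The signed sum
#'   preserves the step-periodic fundamental; rectification doubles the
#'   effective frequency content and can plant a half-period
#'   autocovariance peak.
#' @param acv_window Autocovariance window length in s.
#' @param acv_overlap Fractional overlap between autocovariance windows.
#' @param acv_min_lag,acv_max_lag Lag range in s within which the first
#'   autocovariance peak is accepted as a step-time estimate.
#' @param acv_prominence First-peak prominence as a fraction of the lag-0
#'   autocovariance.
#' @param scale_relation Affine step-frequency to wavelet-frequency
#'   relations, a list with elements `ic = c(a, b)` and `fc = c(a, b)`
#'   giving `f_CWT = a * f_step + b` in Hz. Defaults were fitted with
#'   [calibrate_scale_relation()] on the packaged simulator across the
#'   1.2-2.2 Hz step-frequency range.
#' @param prominence_factor Peak prominence threshold in units of the SD of
#'   the CWT coefficient series (sigma_Wn).
#' @param distance_factor Minimum peak separation as a fraction of the mean
#'   step time.
#' @param ic_search_margin Fraction of the mean step time immediately before
#'   a final contact excluded from the backward initial-contact search (the
#'   final contact produces its own jerk zero-crossing).
#' @param legacy_fs Sampling rate in Hz to which the legacy detector
#'   decimates.
#' @param legacy_scale_freq Wavelet central frequency in Hz for the legacy
#'   detector (1.25 Hz; scale 8 at 50 Hz).
#' @param legacy_height_factor Peak height threshold for the legacy detector
#'   as a fraction of the signal SD.
#' @param qc_mode `"dynamic"` (thresholds from the mean step time) or
#'   `"static"` (legacy constants).
#' @param t_max_stride,c_loading Static quality-control constants used when
#'   `qc_mode = "static"`.
#' @param pendulum_model Inverted pendulum model for step length: `2`
#'   (two-phase, default) or `1` (single inverted pendulum).
#' @param leg_length_factor Leg length as a fraction of height.
#' @param length_ratio_C Dimensionless constant relating the double-support
#'   pendulum length to leg length times the double/single support time
#'   ratio.
#' @param match_window Total event-matching window in s (half on each side).
#' @return A list of class `"gait_config"`.
#' @export
gait_config <- function(units = c("m/s^2", "g"),
                        time_col = "time",
                        accel_cols = c("ax", "ay", "az"),
                        height = NA_real_,
                        detector = c("adaptive", "legacy"),
                        bandpass = c(0.25, 7.5),
                        lowpass = 20,
                        filter_order = 4L,
                        step_freq_band = c(0.5, 5.0),
                        n_scales = 10L,
                        cwt_power = c("signed", "abs"),
                        acv_window = 5,
                        acv_overlap = 0.5,
                        acv_min_lag = 0.2,
                        acv_max_lag = 2.0,
                        acv_prominence = 0.1,
                        scale_relation = NULL,
                        prominence_factor = 0.6,
                        distance_factor = 0.5,
                        ic_search_margin = 0.1,
                        legacy_fs = 50,
                        legacy_scale_freq = 1.25,
                        legacy_height_factor = 0.5,
                        qc_mode = c("dynamic", "static"),
                        t_max_stride = 2.25,
                        c_loading = 0.2,
                        pendulum_model = 2L,
                        leg_length_factor = 0.53,
                        length_ratio_C = 1.1,
                        match_window = 0.3) {
  units <- match.arg(units)
  detector <- match.arg(detector)
  cwt_power <- match.arg(cwt_power)
  qc_mode <- match.arg(qc_mode)
  if (is.null(scale_relation)) scale_relation <- default_scale_relation()
  stopifnot(pendulum_model %in% c(1L, 2L),
            length(bandpass) == 2L, match_window > 0)
  cfg <- list(
    units = units, time_col = time_col, accel_cols = accel_cols,
    height = height, detector = detector,
    bandpass = bandpass, lowpass = lowpass,
    filter_order = as.integer(filter_order),
    step_freq_band = step_freq_band, n_scales = as.integer(n_scales),
    cwt_power = cwt_power,
    acv_window = acv_window, acv_overlap = acv_overlap,
    acv_min_lag = acv_min_lag, acv_max_lag = acv_max_lag,
    acv_prominence = acv_prominence,
    scale_relation = scale_relation,
    prominence_factor = prominence_factor,
    distance_factor = distance_factor,
    ic_search_margin = ic_search_margin,
    legacy_fs = legacy_fs, legacy_scale_freq = legacy_scale_freq,
    legacy_height_factor = legacy_height_factor,
    qc_mode = qc_mode, t_max_stride = t_max_stride, c_loading = c_loading,
    pendulum_model = as.integer(pendulum_model),
    leg_length_factor = leg_length_factor,
    length_ratio_C = length_ratio_C,
    match_window = match_window)
  class(cfg) <- "gait_config"
  cfg
}

#' Default step-frequency to wavelet-frequency relations
#'
#' Affine relations `f_CWT = a * f_step + b` (Hz) for the final-contact
#' (velocity CWT) and initial-contact (jerk CWT) stages of the adaptive
#' detector. The coefficients were obtained by running
#' [calibrate_scale_relation()] on simulated bouts spanning mean step
#' frequencies 1.2-2.2 Hz and are the packaged defaults; override via
#' `gait_config(scale_relation = ...)` to use externally derived relations.
#'
#' @return List with numeric `ic = c(a, b)` and `fc = c(a, b)`.
#' @export
default_scale_relation <- function() {
  list(ic = c(a = 3, b = 0), fc = c(a = 3, b = 0))
}

#' @export
print.gait_config <- function(x, ...) {
  cat("<gait_config>\n")
  flat <- unlist(lapply(x, function(v) paste(format(v), collapse = ", ")))
  for (nm in names(flat)) cat(sprintf("  %-22s %s\n", nm, flat[[nm]]))
  invisible(x)
}

#' Read / write a run configuration file
#'
#' Configurations serialize to plain YAML. Unknown keys are rejected so that
#' typos do not silently fall back to defaults.
#'
#' @param path File path.
#' @param cfg A `gait_config` object.
#' @return `read_config` returns a `gait_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(gait_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$scale_relation)) {
    raw$scale_relation <- lapply(raw$scale_relation, unlist)
  }
  do.call(gait_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "gait_config"))
  out <- unclass(cfg)
  out$scale_relation <- lapply(out$scale_relation, as.list)
  yaml::write_yaml(out, path)
  invisible(path)
}
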