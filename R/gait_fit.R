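# Top-level estimator: one call from a recording to a fitted gait object.

#' Estimate gait events and metrics for a walking bout
#'
#' Runs the full pipeline on one recording: axis identification and tilt
#' correction, mean step-frequency estimation, contact-event detection
#' (adaptive AP-axis detector by default, or the legacy vertical-axis
#' comparator), dynamic physiological quality control, inverted-pendulum
#' spatial modeling, and per-stride/per-bout metrics.
#'
#' @param rec An [accel_recording()] (or a file path, read with
#'   [read_recording()]).
#' @param height Participant height in m; overrides `cfg$height`. Spatial
#'   metrics are skipped when no height is available.
#' @param cfg A [gait_config()].
#' @return Object of class `"gait_fit"` with elements `profile`, `events`,
#'   `thresholds`, `strides` (data frame), `metrics` (a `gait_metrics`),
#'   `config`, and the tilt-corrected `recording`.
#' @examples
#' sim <- simulate_bout(walker_spec(f_step = 1.8, duration = 20))
#' fit <- estimate_gait(sim$recording, height = 1.7)
#' summary(fit)
#' @export
estimate_gait <- function(rec, height = NULL, cfg = gait_config()) {
  if (is.character(rec)) rec <- read_recording(rec, cfg)
  stopifnot(inherits(rec, "accel_recording"))
  if (!is.null(height)) cfg$height <- height
  prof <- bout_profile(rec, cfg)
  events <- if (cfg$detector == "adaptive") {
    detect_contacts(prof, cfg)
  } else {
    detect_contacts_legacy(prof$recording$a[, prof$vertical], rec$fs, cfg)
  }
  thr <- if (cfg$qc_mode == "dynamic") {
    dynamic_thresholds(prof$step_time)
  } else {
    legacy_thresholds(cfg$t_max_stride, cfg$c_loading)
  }
  strides <- assemble_strides(events, thr)
  if (!is.na(cfg$height) && cfg$height > 0) {
    strides <- add_spatial_metrics(strides, prof$recording$a[, prof$vertical],
                                   rec$fs, cfg$height, cfg)
  }
  metrics <- compute_metrics(strides)
  structure(list(profile = prof, events = events, thresholds = thr,
                 strides = metrics$strides, metrics = metrics,
                 config = cfg, recording = prof$recording),
            class = "gait_fit")
}

#' @export
print.gait_fit <- function(x, ...) {
  cat(sprintf("Gait bout fit (%s detector)\n", x$events$detector))
  print(x$profile)
  cat(sprintf("  events: %d IC, %d FC\n",
              length(x$events$ic), length(x$events$fc)))
  print(x$metrics)
  invisible(x)
}

#' @export
summary.gait_fit <- function(object, ...) {
  s <- object$metrics$summary
  out <- data.frame(metric = names(s),
                    value = vapply(s, function(v) as.numeric(v)[1],
                                   numeric(1)),
                    row.names = NULL)
  class(out) <- c("summary.gait_fit", "data.frame")
  out
}

#' @export
print.summary.gait_fit <- function(x, ...) {
  cat("Bout summary (medians across steps):\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @export
coef.gait_fit <- function(object, ...) {
  s <- object$metrics$summary
  unlist(s[c("step_time", "stride_time", "cadence", "step_length",
             "stride_length", "gait_speed")])
}

#' @export
as.data.frame.gait_fit <- function(x, ...) x$strides

#' @export
plot.gait_fit <- function(x, channel = c("ap", "vertical"), xlim = NULL,
                          ...) {
  channel <- match.arg(channel)
  rec <- x$recording
  j <- if (channel == "ap") x$profile$ap else x$profile$vertical
  y <- rec$a[, j]
  if (channel == "vertical") y <- y + STANDARD_GRAVITY
  graphics::plot(rec$t, y, type = "l", col = "grey30",
                 xlab = "time (s)", ylab = sprintf("%s accel (m/s^2)",
                                                   channel),
                 xlim = xlim, ...)
  graphics::abline(v = x$events$ic, col = "firebrick", lty = 2)
  graphics::abline(v = x$events$fc, col = "steelblue", lty = 3)
  graphics::legend("topright", c("IC", "FC"), lty = c(2, 3),
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}
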