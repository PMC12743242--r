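# Per-stride and per-bout spatiotemporal gait metrics.

#' Compute gait metrics from a stride table
#'
#' Adds cadence (`60 / t_step`, steps/min) per row and summarizes the bout
#' with the median of each metric across steps (the standard midpoint
#' convention for even counts), together with step/stride/rejection counts.
#' Row-level identities hold exactly: `cadence * t_step = 60` and
#' `gait_speed * stride_time = stride_length`.
#'
#' @param strides Stride data frame from [assemble_strides()], optionally
#'   with spatial columns from [add_spatial_metrics()].
#' @return List of class `"gait_metrics"` with `strides` (the per-row
#'   table including `cadence`) and `summary` (named medians and counts).
#' @export
compute_metrics <- function(strides) {
  df <- as.data.frame(strides)
  df$cadence <- if (nrow(df)) 60 / df$t_step else numeric(0)
  med <- function(cl) {
    if (!cl %in% names(df)) return(NA_real_)
    v <- df[[cl]][!is.na(df[[cl]])]
    if (!length(v)) NA_real_ else stats::median(v)
  }
  summary <- list(
    n_steps = nrow(df),
    n_strides = if (nrow(df)) sum(!is.na(df$stride_time)) else 0L,
    n_rejected = length(attr(strides, "rejections")),
    step_time = med("t_step"),
    stride_time = med("stride_time"),
    t_bip = med("t_bip"),
    t_sup = med("t_sup"),
    stance = med("stance"),
    cadence = med("cadence"),
    delta_h = med("delta_h"),
    step_length = med("step_length"),
    stride_length = med("stride_length"),
    gait_speed = med("gait_speed"))
  structure(list(strides = df, summary = summary), class = "gait_metrics")
}

#' @export
print.gait_metrics <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<gait_metrics> %d steps, %d strides (%d candidates rejected)\n",
              s$n_steps, s$n_strides, s$n_rejected))
  show <- c(step_time = "s", stride_time = "s", cadence = "steps/min",
            step_length = "m", stride_length = "m", gait_speed = "m/s")
  for (nm in names(show)) {
    if (!is.na(s[[nm]])) {
      cat(sprintf("  median %-13s %8.3f %s\n", nm, s[[nm]], show[[nm]]))
    }
  }
  invisible(x)
}
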