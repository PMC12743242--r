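# Step/stride assembly from contact events and the physiological
# quality-control thresholds (dynamic or legacy static).

#' Quality-control thresholds
#'
#' Dynamic thresholds scale with the bout mean step time `x`:
#' maximum stride time `t_max_stride = 2x + 1` (at least 2 SDs above the
#' expected mean stride time) and loading factor
#' `C_loading = 0.17x + 0.05` (the loading factor falls as walking speed
#' rises). The derived limits are: maximum initial double support
#' `C_loading * t_max_stride`, and maximum stance
#' `t_max_stride / 2 + C_loading * t_max_stride`. The legacy static pair
#' (2.25 s, 0.2) is available via [legacy_thresholds()].
#'
#' @param step_time Bout mean step time in s, within [0.2, 2].
#' @return List of class `"qc_thresholds"` with `t_max_stride`,
#'   `c_loading`, `max_loading`, `max_stance`, `mode`.
#' @export
dynamic_thresholds <- function(step_time) {
  if (step_time < 0.2 || step_time > 2) {
    stop("mean step time outside the supported range [0.2, 2] s")
  }
  t_max <- 2 * step_time + 1
  c_load <- 0.17 * step_time + 0.05
  qc_thresholds(t_max, c_load, mode = "dynamic")
}

#' @rdname dynamic_thresholds
#' @param t_max_stride,c_loading Static threshold values.
#' @export
legacy_thresholds <- function(t_max_stride = 2.25, c_loading = 0.2) {
  qc_thresholds(t_max_stride, c_loading, mode = "static")
}

qc_thresholds <- function(t_max_stride, c_loading, mode) {
  stopifnot(t_max_stride > 0, c_loading > 0)
  structure(list(t_max_stride = t_max_stride, c_loading = c_loading,
                 max_loading = c_loading * t_max_stride,
                 max_stance = t_max_stride / 2 + c_loading * t_max_stride,
                 mode = mode),
            class = "qc_thresholds")
}

#' @export
print.qc_thresholds <- function(x, ...) {
  cat(sprintf(paste0(
    "<qc_thresholds> (%s) t_max_stride %.3f s, C_loading %.3f\n",
    "  max loading %.3f s, max stance %.3f s\n"),
    x$mode, x$t_max_stride, x$c_loading, x$max_loading, x$max_stance))
  invisible(x)
}

#' Assemble quality-controlled steps and strides from contact events
#'
#' Each step is a group of one IC and the two following FCs (opposite side,
#' then same side). Candidates are screened left to right against three
#' rules: (1) loading (initial double support, IC to first FC) below
#' `C_loading * t_max_stride`; (2) stance (IC to second FC) below
#' `t_max_stride / 2` plus the rule-1 limit; (3) stride time (two
#' consecutive step times) below `t_max_stride`. When two ICs share the
#' same first FC the later IC wins (the earlier one would imply an
#' implausibly long loading phase). Continuity requires a retained step's
#' same-side FC to be the next step's opposite-side FC; breaks partition
#' the bout into runs, and step/stride times are only defined within runs.
#' The terminal step of a run has no following IC and therefore no step
#' time.
#'
#' @param events A [contact_events()].
#' @param thr A `qc_thresholds` object.
#' @return Data frame with one row per retained step: `ic`, `fc_opp`,
#'   `fc_same`, `ic_next`, `t_bip`, `t_sup`, `t_step`, `stance`,
#'   `stride_time`, `run`; attribute `"rejections"` logs dropped
#'   candidates and reasons.
#' @export
assemble_strides <- function(events, thr) {
  ic <- events$ic
  fc <- events$fc
  rej <- list()
  rows <- list()
  for (k in seq_along(ic)) {
    above <- fc[fc > ic[k]]
    if (length(above) < 2) next
    if (k < length(ic) && ic[k + 1] < above[1]) {
      rej[[length(rej) + 1]] <- c(ic = ic[k], reason = "shared first FC")
      next                               # later IC claims this FC pair
    }
    fc_opp <- above[1]
    fc_same <- above[2]
    t_bip <- fc_opp - ic[k]
    stance <- fc_same - ic[k]
    if (t_bip >= thr$max_loading) {
      rej[[length(rej) + 1]] <- c(ic = ic[k], reason = "loading")
      next
    }
    if (stance >= thr$max_stance) {
      rej[[length(rej) + 1]] <- c(ic = ic[k], reason = "stance")
      next
    }
    rows[[length(rows) + 1]] <-
      data.frame(ic = ic[k], fc_opp = fc_opp, fc_same = fc_same,
                 t_bip = t_bip, stance = stance)
  }
  if (!length(rows)) {
    out <- data.frame(ic = numeric(0), fc_opp = numeric(0),
                      fc_same = numeric(0), ic_next = numeric(0),
                      t_bip = numeric(0), t_sup = numeric(0),
                      t_step = numeric(0), stance = numeric(0),
                      stride_time = numeric(0), run = integer(0))
    attr(out, "rejections") <- rej
    return(out)
  }
  df <- do.call(rbind, rows)
  n <- nrow(df)
  # continuity: same-side FC must be the next step's opposite-side FC
  cont <- c(df$fc_same[-n] == df$fc_opp[-1], FALSE)
  df$run <- cumsum(c(1L, as.integer(!cont[-n])))
  df$ic_next <- c(df$ic[-1], NA_real_)
  df$ic_next[!cont] <- NA_real_
  df$t_step <- df$ic_next - df$ic
  df$t_sup <- df$t_step - df$t_bip
  bad <- !is.na(df$t_sup) & df$t_sup <= 0
  if (any(bad)) {
    # non-positive single support: sever the chain at these steps
    df$t_step[bad] <- NA_real_
    df$t_sup[bad] <- NA_real_
    df$ic_next[bad] <- NA_real_
  }
  # stride time spans two consecutive step times within a run
  df$stride_time <- rep(NA_real_, n)
  if (n >= 2) {
    same_run <- df$run[-n] == df$run[-1]
    st <- df$t_step[-n] + df$t_step[-1]
    ok <- same_run & !is.na(st) & st < thr$t_max_stride
    df$stride_time[c(ok, FALSE)] <- st[ok]
    over <- same_run & !is.na(st) & st >= thr$t_max_stride
    for (i in which(over)) {
      rej[[length(rej) + 1]] <- c(ic = df$ic[i], reason = "stride time")
    }
  }
  df <- df[, c("ic", "fc_opp", "fc_same", "ic_next", "t_bip", "t_sup",
               "t_step", "stance", "stride_time", "run")]
  rownames(df) <- NULL
  attr(df, "rejections") <- rej
  df
}
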