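# Reading and writing recordings, event lists and stride tables.

STANDARD_GRAVITY <- 9.80665

#' Construct an acceleration recording
#'
#' The internal container for a uniformly sampled tri-axial lumbar
#' acceleration bout. Time is float seconds from bout start; acceleration is
#' stored in m/s^2 with the gravity component present in the raw signal.
#'
#' @param t Time in seconds, strictly increasing, uniform grid.
#' @param a Numeric matrix with 3 columns of acceleration in m/s^2.
#' @param fs Sampling rate in Hz.
#' @param meta Free-form provenance list (source file, original units, ...).
#' @return Object of class `"accel_recording"` with elements `t`, `a`, `fs`,
#'   `meta`.
#' @export
accel_recording <- function(t, a, fs, meta = list()) {
  a <- as.matrix(a)
  stopifnot(fs > 0, ncol(a) == 3, nrow(a) == length(t), length(t) >= 2)
  if (abs(stats::median(diff(t)) - 1 / fs) > 1e-6) {
    stop("time grid is inconsistent with the stated sampling rate")
  }
  if (nrow(a) < 2 * fs) {
    stop("recording shorter than 2 s; too short for processing")
  }
  structure(list(t = as.numeric(t), a = unname(a), fs = fs, meta = meta),
            class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf(
    "<accel_recording> %.2f s at %g Hz (%d samples), channel means: %s m/s^2\n",
    x$t[length(x$t)] - x$t[1], x$fs, nrow(x$a),
    paste(sprintf("%.2f", colMeans(x$a)), collapse = ", ")))
  invisible(x)
}

#' Read a tri-axial recording from a delimited text file
#'
#' Expects a header row and one time column plus three acceleration columns
#' (names or positions set in the configuration). Units are converted to
#' m/s^2 (x 9.80665 for g inputs), time is rebased to start at zero, and
#' irregular timestamps are repaired by linear interpolation onto the
#' nominal uniform grid when the observed jitter exceeds 1e-4 s.
#'
#' @param path Path to a CSV/TSV file (delimiter sniffed from the header).
#' @param cfg A [gait_config()]; `time_col`, `accel_cols` and `units` are
#'   used.
#' @return An [accel_recording()].
#' @export
read_recording <- function(path, cfg = gait_config()) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(";", header)) ";" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "")
  pick <- function(col) {
    if (is.numeric(col)) {
      if (col > ncol(df)) stop("column index ", col, " out of range")
      return(df[[col]])
    }
    if (!col %in% names(df)) {
      stop("missing column '", col, "' in ", basename(path))
    }
    df[[col]]
  }
  t <- as.numeric(pick(cfg$time_col))
  a <- vapply(cfg$accel_cols, function(cl) as.numeric(pick(cl)),
              numeric(nrow(df)))
  if (anyNA(t) || anyNA(a)) stop("non-numeric values in data columns")
  if (any(diff(t) <= 0)) {
    # tolerate isolated duplicates (repaired below) but not reversals
    if (any(diff(t) < 0)) stop("time column is not monotone")
  }
  if (cfg$units == "g") a <- a * STANDARD_GRAVITY
  t <- t - t[1]
  dt <- stats::median(diff(t))
  if (dt <= 0) stop("cannot infer sampling interval")
  fs <- 1 / dt
  jitter <- max(abs(diff(t) - dt))
  if (jitter > 1e-4) {
    # resample onto the nominal grid by linear interpolation; duplicated
    # timestamps keep their first sample
    keep <- !duplicated(t)
    a <- a[keep, , drop = FALSE]
    t <- t[keep]
    tg <- seq(0, t[length(t)], by = dt)
    a <- vapply(1:3, function(j) {
      stats::approx(t, a[, j], xout = tg, rule = 2)$y
    }, numeric(length(tg)))
    t <- tg
  }
  if (length(t) < 2 * fs) stop("recording shorter than 2 s")
  accel_recording(t, a, fs,
                  meta = list(source = path, original_units = cfg$units))
}

# column layout of a stride table on disk
STRIDE_COLS <- c("ic", "fc_opp", "fc_same", "ic_next", "t_bip", "t_sup",
                 "t_step", "stance", "stride_time", "delta_h", "delta_bip",
                 "delta_sup", "step_length", "stride_length", "gait_speed",
                 "cadence")

#' Write / read a stride table
#'
#' One row per quality-controlled step, ordered by initial-contact time,
#' with times in s, lengths in m, speed in m/s and cadence in steps/min.
#' Values are written with full precision so a round trip is lossless to
#' better than 1e-9. An empty stride list writes the header only.
#'
#' @param strides Data frame of strides (as produced by [estimate_gait()] or
#'   [assemble_strides()] plus the spatial stage); missing columns are
#'   filled with NA.
#' @param path Output CSV path.
#' @return `write_stride_table` returns `path` invisibly;
#'   `read_stride_table` returns the stride data frame.
#' @export
write_stride_table <- function(strides, path) {
  df <- as.data.frame(strides)
  if (nrow(df)) {
    stopifnot(!is.unsorted(df$ic))
    for (cl in setdiff(STRIDE_COLS, names(df))) df[[cl]] <- NA_real_
    df <- df[, STRIDE_COLS]
    df[] <- lapply(df, function(v) sprintf("%.12g", v))
  } else {
    df <- as.data.frame(matrix(nrow = 0, ncol = length(STRIDE_COLS),
                               dimnames = list(NULL, STRIDE_COLS)))
  }
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stride_table
#' @export
read_stride_table <- function(path) {
  df <- utils::read.csv(path)
  df[] <- lapply(df, as.numeric)
  df
}

#' Write / read a contact-event list
#'
#' Two-column CSV (`time`, `event`) with `event` in `{"ic", "fc"}`, sorted
#' by time within each event type.
#'
#' @param events A `contact_events` object (see [contact_events()]).
#' @param path CSV path.
#' @return `write_events` returns `path` invisibly; `read_events` returns a
#'   `contact_events` object (detector tag taken from the file attribute
#'   column if present).
#' @export
write_events <- function(events, path) {
  df <- rbind(
    data.frame(time = events$ic, event = rep("ic", length(events$ic))),
    data.frame(time = events$fc, event = rep("fc", length(events$fc))))
  df <- df[order(df$time), , drop = FALSE]
  utils::write.table(
    data.frame(time = sprintf("%.12g", df$time), event = df$event),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path)
  contact_events(ic = as.numeric(df$time[df$event == "ic"]),
                 fc = as.numeric(df$time[df$event == "fc"]),
                 detector = "file")
}

#' Write a run-metadata sidecar
#'
#' JSON sidecar with the effective configuration, package version and the
#' bout profile, written next to analysis outputs for provenance.
#'
#' @param fit A `gait_fit` object.
#' @param path Output path (.json).
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(fit, path) {
  stopifnot(inherits(fit, "gait_fit"))
  meta <- list(
    package = "lumbargait",
    version = as.character(utils::packageVersion("lumbargait")),
    config = unclass(fit$config),
    profile = fit$profile[c("vertical", "vertical_sign", "ap", "ap_sign",
                            "step_time", "step_freq")],
    n_strides = nrow(fit$strides))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
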