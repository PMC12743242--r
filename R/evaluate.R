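# Scoring detected events and metrics against a reference: one-to-one
# event matching, sensitivity/precision/F1, MAE, and ICC(2,1).

#' Match detected events to reference events
#'
#' One-to-one greedy matching: reference events are visited in time order
#' and each takes its nearest unmatched detected event within half the
#' total window. Unmatched reference events are false negatives; unmatched
#' detected events inside the analysis region are false positives; detected
#' events outside the region are ignored (mirroring events off the
#' reference walkway), as are reference events outside it. The signed
#' timing error convention is detected minus reference (positive = late
#' detection), and MAE is computed over matched events only. Metrics whose
#' denominator is zero are reported as `NA`, not 0.
#'
#' @param detected,reference Sorted event times in s.
#' @param window Total matching window in s (default 0.3, i.e. 0.15 s on
#'   each side).
#' @param region Optional `[t0, t1]` analysis region in s.
#' @return List of class `"event_match"`: `tp`, `fp`, `fn`, `errors`
#'   (signed, matched events), `sensitivity`, `precision`, `f1`, `mae`,
#'   and the matched index pairs.
#' @export
match_events <- function(detected, reference, window = 0.3, region = NULL) {
  stopifnot(!is.unsorted(detected), !is.unsorted(reference), window > 0)
  half <- window / 2
  det_in <- if (is.null(region)) rep(TRUE, length(detected)) else {
    detected >= region[1] & detected <= region[2]
  }
  if (!is.null(region)) {
    reference <- reference[reference >= region[1] & reference <= region[2]]
  }
  used <- rep(FALSE, length(detected))
  pairs <- matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("reference", "detected")))
  errors <- numeric(0)
  for (r in seq_along(reference)) {
    d <- abs(detected - reference[r])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= half) {
      used[j] <- TRUE
      pairs <- rbind(pairs, c(r, j))
      errors <- c(errors, detected[j] - reference[r])
    }
  }
  tp <- nrow(pairs)
  fn <- length(reference) - tp
  fp <- sum(!used & det_in)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0) {
    2 * prec * sens / (prec + sens)
  } else {
    NA_real_
  }
  mae <- if (tp > 0) mean(abs(errors)) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, errors = errors,
                 sensitivity = sens, precision = prec, f1 = f1, mae = mae,
                 pairs = pairs, window = window, region = region),
            class = "event_match")
}

#' @export
print.event_match <- function(x, ...) {
  cat(sprintf(
    "<event_match> TP %d, FP %d, FN %d | F1 %.3f, MAE %.4f s\n",
    x$tp, x$fp, x$fn,
    if (is.na(x$f1)) NA else x$f1, if (is.na(x$mae)) NA else x$mae))
  invisible(x)
}

#' Intraclass correlation ICC(2,1)
#'
#' Single-measure, two-way random-effects, absolute-agreement ICC from the
#' two-way ANOVA decomposition of a subjects-by-raters matrix:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with MSR,
#' MSC, MSE the row (subject), column (rater) and residual mean squares.
#' The 95% confidence interval uses the standard F-distribution bounds
#' with Satterthwaite degrees of freedom.
#'
#' @param x Numeric matrix, subjects in rows, raters/methods in columns, no
#'   missing cells.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `"icc"`: `icc`, `lower`, `upper`, mean squares and
#'   dimensions.
#' @export
icc_2_1 <- function(x, conf_level = 0.95) {
  x <- as.matrix(x)
  stopifnot(is.numeric(x), nrow(x) >= 2, ncol(x) >= 2, !anyNA(x))
  n <- nrow(x)
  k <- ncol(x)
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= mse) {
    warning("between-subject variance does not exceed residual variance; ",
            "ICC is degenerate")
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  fj <- msc / mse
  num <- (k - 1) * (n - 1) *
    (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
  den <- (n - 1) * k^2 * icc^2 * fj^2 +
    (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- num / den
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  structure(list(icc = icc, lower = lower, upper = upper,
                 msr = msr, msc = msc, mse = mse, n = n, k = k,
                 conf_level = conf_level),
            class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.4f (%d%% CI %.4f-%.4f), n = %d subjects, k = %d raters\n",
              x$icc, round(100 * x$conf_level), x$lower, x$upper, x$n, x$k))
  invisible(x)
}
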