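# Shared signal operators: zero-phase Butterworth filtering, tilt correction,
# cumulative-trapezoid integration, and the single-scale Gaussian
# first-derivative CWT with its frequency <-> scale convention.

#' Zero-phase Butterworth filter
#'
#' Designs a Butterworth filter and applies it forward and backward so the
#' output has zero phase lag. Event timing is the deliverable of this
#' package, so all filtering is zero-phase: a one-pass IIR filter would bias
#' contact-event times by tens of milliseconds. The signal is extended at
#' both ends by odd reflection and the filter is seeded with its steady-state
#' initial conditions, so edge transients are confined to the (discarded)
#' extensions.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param kind `"lowpass"` or `"bandpass"`.
#' @param cutoffs Cutoff frequency in Hz (length 1 for lowpass, 2 for
#'   bandpass). Must lie strictly inside (0, fs/2).
#' @param order Order of the one-pass filter (default 4).
#' @return Filtered signal, same length as `x`.
#' @export
butterworth_filter <- function(x, fs, kind = c("bandpass", "lowpass"),
                               cutoffs, order = 4L) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(x), fs > 0)
  nyq <- fs / 2
  if (any(cutoffs <= 0) || any(cutoffs >= nyq)) {
    stop("cutoff frequencies must lie strictly inside (0, fs/2)")
  }
  if (kind == "bandpass" && length(cutoffs) != 2L) {
    stop("bandpass requires two cutoff frequencies")
  }
  if (kind == "lowpass" && length(cutoffs) != 1L) {
    stop("lowpass requires a single cutoff frequency")
  }
  bf <- signal::butter(order, sort(cutoffs) / nyq,
                       type = if (kind == "bandpass") "pass" else "low")
  # pad long enough for the slowest pole's transient (lowest cutoff)
  padlen <- max(3L * (2L * order + 1L), ceiling(4 * fs / min(cutoffs)))
  filtfilt_padded(bf$b, bf$a, x, padlen)
}

# Forward-backward IIR filtering with odd-reflection padding and
# steady-state initial conditions (direct form II transposed).
filtfilt_padded <- function(b, a, x, padlen = NULL) {
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  if (is.null(padlen)) padlen <- 3L * (nfilt - 1L)
  padlen <- min(padlen, length(x) - 1L)
  if (length(x) <= 3L * (nfilt - 1L)) {
    stop("signal too short for the requested filter (need > ",
         3L * (nfilt - 1L), " samples)")
  }
  # odd extension about the end points
  pre <- 2 * x[1] - x[seq(padlen + 1L, 2L)]
  post <- 2 * x[length(x)] - x[seq(length(x) - 1L, length(x) - padlen)]
  xx <- c(pre, x, post)
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, xx, zi * xx[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[seq(padlen + 1L, padlen + length(x))]
}

# Steady-state initial filter state for a unit-step input so that
# filtering a constant yields that constant from the first sample.
lfilter_zi <- function(b, a) {
  n <- length(a) - 1L
  if (a[1] != 1) {
    b <- b / a[1]
    a <- a / a[1]
  }
  # companion matrix of a, transposed
  A <- matrix(0, n, n)
  A[1, ] <- -a[-1]
  if (n > 1) A[cbind(seq(2, n), seq(1, n - 1))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n) - t(A), B)
}

# Direct form II transposed IIR filter with initial state zi.
iir_filter <- function(b, a, x, zi) {
  n <- length(a) - 1L
  y <- numeric(length(x))
  z <- zi
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (n > 1) {
      z[seq_len(n - 1)] <- b[seq(2, n)] * xi + z[seq(2, n)] - a[seq(2, n)] * yi
    }
    z[n] <- b[n + 1] * xi - a[n + 1] * yi
    y[i] <- yi
  }
  y
}

#' Gravity-based tilt correction
#'
#' Rotates the three acceleration channels so that the time-averaged gravity
#' vector lies along the vertical axis, using the per-channel mean
#' accelerations over the whole bout (small-angle orientation correction for
#' an approximately upright walker). Two sequential rotations are applied:
#' vertical-AP plane first, then vertical-ML. Being pure rotations, the
#' total signal energy across the three channels is preserved.
#'
#' @param a Numeric matrix with three columns of acceleration in m/s^2.
#' @param vertical Column index of the vertical channel (sensor measures -g
#'   at rest, so its mean must be strongly negative after sign alignment).
#' @param ap Column index of the anterior-posterior channel.
#' @return Matrix of the same shape with rotated channels.
#' @export
tilt_correct <- function(a, vertical, ap) {
  stopifnot(is.matrix(a), ncol(a) == 3, vertical != ap)
  ml <- setdiff(1:3, c(vertical, ap))
  mv <- mean(a[, vertical])
  if (abs(mv) < 0.5 * 9.80665) {
    stop("vertical channel mean not gravity-dominated; ",
         "bout does not look like upright walking")
  }
  # rotate in the vertical-AP plane to zero the mean AP acceleration
  alpha <- atan2(mean(a[, ap]), -mv)
  ap2 <- cos(alpha) * a[, ap] + sin(alpha) * a[, vertical]
  v2 <- -sin(alpha) * a[, ap] + cos(alpha) * a[, vertical]
  # then in the vertical-ML plane to zero the mean ML acceleration
  beta <- atan2(mean(a[, ml]), -mean(v2))
  ml2 <- cos(beta) * a[, ml] + sin(beta) * v2
  v3 <- -sin(beta) * a[, ml] + cos(beta) * v2
  out <- a
  out[, ap] <- ap2
  out[, ml] <- ml2
  out[, vertical] <- v3
  out
}

#' Cumulative trapezoid integration
#'
#' @param x Numeric signal sampled at `fs` Hz.
#' @param fs Sampling rate in Hz.
#' @return Integral of `x` with respect to time, starting at 0; same length
#'   as `x`.
#' @export
integrate_trapz <- function(x, fs) {
  stopifnot(length(x) >= 2, fs > 0)
  as.numeric(pracma::cumtrapz(seq_along(x) / fs, x))
}

# Discrete Gaussian first-derivative wavelet sampled at a given scale,
# L2-normalized. Oriented so that the transform of a slowly varying signal
# approximates its (smoothed) first derivative.
gaus1_kernel <- function(scale) {
  half <- ceiling(5 * scale)
  u <- seq(-half, half) / scale
  psi <- u * exp(-u^2)
  psi <- psi - mean(psi)        # exact zero mean in discrete form
  psi / sqrt(sum(psi^2))
}

#' Single-scale CWT with a Gaussian first-derivative wavelet
#'
#' Correlates the signal with an L2-normalized first derivative of a
#' Gaussian dilated to `scale` samples. The output approximates a smoothed
#' derivative of the input: band-tuned differentiation. Edges are handled by
#' symmetric reflection; downstream detectors discard peaks within the edge
#' margin (see [cwt_edge_margin()]).
#'
#' @param x Numeric signal.
#' @param scale Dimensionless scale in samples (>= 1).
#' @return Coefficient series, same length as `x`, linear in `x`.
#' @export
cwt_gaus1 <- function(x, scale) {
  if (scale < 1) stop("scale must be >= 1")
  k <- gaus1_kernel(scale)
  half <- (length(k) - 1L) / 2L
  n <- length(x)
  if (n < 2) stop("signal too short")
  # symmetric (reflect) extension by the kernel half width
  idx <- c(pmin(n, pmax(1, seq(half + 1, 2))), seq_len(n),
           pmin(n, pmax(1, seq(n - 1, n - half))))
  xx <- x[idx]
  y <- stats::filter(xx, rev(k), method = "convolution", sides = 2)
  as.numeric(y[seq(half + 1L, half + n)])
}

#' Edge margin for CWT-based peak detection
#'
#' Number of samples at each end of a coefficient series within which peaks
#' are unreliable because of edge extension, taken as `2 * scale`.
#'
#' @param scale CWT scale in samples.
#' @return Margin in samples.
#' @export
cwt_edge_margin <- function(scale) ceiling(2 * scale)

#' Normalized central frequency of the Gaussian first-derivative wavelet
#'
#' The dimensionless per-sample central frequency used to convert between a
#' target frequency in Hz and a CWT scale: `scale = f_norm * fs / f_target`.
#' The value 0.2 fixes the conventional mapping in which a 1.25 Hz target at
#' a 50 Hz sampling rate corresponds to scale 8.
#' @export
GAUS1_CENTRAL_FREQ <- 0.2

#' Convert a target frequency to a CWT scale
#'
#' `scale = 0.2 * fs / f_target`, rounded to the nearest 0.1 (continuous
#' scales are allowed).
#'
#' @param f_target Target central frequency in Hz, in (0, fs/2).
#' @param fs Sampling rate in Hz.
#' @return Dimensionless scale.
#' @export
frequency_to_scale <- function(f_target, fs) {
  if (any(f_target <= 0) || any(f_target >= fs / 2)) {
    stop("f_target must lie strictly inside (0, fs/2)")
  }
  round(GAUS1_CENTRAL_FREQ * fs / f_target, 1)
}

#' Convert a CWT scale back to its central frequency
#'
#' @param scale Dimensionless scale (> 0).
#' @param fs Sampling rate in Hz.
#' @return Central frequency in Hz.
#' @export
scale_to_frequency <- function(scale, fs) {
  stopifnot(all(scale > 0))
  GAUS1_CENTRAL_FREQ * fs / scale
}

# --- peak finding -----------------------------------------------------------

# Local maxima of x with optional height, prominence and minimum-distance
# constraints, mirroring the standard prominence definition: for each peak,
# descend on both sides to the lowest point before a higher peak (or the
# signal edge); prominence = peak height - max(left base, right base).
# Distance filtering keeps the highest peaks greedily. With refine = TRUE a
# parabolic interpolation through the peak sample and its neighbours returns
# sub-sample locations.
find_peaks <- function(x, height = -Inf, prominence = 0,
                       distance = 1, refine = FALSE) {
  n <- length(x)
  if (n < 3) {
    return(data.frame(index = numeric(0), value = numeric(0),
                      prominence = numeric(0)))
  }
  dx <- diff(x)
  # local maxima; for flat tops take the left edge of the plateau
  cand <- which(dx[-1] < 0 & dx[-(n - 1)] > 0) + 1L
  # plateaus
  flat <- which(dx == 0)
  if (length(flat)) {
    for (i in flat) {
      j <- i
      while (j < n - 1 && x[j + 1] == x[i]) j <- j + 1L
      if (i > 1 && x[i - 1] < x[i] && j < n && x[j + 1] < x[i]) {
        cand <- c(cand, i)
      }
    }
    cand <- sort(unique(cand))
  }
  if (!length(cand)) {
    return(data.frame(index = numeric(0), value = numeric(0),
                      prominence = numeric(0)))
  }
  prom <- vapply(cand, function(i) {
    # left base
    lo <- x[i]
    j <- i
    while (j > 1 && x[j - 1] <= x[i]) {
      j <- j - 1L
      if (x[j] < lo) lo <- x[j]
    }
    left <- lo
    lo <- x[i]
    j <- i
    while (j < n && x[j + 1] <= x[i]) {
      j <- j + 1L
      if (x[j] < lo) lo <- x[j]
    }
    x[i] - max(left, lo)
  }, numeric(1))
  keep <- x[cand] >= height & prom >= prominence
  cand <- cand[keep]
  prom <- prom[keep]
  if (length(cand) && distance > 1) {
    ord <- order(x[cand], decreasing = TRUE)
    alive <- rep(TRUE, length(cand))
    for (k in ord) {
      if (!alive[k]) next
      too_close <- abs(cand - cand[k]) < distance & seq_along(cand) != k
      alive[too_close & x[cand] <= x[cand[k]]] <- FALSE
    }
    prom <- prom[alive]
    cand <- cand[alive]
  }
  idx <- as.numeric(cand)
  if (refine && length(cand)) {
    ok <- cand > 1 & cand < n
    i <- cand[ok]
    denom <- x[i - 1] - 2 * x[i] + x[i + 1]
    shift <- ifelse(denom < 0, 0.5 * (x[i - 1] - x[i + 1]) / denom, 0)
    idx[ok] <- i + pmax(-0.5, pmin(0.5, shift))
  }
  data.frame(index = idx, value = x[cand], prominence = prom)
}
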