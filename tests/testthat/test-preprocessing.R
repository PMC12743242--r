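test_that("butterworth bandpass rejects DC and preserves the passband", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  dc <- rep(2.5, length(t))
  y <- butterworth_filter(dc, fs, "bandpass", c(0.25, 7.5), 4)
  core <- y[(2 * fs):(8 * fs)]
  expect_lt(max(abs(core)), 1e-6 * 2.5)

  x <- sin(2 * pi * 2 * t)
  y2 <- butterworth_filter(x, fs, "lowpass", 20, 4)
  core2 <- y2[(2 * fs):(8 * fs)]
  expect_lt(abs(max(core2) - 1), 0.01)

  # zero phase: cross-correlation peak of filtered vs raw 2 Hz tone at lag 0
  yb <- butterworth_filter(x, fs, "bandpass", c(0.25, 7.5), 4)
  cc <- stats::ccf(yb[(2 * fs):(8 * fs)], x[(2 * fs):(8 * fs)],
                   lag.max = 25, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("filtering commutes with time reversal (zero-phase property)", {
  set.seed(11)
  fs <- 64
  n <- 60 * fs
  x <- stats::filter(rnorm(n), rep(1 / 5, 5), sides = 2)
  x[is.na(x)] <- 0
  x <- as.numeric(x)
  al <- butterworth_filter(x, fs, "lowpass", 20, 4)
  bl <- rev(butterworth_filter(rev(x), fs, "lowpass", 20, 4))
  i <- seq(25 * fs, 35 * fs)
  expect_lt(max(abs(al[i] - bl[i])), 1e-9)
  # the walking-band bandpass has poles within ~f_low/fs of the unit
  # circle, which amplifies double-precision rounding; its commutation
  # floor sits near 1e-8 rather than 1e-9
  a <- butterworth_filter(x, fs, "bandpass", c(0.25, 7.5), 4)
  b <- rev(butterworth_filter(rev(x), fs, "bandpass", c(0.25, 7.5), 4))
  expect_lt(max(abs(a[i] - b[i])), 1e-7)
})

test_that("butterworth rejects invalid cutoffs and too-short input", {
  expect_error(butterworth_filter(rnorm(100), 50, "lowpass", 30, 4),
               "inside")
  expect_error(butterworth_filter(rnorm(10), 50, "bandpass", c(0.25, 7.5), 4),
               "short")
})

test_that("cumulative trapezoid integration matches closed forms", {
  # 11 samples at 10 Hz span 10 intervals of 0.1 s: integral of 1 is 1.0
  expect_equal(integrate_trapz(rep(1, 11), 10)[11], 1.0)
  expect_equal(integrate_trapz(rep(1, 11), 10)[1], 0)
  expect_identical(integrate_trapz(rep(0, 50), 10), rep(0, 50))
  fs <- 100
  t <- seq(0, 3, by = 1 / fs)
  y <- integrate_trapz(sin(2 * pi * t), fs)
  expect_lt(abs(y[length(y)]), 1e-3)
})

test_that("gaus1 CWT is linear and shift-covariant", {
  set.seed(4)
  x <- rnorm(400)
  expect_identical(cwt_gaus1(rep(0, 200), 6), rep(0, 200))
  expect_equal(cwt_gaus1(2 * x, 6), 2 * cwt_gaus1(x, 6))
  # translation covariance in the interior (outside one kernel support of
  # either edge in both the original and shifted frames)
  k <- 25
  xs <- c(rep(0, k), x)[1:400]
  a <- cwt_gaus1(x, 6)
  b <- cwt_gaus1(xs, 6)
  margin <- ceiling(5 * 6) + k + 1
  i <- seq(margin + 1, 400 - margin)
  expect_lt(max(abs(b[i] - a[i - k])), 1e-9)
  expect_error(cwt_gaus1(x, 0.5), "scale")
})

test_that("gaus1 CWT responds most to its matched frequency", {
  fs <- 100
  t <- seq(0, 20, by = 1 / fs)
  scale <- frequency_to_scale(1.25, fs)
  matched <- cwt_gaus1(sin(2 * pi * 1.25 * t), scale)
  off <- cwt_gaus1(sin(2 * pi * 8 * t), scale)
  expect_gt(sqrt(mean(matched^2)), 3 * sqrt(mean(off^2)))
})

test_that("frequency/scale conversion follows the 1.25 Hz / scale 8 convention", {
  expect_identical(frequency_to_scale(1.25, 50), 8)
  expect_identical(frequency_to_scale(2.0, 100), 10)
  expect_equal(frequency_to_scale(1.25, 100), 2 * frequency_to_scale(1.25, 50))
  # round trip within the 0.1 rounding of the scale
  for (f in c(0.7, 1.25, 3.3)) {
    s <- frequency_to_scale(f, 128)
    expect_equal(scale_to_frequency(s, 128), f, tolerance = 0.02)
  }
  expect_error(frequency_to_scale(30, 50), "inside")
  expect_error(frequency_to_scale(0, 50), "inside")
})

test_that("tilt correction recovers a leveled frame and preserves energy", {
  t <- (0:2047) / 128                     # integer periods: exact zero means
  a0 <- cbind(sin(2 * pi * t), 0.1 * cos(2 * pi * t),
              -9.80665 + 0.2 * sin(4 * pi * t))
  # already level: correction is the identity
  out0 <- tilt_correct(a0, vertical = 3, ap = 1)
  expect_equal(out0, a0, tolerance = 1e-12)

  th <- 5 * pi / 180
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
              3, 3, byrow = TRUE)
  tilted <- a0 %*% t(R)
  out <- tilt_correct(tilted, vertical = 3, ap = 1)
  expect_lt(abs(mean(out[, 3]) + 9.80665) / 9.80665, 0.005)
  expect_lt(abs(mean(out[, 1])), 0.05 * 9.81)
  expect_equal(sum(out^2), sum(tilted^2), tolerance = 1e-9)

  expect_error(tilt_correct(matrix(rnorm(300), 100, 3), 3, 1),
               "gravity")
})
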