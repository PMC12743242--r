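test_that("event matching handles identity, shift, and window boundary", {
  ref <- c(1, 1.5, 2, 2.5, 3)
  m0 <- match_events(ref, ref)
  expect_equal(m0$tp, 5)
  expect_equal(m0$fp, 0)
  expect_equal(m0$fn, 0)
  expect_equal(m0$f1, 1)
  expect_equal(m0$mae, 0)

  m1 <- match_events(ref + 0.10, ref)
  expect_equal(m1$tp, 5)
  expect_equal(m1$mae, 0.10, tolerance = 1e-12)
  expect_true(all(m1$errors > 0))          # detected - reference convention

  m2 <- match_events(ref + 0.20, ref)
  expect_equal(m2$tp, 0)
  expect_true(is.na(m2$mae))
})

test_that("undefined metrics are NA, not zero", {
  m <- match_events(numeric(0), numeric(0))
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$f1))
})

test_that("region masks exclude off-walkway events from FP and FN", {
  ref <- c(1, 2, 3)
  det <- c(1.01, 2.01, 3.01, 8)            # one detection far off the region
  m <- match_events(det, ref, region = c(0.5, 3.5))
  expect_equal(m$tp, 3)
  expect_equal(m$fp, 0)
  m2 <- match_events(det, ref)
  expect_equal(m2$fp, 1)
})

test_that("matching counts are consistent and window-monotone", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    ref <- cumsum(stats::runif(n, 0.35, 0.8))
    det <- sort(c(ref + stats::rnorm(n, 0, 0.06),
                  if (i %% 3 == 0) max(ref) + 0.5))
    m_wide <- match_events(det, ref, window = 0.3)
    m_narrow <- match_events(det, ref, window = 0.1)
    expect_lte(m_narrow$tp, m_wide$tp)
    expect_lte(m_wide$tp, min(length(det), length(ref)))
    expect_equal(m_wide$tp + m_wide$fn, length(ref))
  }
})

test_that("greedy matching achieves the brute-force optimal match count", {
  set.seed(17)
  for (i in 1:40) {
    n_ref <- sample(2:8, 1)
    ref <- cumsum(stats::runif(n_ref, 0.35, 0.9))
    keep <- stats::runif(n_ref) < 0.8
    det <- ref[keep] + stats::rnorm(sum(keep), 0, 0.05)
    if (i %% 2 == 0) det <- c(det, stats::runif(1, 0, max(ref) + 0.3))
    det <- sort(det)
    m <- match_events(det, ref, window = 0.3)
    expect_equal(m$tp, bf_match_count(det, ref, 0.3))
  }
})

test_that("ICC(2,1) matches a brute-force ANOVA oracle", {
  set.seed(23)
  for (i in 1:8) {
    n <- sample(5:20, 1)
    k <- sample(2:4, 1)
    x <- matrix(stats::rnorm(n * k, sd = 1), n, k) +
      stats::rnorm(n, sd = 2)              # subject effects
    r <- icc_2_1(x)
    expect_equal(r$icc, aov_icc21(x), tolerance = 1e-6)
    expect_lte(r$lower, r$icc)
    expect_gte(r$upper, r$icc)
  }
})

test_that("ICC(2,1) equals 1 under exact agreement and penalizes rater shift", {
  x <- cbind(c(3, 5, 9, 2, 7), c(3, 5, 9, 2, 7))
  expect_equal(icc_2_1(x)$icc, 1)
  y <- cbind(c(3, 5, 9, 2, 7), c(3, 5, 9, 2, 7) + 2)
  r <- icc_2_1(y)
  # consistency-type ICC ignores the shift entirely; absolute agreement must
  # fall strictly below it
  expect_lt(r$icc, 1)
  expect_equal(r$icc, aov_icc21(y), tolerance = 1e-6)
  # subject relabeling leaves the estimate unchanged
  expect_equal(icc_2_1(y[c(4, 1, 5, 2, 3), ])$icc, r$icc)
})

test_that("the classic 6x4 reliability matrix reproduces the oracle value", {
  x <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 8,
                7, 1, 2, 6,
                10, 5, 6, 9,
                6, 2, 4, 7), 6, 4, byrow = TRUE)
  r <- icc_2_1(x)
  expect_equal(r$icc, aov_icc21(x), tolerance = 1e-6)
  expect_equal(r$icc, 0.29, tolerance = 0.005)
})

test_that("degenerate between-subject variance warns", {
  x <- cbind(rep(1, 4), c(1.1, 0.9, 1.05, 0.95))
  expect_warning(icc_2_1(x), "degenerate")
})
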