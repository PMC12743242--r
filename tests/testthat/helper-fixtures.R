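# Shared simulated fixtures, cached for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

# one simulated bout, memoised on its parameters
sim_fixture <- function(f_step = 1.7, duration = 20, noise_snr_db = NULL,
                        tilt = 0, seed = 7L, duty = 0.25) {
  key <- paste(f_step, duration, noise_snr_db %||% "clean", tilt, seed, duty,
               sep = "|")
  if (is.null(.fixture_cache[[key]])) {
    spec <- walker_spec(f_step = f_step, duration = duration, duty = duty,
                        tilt_deg = c(tilt, tilt / 2), seed = seed)
    if (!is.null(noise_snr_db)) {
      spec$noise_sd <- noise_sd_for_snr(spec, noise_snr_db)
    }
    .fixture_cache[[key]] <- simulate_bout(spec)
  }
  .fixture_cache[[key]]
}

# the standard 12-fixture grid (expensive; built once per run)
suite_fixture <- function() {
  if (is.null(.fixture_cache$suite)) {
    .fixture_cache$suite <- make_test_suite()
  }
  .fixture_cache$suite
}

# analysis region excluding detector edge effects
truth_region <- function(truth, margin = 1) {
  c(margin, max(truth$t) - margin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force maximum-cardinality event matching (for oracle comparison):
# recursively assign each reference event to any unmatched detected event
# within the half-window, or leave it unmatched, and maximize matches
bf_match_count <- function(detected, reference, window = 0.3) {
  half <- window / 2
  best <- 0L
  recurse <- function(r, used) {
    if (r > length(reference)) return(0L)
    cand <- which(!used & abs(detected - reference[r]) <= half)
    top <- recurse(r + 1L, used)        # leave reference[r] unmatched
    for (j in cand) {
      used[j] <- TRUE
      top <- max(top, 1L + recurse(r + 1L, used))
      used[j] <- FALSE
    }
    top
  }
  recurse(1L, rep(FALSE, length(detected)))
}

# ICC(2,1) oracle: mean squares from a full two-way ANOVA fit via aov()
aov_icc21 <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  d <- data.frame(y = as.vector(x),
                  subject = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ subject + rater, data = d))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
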