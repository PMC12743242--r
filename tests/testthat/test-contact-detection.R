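detect_on <- function(sim, cfg = gait_config()) {
  prof <- bout_profile(sim$recording, cfg)
  list(prof = prof, events = detect_contacts(prof, cfg))
}

test_that("a constant signal yields no contact events", {
  out <- detect_fc(rep(0, 1000), 100, 0.5)
  expect_length(out$fc, 0)
  ev <- detect_contacts_legacy(rep(-9.81, 1000), 100)
  expect_length(ev$ic, 0)
  expect_length(ev$fc, 0)
})

test_that("noiseless walkers are recovered with F1 >= 0.98 and MAE <= 0.03 s", {
  for (f in c(1.2, 1.7, 2.2)) {
    sim <- sim_fixture(f_step = f, duration = 20)
    out <- detect_on(sim)
    reg <- truth_region(sim$truth)
    mf <- match_events(out$events$fc, sim$truth$fc, 0.3, reg)
    mi <- match_events(out$events$ic, sim$truth$ic, 0.3, reg)
    expect_gte(mf$f1, 0.98)
    expect_gte(mi$f1, 0.98)
    expect_lte(mf$mae, 0.03)
    expect_lte(mi$mae, 0.03)
    expect_lt(stats::median(abs(mf$errors)), 0.03)
    expect_lt(stats::median(abs(mi$errors)), 0.03)
  }
})

test_that("every IC precedes its paired FC", {
  sim <- sim_fixture(f_step = 1.7, duration = 20)
  prof <- bout_profile(sim$recording)
  ap <- butterworth_filter(prof$recording$a[, prof$ap],
                           sim$recording$fs, "lowpass", 20, 4)
  fcr <- detect_fc(ap, sim$recording$fs, prof$step_time)
  icr <- detect_ic(ap, sim$recording$fs, prof$step_time, fcr$fc)
  expect_true(all(icr$ic < icr$fc_paired))
})

test_that("detection is deterministic and amplitude-invariant", {
  sim <- sim_fixture(f_step = 1.7, duration = 20, noise_snr_db = 10)
  a <- detect_on(sim)$events
  b <- detect_on(sim)$events
  expect_identical(a$ic, b$ic)
  expect_identical(a$fc, b$fc)

  scaled <- sim
  scaled$recording$a <- scaled$recording$a * 4.2  # gravity scales too; use raw AP path
  prof <- bout_profile(sim$recording)
  ap <- butterworth_filter(prof$recording$a[, prof$ap],
                           sim$recording$fs, "lowpass", 20, 4)
  fs <- sim$recording$fs
  f1 <- detect_fc(ap, fs, prof$step_time)
  f2 <- detect_fc(3.7 * ap, fs, prof$step_time)
  expect_equal(f1$fc, f2$fc, tolerance = 1e-9)
  i1 <- detect_ic(ap, fs, prof$step_time, f1$fc)
  i2 <- detect_ic(3.7 * ap, fs, prof$step_time, f2$fc)
  expect_equal(i1$ic, i2$ic, tolerance = 1e-9)
})

test_that("prepending silence shifts events by exactly the pad duration", {
  sim <- sim_fixture(f_step = 1.7, duration = 20)
  prof <- bout_profile(sim$recording)
  fs <- sim$recording$fs
  ap <- butterworth_filter(prof$recording$a[, prof$ap], fs, "lowpass", 20, 4)
  k <- 2                                   # seconds
  padded <- c(rep(0, k * fs), ap)
  f1 <- detect_fc(ap, fs, prof$step_time)
  f2 <- detect_fc(padded, fs, prof$step_time)
  interior <- f1$fc[f1$fc > 1 & f1$fc < max(f1$fc) - 1]
  for (ev in interior) {
    expect_lt(min(abs(f2$fc - (ev + k))), 1e-6)
  }
})

test_that("legacy detector lags the true IC and loses to the adaptive one", {
  for (f in c(1.2, 2.2)) {
    sim <- sim_fixture(f_step = f, duration = 20)
    reg <- truth_region(sim$truth)
    out <- detect_on(sim)
    vert <- out$prof$recording$a[, out$prof$vertical]
    legacy <- detect_contacts_legacy(vert, sim$recording$fs)
    mi_l <- match_events(legacy$ic, sim$truth$ic, 0.3, reg)
    mi_a <- match_events(out$events$ic, sim$truth$ic, 0.3, reg)
    expect_gt(mi_l$tp, 0)
    expect_gt(mean(mi_l$errors), 0)        # positive lag toward the loading peak
    expect_gt(mi_l$mae, mi_a$mae)          # strictly worse than adaptive
  }
})

test_that("legacy detector on a matched-band tone spaces events by its period", {
  fs <- 50
  t <- seq(0, 20, by = 1 / fs)
  vert <- -9.81 + sin(2 * pi * 1.25 * t)
  ev <- detect_contacts_legacy(vert, fs)
  expect_gt(length(ev$ic), 5)
  expect_equal(stats::median(diff(ev$ic)), 0.8, tolerance = 0.02)
})

test_that("scale-relation calibration recovers trivial structures", {
  skip_if(Sys.getenv("LUMBARGAIT_FAST") == "1")
  bouts <- lapply(c(1.3, 1.7, 2.1), function(f) {
    sim <- sim_fixture(f_step = f, duration = 20, seed = 30 + round(10 * f))
    list(recording = sim$recording, ic = sim$truth$ic, fc = sim$truth$fc)
  })
  cal <- calibrate_scale_relation(bouts, grid = seq(1.5, 4, by = 0.5))
  d <- cal$diagnostics
  # the sweep must land inside the plateau of scales that detect the
  # simulator's events essentially perfectly: near-zero cost, wavelet
  # frequency a low multiple of the step frequency for both stages
  expect_true(all(d$cost_fc < 0.05))
  expect_true(all(d$cost_ic < 0.05))
  expect_true(all(d$f_fc / d$f_step >= 2 & d$f_fc / d$f_step <= 4))
  expect_true(all(d$f_ic / d$f_step >= 2 & d$f_ic / d$f_step <= 4))

  same <- lapply(1:3, function(i) {
    sim <- sim_fixture(f_step = 1.7, duration = 20)
    list(recording = sim$recording, ic = sim$truth$ic, fc = sim$truth$fc)
  })
  expect_error(calibrate_scale_relation(same, grid = seq(2, 4, by = 1)),
               "degenerate")
})
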