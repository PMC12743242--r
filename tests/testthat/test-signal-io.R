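test_that("read_recording converts g to m/s^2 and rebases time", {
  path <- withr::local_tempfile(fileext = ".csv")
  t <- seq(2, 6, by = 1 / 64)
  df <- data.frame(time = t, ax = 0, ay = 0, az = -1)
  write.csv(df, path, row.names = FALSE)
  rec <- read_recording(path, gait_config(units = "g"))
  expect_equal(rec$fs, 64)
  expect_equal(rec$t[1], 0)
  expect_equal(unique(rec$a[, 3]), -9.80665)
  expect_equal(unique(rec$a[, 1]), 0)
})

test_that("read_recording leaves a clean uniform grid untouched", {
  path <- withr::local_tempfile(fileext = ".csv")
  t <- (0:511) / 128
  write.csv(data.frame(time = t, ax = sin(t), ay = cos(t), az = -9.81),
            path, row.names = FALSE)
  rec <- read_recording(path, gait_config())
  expect_equal(rec$fs, 128)
  expect_equal(nrow(rec$a), 512)
  expect_equal(rec$a[, 1], sin(t), tolerance = 1e-9)
})

test_that("a duplicated timestamp triggers resampling onto a uniform grid", {
  path <- withr::local_tempfile(fileext = ".csv")
  t <- (0:400) / 100
  x <- sin(2 * pi * t)
  t2 <- t
  t2[201] <- t2[200]                      # duplicate
  write.csv(data.frame(time = t2, ax = x, ay = 0, az = -9.81), path,
            row.names = FALSE)
  rec <- read_recording(path, gait_config())
  expect_true(all(diff(rec$t) > 0))
  expect_equal(stats::median(diff(rec$t)), 1 / 100, tolerance = 1e-9)
  # oracle: direct linear interpolation of the deduplicated series
  keep <- !duplicated(t2)
  oracle <- stats::approx(t2[keep], x[keep], xout = rec$t, rule = 2)$y
  expect_equal(rec$a[, 1], oracle, tolerance = 1e-9)
})

test_that("read_recording rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time = 1:10, ax = 1:10), path, row.names = FALSE)
  expect_error(read_recording(path, gait_config()), "missing column")
  write.csv(data.frame(time = c(1:5, 4, 6:10) / 10, ax = 0, ay = 0, az = -9.8),
            path, row.names = FALSE)
  expect_error(read_recording(path, gait_config()), "monotone")
  write.csv(data.frame(time = (0:20) / 100, ax = 0, ay = 0, az = -9.8),
            path, row.names = FALSE)
  expect_error(read_recording(path, gait_config()), "2 s")
})

test_that("stride tables round-trip losslessly", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_stride_table(data.frame(), path)
  empty <- read_stride_table(path)
  expect_equal(nrow(empty), 0)
  expect_true("step_length" %in% names(empty))

  sim <- sim_fixture(f_step = 1.7, duration = 20)
  fit <- estimate_gait(sim$recording, height = 1.7)
  write_stride_table(fit$strides, path)
  back <- read_stride_table(path)
  expect_equal(nrow(back), nrow(fit$strides))
  expect_true(all(diff(back$ic) > 0))
  for (cl in c("ic", "t_bip", "t_step", "step_length")) {
    expect_equal(back[[cl]], fit$strides[[cl]], tolerance = 1e-9)
  }
})

test_that("event lists and configurations round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  ev <- contact_events(ic = c(0.5, 1.1), fc = c(0.65, 1.25, 1.8))
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(back$ic, ev$ic, tolerance = 1e-12)
  expect_equal(back$fc, ev$fc, tolerance = 1e-12)

  cfgp <- withr::local_tempfile(fileext = ".yaml")
  cfg <- gait_config(height = 1.66, detector = "legacy",
                     scale_relation = list(ic = c(a = 2.5, b = 0.1),
                                           fc = c(a = 3, b = 0)))
  write_config(cfg, cfgp)
  cfg2 <- read_config(cfgp)
  expect_equal(cfg2$height, 1.66)
  expect_equal(cfg2$detector, "legacy")
  expect_equal(unname(cfg2$scale_relation$ic), c(2.5, 0.1))
  writeLines("nonsense: 1", cfgp)
  expect_error(read_config(cfgp), "unknown configuration")
})

test_that("run metadata sidecar captures the effective configuration", {
  sim <- sim_fixture(f_step = 1.7, duration = 20)
  fit <- estimate_gait(sim$recording, height = 1.7)
  path <- withr::local_tempfile(fileext = ".json")
  write_run_metadata(fit, path)
  meta <- jsonlite::read_json(path)
  expect_equal(meta$package, "lumbargait")
  expect_equal(meta$config$height, 1.7)
  expect_equal(meta$profile$vertical, 3)
})
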