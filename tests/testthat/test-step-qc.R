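test_that("dynamic thresholds follow the printed linear relations", {
  thr <- dynamic_thresholds(0.5)
  expect_equal(thr$t_max_stride, 2.0)
  expect_equal(thr$c_loading, 0.135)
  # at a 0.625 s step time the dynamic maximum stride time meets the
  # legacy static 2.25 s value
  expect_equal(dynamic_thresholds(0.625)$t_max_stride, 2.25)
  expect_error(dynamic_thresholds(0.1), "range")
  expect_error(dynamic_thresholds(2.5), "range")
})

test_that("legacy static thresholds give the 0.45 s loading limit", {
  thr <- legacy_thresholds()
  expect_equal(thr$max_loading, 0.45)
  expect_equal(thr$max_stance, 2.25 / 2 + 0.45)
})

test_that("a single IC with two FCs makes one step and no stride", {
  ev <- contact_events(ic = 1.0, fc = c(1.15, 1.6))
  df <- assemble_strides(ev, dynamic_thresholds(0.5))
  expect_equal(nrow(df), 1)
  expect_equal(df$t_bip, 0.15)
  expect_equal(df$stance, 0.6)
  expect_true(is.na(df$stride_time))
  expect_true(is.na(df$t_step))
})

test_that("clean simulated events assemble into QC-passing strides", {
  sim <- sim_fixture(f_step = 1.7, duration = 20)
  tr <- sim$truth
  ev <- contact_events(ic = tr$ic, fc = tr$fc)
  thr <- dynamic_thresholds(tr$step_time)
  df <- assemble_strides(ev, thr)
  expect_gte(nrow(df), length(tr$ic) - 2)
  full <- !is.na(df$t_step)
  expect_equal(unique(round(df$t_step[full], 9)),
               round(tr$step_time, 9))
  expect_true(all(df$t_bip < thr$max_loading))
  expect_true(all(df$stance < thr$max_stance))
  expect_true(all(df$stride_time[!is.na(df$stride_time)] < thr$t_max_stride))
  expect_true(all(abs(df$t_step[full] - (df$t_bip + df$t_sup)[full]) < 1e-12))
})

test_that("a spurious FC breaks continuity only locally", {
  sim <- sim_fixture(f_step = 1.7, duration = 20)
  tr <- sim$truth
  thr <- dynamic_thresholds(tr$step_time)
  base <- assemble_strides(contact_events(tr$ic, tr$fc), thr)
  mid <- tr$ic[10] + 0.4 * tr$t_bip
  fc2 <- sort(c(tr$fc, mid))
  pert <- assemble_strides(contact_events(tr$ic, fc2), thr)
  # steps far from the injected event are unchanged
  far_base <- base[base$ic < tr$ic[8] | base$ic > tr$ic[13], ]
  far_pert <- pert[pert$ic < tr$ic[8] | pert$ic > tr$ic[13], ]
  expect_equal(far_base$t_bip, far_pert$t_bip)
  # the affected neighbourhood loses at least one full stride
  expect_lt(sum(!is.na(pert$stride_time)), sum(!is.na(base$stride_time)))
})

test_that("relaxing thresholds never removes strides", {
  sim <- sim_fixture(f_step = 1.2, duration = 20)
  tr <- sim$truth
  ev <- contact_events(tr$ic, tr$fc)
  tight <- assemble_strides(ev, qc <- dynamic_thresholds(tr$step_time))
  loose <- assemble_strides(
    ev, legacy_thresholds(qc$t_max_stride * 2, qc$c_loading * 2))
  expect_gte(nrow(loose), nrow(tight))
})

test_that("later of two ICs sharing a first FC wins", {
  ev <- contact_events(ic = c(1.0, 1.05), fc = c(1.2, 1.7, 2.2))
  df <- assemble_strides(ev, legacy_thresholds())
  expect_equal(df$ic, 1.05)
})

test_that("dynamic thresholds keep a consistent headroom across speeds", {
  # headroom = loading-time limit relative to the observed median loading
  # time; the dynamic rule tracks walking speed while the static limit
  # drifts far from it at fast cadences
  ratio_dyn <- c()
  ratio_stat <- c()
  for (f in c(1.2, 1.7, 2.2)) {
    sim <- sim_fixture(f_step = f, duration = 20)
    fit <- estimate_gait(sim$recording, height = 1.7)
    t_bip_obs <- fit$metrics$summary$t_bip
    ratio_dyn <- c(ratio_dyn,
                   dynamic_thresholds(fit$profile$step_time)$max_loading /
                     t_bip_obs)
    ratio_stat <- c(ratio_stat, legacy_thresholds()$max_loading / t_bip_obs)
  }
  var_dyn <- max(ratio_dyn) / min(ratio_dyn) - 1
  var_stat <- max(ratio_stat) / min(ratio_stat) - 1
  expect_lt(var_dyn, 0.5)
  expect_gt(var_stat, 2 * var_dyn)
})
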