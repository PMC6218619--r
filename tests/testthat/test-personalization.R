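test_that("measurement bundles validate their fields and waveforms", {
  fx <- noisefree_subject()
  m <- fx$m
  expect_s3_class(m, "subject_measurements")
  wfs_no_aa <- m$waveforms[c("MV", "AV")]
  expect_error(subject_measurements(m$T, m$SBP, m$DBP, m$LVESV, m$A_ao,
                                    m$VTI, wfs_no_aa), "AA")
  expect_error(subject_measurements(m$T, m$SBP, m$DBP, NA, m$A_ao, m$VTI,
                                    m$waveforms), "LVESV")
  expect_error(subject_measurements(m$T, 80, 90, m$LVESV, m$A_ao, m$VTI,
                                    m$waveforms), "SBP")
})

test_that("direct assignment leaves the provenance audit intact", {
  fx <- noisefree_subject()
  ps <- assign_direct_parameters(fx$m)
  prov <- table(ps$provenance)
  expect_equal(unname(prov[["optimized"]]), 20L)
  expect_equal(unname(prov[["direct"]]), 3L)
  expect_equal(unname(prov[["literature"]]), 17L)
  # 23 subject-specific parameters in total
  expect_equal(sum(ps$provenance != "literature"), 23L)
  # T from HR 66
  m66 <- fx$m
  m66$T <- 60 / 66
  for (s in c("MV", "AV", "AA")) m66$waveforms[[s]]$T <- 60 / 66
  ps66 <- assign_direct_parameters(m66)
  expect_equal(ps66$values[["T"]], 0.909, tolerance = 1e-3)
})

test_that("single-beat elastance initialization has its closed form", {
  expect_equal(single_beat_emax_init(70.3, 115.5, V_o = 10),
               0.9 * 115.5 / 60.3, tolerance = 1e-12)
  expect_equal(single_beat_emax_init(70.3, 115.5, V_o = 10), 1.72,
               tolerance = 0.01)
  expect_equal(single_beat_emax_init(60, 100 / 0.9 * 1, V_o = 10,
                                     pes_frac = 0.9), 2.0)
  expect_error(single_beat_emax_init(8, 115, V_o = 10), "exceed")
  # the estimate blows up as ESV approaches the intercept but the
  # initializer clamps it to the optimization bounds
  expect_gt(single_beat_emax_init(10.5, 115), 100)
  fx <- noisefree_subject()
  m <- fx$m
  m$LVESV <- 10.2
  ps <- initialize_parameters(m, assign_direct_parameters(m))
  expect_lte(ps$values[["lv.E_max"]],
             param_table()$upper[param_table()$name == "lv.E_max"])
})

test_that("the objective is near zero at generator truth and rises locally", {
  fx <- noisefree_subject()
  obj <- build_objective(fx$m, base_ps = fx$truth)
  tv <- fx$truth$values[optimized_parameter_names()]
  c0 <- obj(tv)
  expect_lt(c0, 1) # (mL/s)^2, self-consistency at truth
  up <- tv
  up[["lv.E_max"]] <- up[["lv.E_max"]] * 1.2
  expect_gt(obj(up), c0 + 10)
  dn <- tv
  dn[["lv.alpha_D"]] <- dn[["lv.alpha_D"]] * 0.8
  expect_gt(obj(dn), c0 + 10)
})

test_that("objective cost decomposes into per-site RMSE terms", {
  fx <- noisefree_subject()
  # anchors disabled: the cost must equal the sum of squared site RMSEs
  obj <- build_objective(fx$m, base_ps = fx$truth, anchor_weight = 0)
  ps <- set_parameters(fx$truth,
                       c("lv.E_max" = fx$truth$values[["lv.E_max"]] * 1.1))
  sim <- run_to_periodic_steady_state(ps, control = simulation_control())
  mod <- sample_waveforms(sim, fx$m$waveforms$MV$n_frames)
  rmse2 <- sum(vapply(c("MV", "AV", "AA"), function(s)
    waveform_rmse(fx$m$waveforms[[s]], mod[[s]])^2, numeric(1)))
  tv <- ps$values[optimized_parameter_names()]
  expect_equal(obj(tv), rmse2, tolerance = 0.02 * rmse2)
})

test_that("optimization is deterministic given the seed", {
  fx <- noisefree_subject()
  f1 <- personalize_subject(fx$m, seed = 4, n_starts = 2, maxiter = 3,
                            n_rounds = 1)
  f2 <- personalize_subject(fx$m, seed = 4, n_starts = 2, maxiter = 3,
                            n_rounds = 1)
  expect_identical(f1$params$values, f2$params$values)
  expect_identical(f1$rmse, f2$rmse)
  expect_identical(f1$rss_trace, f2$rss_trace)
})
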