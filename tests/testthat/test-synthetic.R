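test_that("degenerate SDs reproduce the regime means exactly", {
  rt <- cardioelast:::.default_regime_table()
  rt$rest_sd <- 0
  rt$stress_sd <- 0
  spec <- cohort_spec(n_subjects = 2, seed = 1, regimes = rt)
  set.seed(1)
  d <- sample_truth_params(spec, "rest")
  expect_equal(60 / d$ps$values[["T"]], 66, tolerance = 1e-9)
  expect_equal(d$ps$values[["lv.R_C"]], 1.5)
  expect_equal(d$ps$values[["lv.alpha_D"]], 0.4)
  s <- sample_truth_params(spec, "stress", z_subject = d$z_subject,
                           subject_values = d$subject_values)
  expect_equal(60 / s$ps$values[["T"]], 105, tolerance = 1e-9)
  expect_equal(s$ps$values[["lv.R_R"]], 46.1)
})

test_that("sampled parameters are calibrated to the regime centers", {
  spec <- cohort_spec(n_subjects = 2, seed = 2)
  set.seed(2)
  n <- 200
  rc <- rr <- ad <- hr <- numeric(n)
  for (k in seq_len(n)) {
    d <- sample_truth_params(spec, "rest")
    rc[k] <- d$ps$values[["lv.R_C"]]
    rr[k] <- d$ps$values[["lv.R_R"]]
    ad[k] <- d$ps$values[["lv.alpha_D"]]
    hr[k] <- 60 / d$ps$values[["T"]]
  }
  # cohort means within 3 standard errors of the specified centers
  expect_lt(abs(mean(rc) - 1.5), 3 * 0.3 / sqrt(n))
  expect_lt(abs(mean(ad) - 0.4), 3 * 0.05 / sqrt(n))
  expect_lt(abs(mean(hr) - 66), 3.5 * 9 / sqrt(n))
  expect_lt(abs(mean(rr) - 37.2), 3 * 6.9 / sqrt(n))
  expect_gt(stats::sd(rc), 0.15) # variation is actually present
})

test_that("generation is a pure function of spec and seed", {
  spec <- cohort_spec(n_subjects = 2, seed = 33, n_frames = 20)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$subjects[[1]]$rest_truth$values,
                   b$subjects[[1]]$rest_truth$values)
  expect_identical(a$subjects[[2]]$stress_measurements$waveforms$AV$flow,
                   b$subjects[[2]]$stress_measurements$waveforms$AV$flow)
  expect_identical(a$manifest$truth, b$manifest$truth)
})

test_that("every generated subject has stress HR above rest HR", {
  spec <- cohort_spec(n_subjects = 4, seed = 5, n_frames = 20)
  coh <- generate_cohort(spec)
  for (sub in coh$subjects) {
    expect_gt(60 / sub$stress_truth$values[["T"]],
              60 / sub$rest_truth$values[["T"]])
    expect_equal(sub$rest_measurements$state, "rest")
    expect_equal(sub$stress_measurements$state, "stress")
  }
})

test_that("waveform noise magnitude matches the requested sigma", {
  spec25 <- cohort_spec(n_subjects = 2, seed = 8,
                        noise_sd = c(rest = 25, stress = 45))
  set.seed(8)
  tr <- sample_truth_params(spec25, "rest")
  sim <- run_to_periodic_steady_state(tr$ps, control = test_control(),
                                      max_cycles = 40)
  clean <- sample_waveforms(sim, 40)
  set.seed(81)
  rmses <- replicate(30, {
    m <- synthesize_measurements(tr$ps, spec25, "rest")
    waveform_rmse(m$waveforms$AV, clean$AV)
  })
  expect_equal(mean(rmses), 25, tolerance = 0.08 * 25)
})

test_that("noise-free bundles close the loop with the generator truth", {
  fx <- noisefree_subject()
  # continuity EOA equals the generator truth exactly
  SV <- stroke_volume(fx$m$waveforms$AV)
  expect_equal(eoa_continuity(SV, fx$m$VTI),
               fx$truth$values[["av.EOA"]], tolerance = 1e-4)
  # direct assignment reproduces T and the aortic geometry
  ps <- assign_direct_parameters(fx$m)
  expect_equal(ps$values[["T"]], fx$truth$values[["T"]])
  expect_equal(ps$values[["av.A_down"]], fx$truth$values[["av.A_down"]])
  expect_equal(ps$values[["av.EOA"]], fx$truth$values[["av.EOA"]],
               tolerance = 1e-3)
})

test_that("generated stress subjects raise cardiac output over rest", {
  spec <- cohort_spec(n_subjects = 3, seed = 13, n_frames = 40)
  coh <- generate_cohort(spec)
  for (sub in coh$subjects) {
    co_rest <- compute_indices(sub$rest_measurements)$CO
    co_stress <- compute_indices(sub$stress_measurements)$CO
    expect_gt(co_stress, co_rest)
  }
})
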