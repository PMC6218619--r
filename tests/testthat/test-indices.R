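make_wf <- function(site, flow, T = 0.909) {
  n <- length(flow)
  flow_waveform(site, seq(0, T, length.out = n + 1)[seq_len(n)], flow, T)
}

test_that("stroke volume integrates simple shapes correctly", {
  T <- 1
  n <- 40
  t <- seq(0, T, length.out = n + 1)[seq_len(n)]
  expect_equal(stroke_volume(make_wf("AV", rep(0, n), T)), 0)
  # rectangle: 300 mL/s for 0.3 s
  rect <- ifelse(t >= 0.2 & t < 0.5, 300, 0)
  expect_equal(stroke_volume(make_wf("AV", rect, T)), 90, tolerance = 0.05)
  # half-sine: peak 400, duration 0.3 -> 400 * (2/pi) * 0.3
  hs <- ifelse(t < 0.3, 400 * sin(pi * t / 0.3), 0)
  expect_equal(stroke_volume(make_wf("AV", hs, T)), 400 * 2 / pi * 0.3,
               tolerance = 0.01 * 76.4)
})

test_that("output and ejection-fraction arithmetic matches cohort-scale values", {
  expect_equal(cardiac_output(85.4, 66), 5.6364, tolerance = 1e-4)
  expect_equal(cardiac_output(0, 66), 0)
  expect_equal(ejection_fraction(85.4, 153.5), 55.64, tolerance = 0.01)
  expect_equal(ejection_fraction(0, 120), 0)
  expect_error(ejection_fraction(100, 90), "EDV")
})

test_that("cuff-derived pressures, resistance and compliance", {
  expect_equal(map_from_cuff(115.5, 66), 82.5)
  expect_equal(map_from_cuff(63, 60), 61)
  expect_error(map_from_cuff(60, 80), "SBP")
  expect_equal(svr(90, 5.4), 1.0)
  expect_equal(svr(86.4, 5.6), 0.9257, tolerance = 1e-4)
  expect_equal(svr(90, 10.8), 0.5)
  expect_equal(total_arterial_compliance(100, 140, 90), 2.0)
  expect_equal(total_arterial_compliance(85.4, 115.5, 66), 1.7253,
               tolerance = 1e-4)
  expect_equal(eoa_continuity(80, 20), 4.0)
})

test_that("E/A analysis separates, ratios and merges mitral peaks", {
  T <- 0.909
  n <- 40
  t <- seq(0, T, length.out = n + 1)[seq_len(n)]
  two <- 430 * exp(-((t - 0.50) / 0.06)^2) +
    165 * exp(-((t - 0.80) / 0.04)^2)
  ea <- mitral_ea_analysis(make_wf("MV", two, T))
  expect_false(ea$merged)
  expect_equal(ea$E_peak, 430, tolerance = 5)
  expect_equal(ea$A_peak, 165, tolerance = 5)
  expect_equal(ea$E_over_A, 430 / 165, tolerance = 0.05)
  expect_lt(ea$t_E, ea$t_A)
  # single hump -> merged
  one <- 500 * exp(-((t - 0.55) / 0.08)^2)
  ea1 <- mitral_ea_analysis(make_wf("MV", one, T))
  expect_true(ea1$merged)
  expect_true(is.na(ea1$A_peak))
  # equal peaks -> ratio 1
  eq <- 300 * exp(-((t - 0.45) / 0.05)^2) +
    300 * exp(-((t - 0.80) / 0.05)^2)
  expect_equal(mitral_ea_analysis(make_wf("MV", eq, T))$E_over_A, 1,
               tolerance = 0.02)
  expect_error(mitral_ea_analysis(make_wf("MV", rep(0, n), T)),
               "positive")
})

test_that("diastolic fraction follows end-systole", {
  expect_equal(diastolic_fraction(0.5, 1), 50)
  expect_equal(diastolic_fraction(0.3, 1), 70)
  expect_error(diastolic_fraction(1.2, 1), "t_max")
})

test_that("waveform RMSE has its closed forms and noise calibration", {
  T <- 0.909
  n <- 40
  f <- 200 + 100 * sin(2 * pi * seq(0, 1, length.out = n + 1)[1:n])
  a <- make_wf("AV", f, T)
  expect_equal(waveform_rmse(a, a), 0)
  b <- make_wf("AV", f + 12.5, T)
  expect_equal(waveform_rmse(a, b), 12.5, tolerance = 1e-12)
  expect_error(waveform_rmse(a, make_wf("MV", f, T)), "site")
  # Monte-Carlo: iid noise sigma = 25 recovers as RMSE ~ 25
  set.seed(5)
  r <- replicate(400, waveform_rmse(make_wf("AV", f + rnorm(n, 0, 25), T),
                                    a))
  expect_equal(mean(r), 25, tolerance = 0.05 * 25)
})

test_that("indices are invariant to a cyclic rotation of the frames", {
  T <- 0.909
  n <- 40
  t <- seq(0, T, length.out = n + 1)[seq_len(n)]
  f <- 430 * exp(-((t - 0.50) / 0.06)^2) +
    165 * exp(-((t - 0.80) / 0.04)^2)
  rot <- function(x, k) c(x[-seq_len(k)], x[seq_len(k)])
  for (k in c(5, 13, 27)) {
    wf0 <- make_wf("MV", f, T)
    wfk <- make_wf("MV", rot(f, k), T)
    expect_equal(stroke_volume(make_wf("AV", rot(f, k), T)),
                 stroke_volume(make_wf("AV", f, T)), tolerance = 1e-9)
    ea0 <- mitral_ea_analysis(wf0)
    eak <- mitral_ea_analysis(wfk)
    # the detected peak set is rotation-invariant (which peak is labeled E
    # depends on where diastole sits relative to the time origin)
    expect_equal(sort(c(eak$E_peak, eak$A_peak)),
                 sort(c(ea0$E_peak, ea0$A_peak)))
  }
})
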