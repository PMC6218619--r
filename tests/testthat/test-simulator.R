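test_that("default parameters reach a conserved periodic steady state", {
  sim <- rest_steady_state()
  expect_true(sim$converged)
  expect_lte(sim$cycles_run, 30)
  s <- sim$series
  T <- sim$T
  # cycle-mean flows agree at all three sites (no branches)
  mean_mv <- cardioelast:::.trapz(s$time, s$Q_mv_pos) / T
  mean_av <- cardioelast:::.trapz(s$time, s$Q_av_pos) / T
  mean_aa <- cardioelast:::.trapz(s$time, s$Q_aa) / T
  expect_lt(abs(mean_mv - mean_av) / mean_av, 0.01)
  expect_lt(abs(mean_aa - mean_av) / mean_av, 0.01)
  # conservation audit: stored volume change equals net boundary inflow
  total <- rowSums(s[, c("V_la", "V_lv", "V_cpv", "V_caa", "V_cwk")])
  net_boundary <- cardioelast:::.trapz(s$time, s$Q_in - s$Q_out)
  audit <- abs((total[length(total)] - total[1]) - net_boundary)
  expect_lt(audit, 0.01)
  # valve flows are non-negative at all output time points
  expect_true(all(s$Q_mv_pos >= 0))
  expect_true(all(s$Q_av_pos >= 0))
  # physiologic sanity of the resting defaults
  expect_gt(sim$stroke_volume, 50)
  expect_lt(sim$stroke_volume, 120)
  expect_gt(max(s$P_aa), 90)
  expect_lt(max(s$P_aa), 140)
})

test_that("halving solver tolerance barely changes the cycle-mean AV flow", {
  sim1 <- rest_steady_state()
  ctrl2 <- simulation_control(points_per_cycle = 100, rtol = 5e-7,
                              atol = 5e-7)
  sim2 <- run_to_periodic_steady_state(default_parameter_set(),
                                       control = ctrl2)
  expect_lt(abs(sim1$stroke_volume - sim2$stroke_volume) /
              sim1$stroke_volume, 0.001)
})

test_that("a passive system (E_max ~ E_min) stops pumping", {
  ps <- default_parameter_set(values = c(
    "lv.E_max" = 0.0701001, "lv.E_min" = 0.07,
    "la.E_max" = 0.1001001, "la.E_min" = 0.1))
  sim <- run_to_periodic_steady_state(ps, control = test_control(),
                                      max_cycles = 40)
  s <- sim$series
  # no pulsatile pumping: only the steady source-driven trickle remains
  # (constant-pressure pulmonary source vs zero outflow pressure)
  expect_lt(max(s$Q_av_pos) - min(s$Q_av_pos), 5)
  expect_lt(max(s$P_aa) - min(s$P_aa), 2)
  expect_lt(sim$stroke_volume, 15)
  # pressures equilibrate across the open mitral pathway
  expect_lt(abs(mean(s$P_la) - mean(s$P_lv)), 2)
})

test_that("steady-state restart converges in one cycle and tol=Inf in one", {
  sim <- rest_steady_state()
  again <- run_to_periodic_steady_state(default_parameter_set(),
                                        control = test_control(),
                                        y0 = sim$final_state)
  expect_true(again$converged)
  expect_equal(again$cycles_run, 1L)
  one <- run_to_periodic_steady_state(default_parameter_set(), tol = Inf,
                                      control = test_control())
  expect_equal(one$cycles_run, 1L)
})

test_that("waveform sampling preserves the cycle integral and spacing", {
  sim <- rest_steady_state()
  wfs <- sample_waveforms(sim, 40)
  expect_named(wfs, c("MV", "AV", "AA"))
  expect_equal(wfs$AV$n_frames, 40L)
  expect_equal(diff(wfs$AV$times)[1], sim$T / 40, tolerance = 1e-12)
  sv_frames <- stroke_volume(wfs$AV)
  expect_lt(abs(sv_frames - sim$stroke_volume) / sim$stroke_volume, 0.01)
  # sampling at the solver's own density reproduces the dense output
  n_dense <- nrow(sim$series) - 1L
  wfd <- sample_waveforms(sim, n_dense)
  expect_equal(wfd$AA$flow, sim$series$Q_aa[seq_len(n_dense)],
               tolerance = 1e-6)
})

test_that("doubling output density leaves reported quantities unchanged", {
  sim1 <- rest_steady_state()
  ctrl2 <- simulation_control(points_per_cycle = 200, rtol = 1e-6,
                              atol = 1e-6)
  sim2 <- run_to_periodic_steady_state(default_parameter_set(),
                                       control = ctrl2)
  expect_lt(abs(sim1$stroke_volume - sim2$stroke_volume) /
              sim1$stroke_volume, 0.001)
  expect_lt(abs(sim1$mean_aortic_pressure - sim2$mean_aortic_pressure) /
              sim1$mean_aortic_pressure, 0.001)
})

test_that("the PV loop closes around end-systole consistently", {
  sim <- rest_steady_state()
  loop <- extract_pv_loop(sim)
  expect_gt(loop$area, 0) # counter-clockwise work loop
  # V at t_max is close to the cycle minimum
  expect_lt(loop$V_es - min(loop$V), 2)
  # elastance relation at end-systole: P = E_max (V - V_o)
  ps <- sim$ps
  P_pred <- ps$values[["lv.E_max"]] *
    (loop$V_es - ps$values[["lv.V_o"]])
  expect_lt(abs(P_pred - loop$P_es) / P_pred, 0.01)
  expect_equal(loop$t_max, sim$derived$t_max_lv)
})

test_that("simulation is deterministic given identical settings", {
  a <- run_to_periodic_steady_state(default_parameter_set(),
                                    control = test_control())
  b <- run_to_periodic_steady_state(default_parameter_set(),
                                    control = test_control())
  expect_identical(a$series, b$series)
})
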