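# Shared fixtures, built in code. Expensive objects (steady-state runs,
# synthetic subjects) are cached per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache))
    assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# fast-but-accurate solver settings for tests
test_control <- function(...) {
  simulation_control(points_per_cycle = 100, rtol = 1e-6, atol = 1e-6, ...)
}

rest_steady_state <- function() {
  cached("rest_steady", {
    run_to_periodic_steady_state(default_parameter_set(),
                                 control = test_control())
  })
}

# one noise-free synthetic rest subject (truth + measurements)
noisefree_subject <- function() {
  cached("noisefree_subject", {
    spec <- cohort_spec(n_subjects = 2, seed = 7,
                        noise_sd = c(rest = 0, stress = 0),
                        cuff_sd = 0, esv_sd = 0)
    set.seed(7)
    tr <- sample_truth_params(spec, "rest")
    m <- synthesize_measurements(tr$ps, spec, "rest", id = "S01")
    list(spec = spec, truth = tr$ps, m = m)
  })
}

# random-but-valid elastance parameter draw used by property tests
random_elastance_params <- function() {
  repeat {
    E_min <- stats::runif(1, 0.02, 0.5)
    E_max <- E_min + stats::runif(1, 0.1, 5)
    p <- try(elastance_params(E_max = E_max, E_min = E_min,
                              R_C = stats::runif(1, 0.5, 8),
                              R_R = stats::runif(1, 2, 120),
                              alpha_S = stats::runif(1, 0.05, 0.6),
                              alpha_D = stats::runif(1, 0.1, 0.8),
                              V_o = stats::runif(1, 0, 30),
                              t_onset = 0), silent = TRUE)
    if (!inherits(p, "try-error")) return(p)
  }
}
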