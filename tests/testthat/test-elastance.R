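test_that("Double-Hill elastance matches a direct evaluation of the formula", {
  p <- elastance_params(E_max = 1.8, E_min = 0.08, R_C = 1.5, R_R = 37.2,
                        alpha_S = 0.3, alpha_D = 0.4)
  T <- 0.909
  # independent naive evaluation (no log-space guards)
  t <- 0.2
  x <- t / (0.3 * T)
  y <- t / (0.4 * T)
  direct <- function(alpha)
    alpha * (1.8 - 0.08) * (x^1.5 / (1 + x^1.5)) * (1 / (1 + y^37.2)) + 0.08
  expect_equal(double_hill_elastance(t, p, T, alpha = 1), direct(1),
               tolerance = 1e-12)
  sc <- compute_alpha_scaling(p, T)
  expect_equal(double_hill_elastance(t, p, T, alpha = sc$alpha),
               direct(sc$alpha), tolerance = 1e-12)
})

test_that("elastance is E_min at activation onset and bounded by E_max", {
  p <- elastance_params(E_max = 2.5, E_min = 0.06, R_C = 2, R_R = 25,
                        alpha_S = 0.25, alpha_D = 0.45)
  sc <- compute_alpha_scaling(p, 1)
  expect_identical(double_hill_elastance(0, p, 1, sc$alpha), p$E_min)
  tt <- seq(0, 1, length.out = 2000)
  e <- double_hill_elastance(tt, p, 1, sc$alpha)
  expect_true(all(e >= p$E_min - 1e-12))
  expect_true(all(e <= p$E_max * (1 + 1e-8)))
  # periodic with period T
  expect_equal(double_hill_elastance(tt + 3, p, 1, sc$alpha), e,
               tolerance = 1e-12)
})

test_that("alpha scaling attains E_max for 1000 random parameter draws", {
  set.seed(42)
  worst <- 0
  for (k in 1:1000) {
    p <- random_elastance_params()
    T <- stats::runif(1, 0.4, 1.2)
    sc <- compute_alpha_scaling(p, T)
    e_peak <- double_hill_elastance(sc$t_max, p, T, sc$alpha)
    worst <- max(worst, abs(e_peak - p$E_max) / p$E_max)
    if (k <= 50) {
      e0 <- double_hill_elastance(0, p, T, sc$alpha)
      expect_identical(e0, p$E_min)
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("t_max matches a dense grid-search oracle", {
  p <- elastance_params(E_max = 1.8, E_min = 0.08, R_C = 1.5, R_R = 37.2,
                        alpha_S = 0.3, alpha_D = 0.4)
  T <- 0.909
  sc <- compute_alpha_scaling(p, T)
  # independent oracle: 1e5-point grid + local quadratic refinement
  grid <- seq(0, T, length.out = 1e5 + 1)[-1]
  shape <- function(t) {
    x <- t / (p$alpha_S * T); y <- t / (p$alpha_D * T)
    (x^p$R_C / (1 + x^p$R_C)) * (1 / (1 + y^p$R_R))
  }
  i <- which.max(shape(grid))
  o <- stats::optimize(shape, lower = grid[i - 1], upper = grid[i + 1],
                       maximum = TRUE, tol = 1e-12)
  expect_equal(sc$t_max, o$maximum, tolerance = 1e-6)
  expect_equal(sc$alpha, 1 / o$objective, tolerance = 1e-8)
})

test_that("unscaled peak of one half gives alpha equal to its reciprocal", {
  # symmetric construction whose raw Hill product peaks at a computable value
  p <- elastance_params(E_max = 2, E_min = 0.1, R_C = 3, R_R = 3,
                        alpha_S = 0.2, alpha_D = 0.2)
  grid <- seq(1e-6, 1, length.out = 2e5)
  x <- grid / 0.2
  raw <- (x^3 / (1 + x^3)) * (1 / (1 + x^3))
  expect_equal(compute_alpha_scaling(p, 1)$alpha, 1 / max(raw),
               tolerance = 1e-6)
})

test_that("chamber pressure is the elastance line through V_o", {
  expect_identical(chamber_pressure(10, 2, 10), 0)
  expect_identical(chamber_pressure(60, 2, 10), 100)
  set.seed(1)
  for (k in 1:20) {
    E <- stats::runif(1, 0.05, 5)
    V_o <- stats::runif(1, 0, 30)
    V <- stats::runif(1, 5, 200)
    P <- chamber_pressure(V, E, V_o)
    expect_equal(P / E + V_o, V, tolerance = 1e-12)
  }
})

test_that("elastance parameter validation rejects bad shapes", {
  expect_error(elastance_params(1, 2, 1, 1, 0.3, 0.4), "E_max > E_min")
  expect_error(elastance_params(2, 1, -1, 1, 0.3, 0.4), "positive")
  expect_error(elastance_params(2, 1, 1, 1, 1.2, 0.4), "alpha")
  expect_error(elastance_params(2, 1, 1, 1, 0.3, 0.4, V_o = -1), "V_o")
})

test_that("time constants are exact products", {
  expect_equal(tau_constants(0.5, 0.5, 60 / 105)[["tau_D"]], 0.5 * 60 / 105)
  expect_equal(unname(tau_constants(0, 0, 1)), c(0, 0))
  expect_equal(tau_constants(0.3, 0.4, 0.909),
               c(tau_S = 0.2727, tau_D = 0.3636), tolerance = 1e-3)
})
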