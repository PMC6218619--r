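# Independent oracle: exact two-sided signed-rank p by brute-force
# enumeration of every sign assignment on the observed ranks.
brute_force_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- signs %*% r
  p_low <- mean(W_all <= W_obs)
  p_high <- mean(W_all >= W_obs)
  min(1, 2 * min(p_low, p_high))
}

test_that("nine uniformly positive differences give the cohort-scale p", {
  rest <- c(55, 60, 62, 64, 66, 68, 70, 75, 82)
  stress <- rest + c(21, 35, 30, 44, 39, 37, 55, 46, 45)
  pc <- wilcoxon_signed_rank(rest, stress, method = "asymptotic")
  expect_equal(pc$W, 45)
  expect_equal(pc$p, 2 * pnorm(-22.5 / sqrt(9 * 10 * 19 / 24)),
               tolerance = 1e-12)
  expect_equal(round(pc$p, 3), 0.008)
  ex <- wilcoxon_signed_rank(rest, stress, method = "exact")
  expect_equal(ex$p, 2 / 512)
  expect_true(pc$significant)
})

test_that("exact p matches brute-force enumeration on random patterns", {
  set.seed(9)
  for (n in c(4, 6, 9, 12)) {
    for (rep in 1:8) {
      d <- round(stats::rnorm(n, mean = 0.3), 2)
      d <- d[d != 0]
      if (length(d) < 2) next
      ours <- wilcoxon_signed_rank(d, method = "exact")$p
      expect_equal(ours, brute_force_p(d), tolerance = 1e-12)
    }
  }
})

test_that("exact p agrees with the reference implementation without ties", {
  set.seed(10)
  for (rep in 1:10) {
    d <- stats::rnorm(9, 0.4)
    ref <- suppressWarnings(stats::wilcox.test(d, exact = TRUE))$p.value
    ours <- wilcoxon_signed_rank(d, method = "exact")$p
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("asymptotic p tracks the exact distribution at n = 9", {
  # enumerate every possible W (no ties): tight agreement in the
  # decision-relevant tails, bounded discrepancy mid-range (the normal
  # approximation without continuity correction is coarse at n = 9)
  n <- 9
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- signs %*% (1:n)
  for (w in 0:45) {
    p_low <- mean(W_all <= w)
    p_high <- mean(W_all >= w)
    pe <- min(1, 2 * min(p_low, p_high))
    z <- (w - n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
    pa <- 2 * pnorm(-abs(z))
    if (pe <= 0.06) expect_lt(abs(pa - pe), 0.01)
    expect_lt(abs(pa - pe), 0.06)
  }
})

test_that("the test is symmetric and drops zero differences", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  y <- c(2, 1, 5, 3, 9, 4, 10, 8, 12)
  p1 <- wilcoxon_signed_rank(x, y)$p
  p2 <- wilcoxon_signed_rank(y, x)$p
  expect_equal(p1, p2, tolerance = 1e-12)
  # zero differences are dropped before ranking
  withz <- wilcoxon_signed_rank(c(0, 0, 1, -2, 3), method = "exact")
  expect_equal(withz$n, 3)
  expect_error(wilcoxon_signed_rank(rep(0, 5)), "undefined|non-zero")
})

test_that("cohort summary pairs subjects and flags significance", {
  set.seed(12)
  df <- data.frame(subject = rep(sprintf("S%02d", 1:9), each = 2),
                   state = rep(c("rest", "stress"), 9))
  df$HR <- ifelse(df$state == "rest", rnorm(18, 66, 5), rnorm(18, 105, 8))
  df$flat <- 3.5
  out <- summarize_cohort(df, c("HR", "flat"))
  hr <- out[out$variable == "HR", ]
  expect_true(hr$significant)
  expect_lt(hr$p, 0.05)
  expect_gt(hr$stress_mean, hr$rest_mean)
  expect_true(hr$rest_min <= hr$rest_mean && hr$rest_mean <= hr$rest_max)
  flat <- out[out$variable == "flat", ]
  expect_equal(flat$rest_sd, 0)
  expect_equal(flat$rest_min, flat$rest_max)
  expect_false(flat$significant)
  # unpaired subject is rejected by name
  bad <- df[-2, ]
  expect_error(summarize_cohort(bad, "HR"), "S01")
})
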