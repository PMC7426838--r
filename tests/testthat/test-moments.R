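test_that("the first moment evaluates the closed form", {
  pc <- crit_params(A = 0)
  expect_equal(first_moment(pc, c(0, 3, 17)), rep(1, 3))

  p <- crit_params(A = 0.05)
  # full periods: the cosine term cancels and the mean returns to 1
  k <- 1:4
  expect_equal(first_moment(p, 2 * pi * k / p$nu), rep(1, 4),
               tolerance = 1e-14)
  # half period nu*t = pi
  expect_equal(first_moment(p, 4), exp(2 * 0.05 * 4 / pi))
  # t < t0: the process has not started
  expect_equal(first_moment(p, -1), 0)

  pr <- subcrit_params()
  expect_equal(first_moment(pr, 10), exp(-0.1))
})

test_that("the exact second moment reduces to 1 + 2 q2 t at A = 0 and is consistent with the expansion", {
  p0 <- crit_params(A = 0)
  expect_equal(as.numeric(second_moment_exact(p0, 0)), 1)
  expect_equal(as.numeric(second_moment_exact(p0, 10)), 11, tolerance = 1e-9)

  # exact - first-order gap scales as A^2: halving A quarters the gap
  for (t in c(8, 16)) {
    gap <- function(A) {
      p <- crit_params(A = A)
      abs(as.numeric(second_moment_exact(p, t)) -
            second_moment_first_order(p, t))
    }
    ratio <- gap(0.1) / gap(0.05)
    expect_gt(ratio, 3); expect_lt(ratio, 5.5)
  }

  # first-order formula refuses off-critical parameters
  expect_error(second_moment_first_order(subcrit_params(), 5), "critical")

  # large-q2t ratio to the A = 0 value approaches 1 - (As/nu)(2 cos(nu t) - 1)
  p <- crit_params(A = 0.05)
  t <- 4000
  lead <- 1 - (p$A * p$s / p$nu) * (2 * cos(p$nu * t) - 1)
  expect_equal(second_moment_first_order(p, t) / (1 + 2 * p$q2 * t), lead,
               tolerance = 1e-3)
})

test_that("second moments agree with Monte-Carlo ensembles within 3 SE", {
  p <- crit_params(A = 0.05)
  grid <- c(4, 8, 16, 24, 30)
  ens <- run_ensemble(p, n_runs = 3e5, horizon = 31, grid = grid, seed = 91)
  m <- ens$moments
  expect_within_3se(m$mean_n, first_moment(p, grid), m$se_n)
  en2 <- vapply(grid, function(t) as.numeric(second_moment_exact(p, t)),
                numeric(1))
  expect_within_3se(m$mean_n2, en2, m$se_n2)
})

test_that("zeroth-order factorial moments evaluate Eq.-style closed forms and limits", {
  p0 <- crit_params(A = 0)
  expect_equal(factorial_moment_g0(p0, 1, 5), 1)
  expect_equal(factorial_moment_g0(p0, 3, 4), 6 * (0.5 * 4)^2)  # 24

  # analytic r -> 0 limit agrees with a small-r numerical evaluation
  pr <- bp_params_rq(r = 1e-8, q2 = 0.5)
  expect_equal(factorial_moment_g0(pr, 3, 4),
               factorial_moment_g0(p0, 3, 4), tolerance = 1e-6)

  # subcritical decay: g_n ~ n! e^{-r d} (q2/r)^{n-1} for r*d >> 1
  ps <- bp_params_rq(r = 0.2, q2 = 0.4)
  d <- 100
  expect_equal(factorial_moment_g0(ps, 2, d),
               2 * exp(-0.2 * d) * (0.4 / 0.2), tolerance = 1e-6)
})

test_that("first-order factorial moments integrate the oscillation kernel correctly", {
  p <- crit_params(A = 0.05)
  # n = 1: the kernel integrates to (1 - cos(nu t))/nu, consistent with
  # expanding the exact mean to O(A)
  for (t in c(3, 8, 13)) {
    expect_equal(factorial_moment_g1(p, 1, t),
                 p$s * (1 - cos(p$nu * t)) / p$nu, tolerance = 1e-8)
  }
  # ... so the order-1 moment reproduces 1 - (As/nu)(cos(nu t) - 1)
  t <- 5
  expect_equal(moment_from_factorial(p, 1, t, max_order_in_A = 1),
               1 - (p$A * p$s / p$nu) * (cos(p$nu * t) - 1),
               tolerance = 1e-8)

  # n = 2 at criticality: closed form of the kernel integral
  for (t in c(6, 18)) {
    expect_equal(
      factorial_moment_g1(p, 2, t),
      factorial_moment_g0(p, 2, t) * (p$s / p$nu) *
        (1 - 2 * cos(p$nu * t) + sin(p$nu * t) / (p$nu * t)),
      tolerance = 1e-7)
  }

  # factorial-moment route equals the printed first-order second moment
  for (t in c(4, 10, 16)) {
    expect_equal(moment_from_factorial(p, 2, t, max_order_in_A = 1),
                 second_moment_first_order(p, t), tolerance = 1e-7)
  }
})

test_that("Stirling conversion assembles raw moments from factorial moments", {
  p <- crit_params(A = 0.02)
  t <- 7
  g <- vapply(1:3, function(n)
    factorial_moment_g0(p, n, t) + p$A * factorial_moment_g1(p, n, t),
    numeric(1))
  expect_equal(moment_from_factorial(p, 1, t), g[1], tolerance = 1e-10)
  expect_equal(moment_from_factorial(p, 2, t), g[2] + g[1], tolerance = 1e-10)
  expect_equal(moment_from_factorial(p, 3, t), g[3] + 3 * g[2] + g[1],
               tolerance = 1e-10)
  expect_error(moment_from_factorial(p, 2, t, max_order_in_A = 2), "0 or 1")
})

test_that("the covariance obeys its structural identities", {
  p <- crit_params(A = 0.05)
  # deterministic initial condition: zero covariance with t_min = t0
  expect_equal(as.numeric(covariance(p, 0, 12)), 0, tolerance = 1e-12)

  # A = 0 equal-time value: (2 q2/r + 1)(e^{-rt} - e^{-2rt})
  pr <- subcrit_params()
  expect_equal(as.numeric(covariance(pr, 10, 10)),
               (2 * 0.495 / 0.01 + 1) * (exp(-0.1) - exp(-0.2)),
               tolerance = 1e-9)

  # symmetry and the variance identity, random times
  set.seed(2)
  for (i in 1:5) {
    t1 <- runif(1, 0, 20); t2 <- runif(1, 0, 20)
    expect_equal(as.numeric(covariance(p, t1, t2)),
                 as.numeric(covariance(p, t2, t1)), tolerance = 1e-9)
  }
  for (t in c(3, 7, 15)) {
    expect_equal(as.numeric(covariance(p, t, t)),
                 as.numeric(second_moment_exact(p, t)) -
                   first_moment(p, t)^2,
                 tolerance = 1e-8)
  }
})

test_that("variances are non-negative across parameter sets", {
  sets <- list(crit_params(A = 0.05), crit_params(A = 0.5),
               subcrit_params(A = 0.04), bp_params(1, 0.3, A = -0.2))
  for (p in sets) {
    for (t in seq(0.5, 25, by = 2)) {
      v <- as.numeric(second_moment_exact(p, t)) - first_moment(p, t)^2
      expect_gte(v, -1e-8)
    }
  }
})

test_that("moment_series returns tidy curves and flags strong perturbations", {
  p <- crit_params(A = 0.05)
  ms <- moment_series(p, c(1, 2, 3), order = 2, method = "exact")
  expect_s3_class(ms, "tbl_df")
  expect_named(ms, c("time", "st", "value", "order", "method"))
  expect_warning(
    moment_series(crit_params(A = 0.5, nu = pi / 8), 1:3, order = 1,
                  method = "first_order"),
    "first-order")
})
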