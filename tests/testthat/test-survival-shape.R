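test_that("first-order survival evaluates the closed form and its limits", {
  p0 <- crit_params(A = 0)
  expect_equal(survival_first_order(p0, 2), 0.5)
  p <- crit_params(A = 0.05)
  expect_equal(survival_first_order(p, 0), 1)
  # at A = 0 survival is monotone non-increasing
  tt <- seq(0, 40, by = 0.1)
  expect_true(all(diff(survival_first_order(p0, tt)) <= 0))
  # positive amplitude lifts survival at every plotted time
  shift <- survival_first_order(p, tt[-1]) - survival_first_order(p0, tt[-1])
  expect_true(all(shift > 0))
  # negative amplitude lowers it
  pm <- crit_params(A = -0.05)
  expect_true(all(survival_first_order(pm, tt[-1]) -
                    survival_first_order(p0, tt[-1]) < 0))
  expect_error(survival_first_order(subcrit_params(), 1), "critical")
})

test_that("the duration density is minus the derivative of survival and normalises", {
  p <- crit_params(A = 0.05)
  h <- 1e-6
  for (t in c(0.5, 3, 11, 27)) {
    num <- -(survival_first_order(p, t + h) -
               survival_first_order(p, t - h)) / (2 * h)
    expect_equal(duration_density(p, t), num, tolerance = 1e-6)
  }
  # normalisation: integrate period by period out to L, close with P_s(L)
  L <- 800; period <- 2 * pi / p$nu
  brk <- c(seq(0, L, by = period), L)
  total <- sum(vapply(seq_len(length(brk) - 1), function(i)
    stats::integrate(function(t) duration_density(p, t), brk[i], brk[i + 1],
                     rel.tol = 1e-10)$value, numeric(1))) +
    survival_first_order(p, L)
  expect_equal(total, 1, tolerance = 1e-6)
  # large-t envelope ~ t^-2: t^2 * P_T stays bounded and oscillates
  tt <- seq(100, 400, by = 0.5)
  env <- tt^2 * duration_density(p, tt)
  expect_true(all(env > 0))
  expect_lt(max(env) / min(env), 1.5)
  expect_gt(max(env) / min(env), 1.01)  # oscillation is superimposed
})

test_that("empirical survival matches the first-order curve within MC error", {
  p <- crit_params(A = 0.05)
  grid <- c(2, 5, 10, 20, 30)
  ens <- run_ensemble(p, n_runs = 2e5, horizon = 31, grid = grid, seed = 14)
  m <- ens$moments
  # O(A^2) slack on top of 3 SE for the truncated expansion
  expect_within_3se(m$survival, survival_first_order(p, grid),
                    m$se_survival, slack = p$A^2)
})

test_that("ultimate survival covers both branches, the tied frequencies, and the critical refusal", {
  pA0 <- bp_params_rq(r = -0.01, q2 = 0.5, A = 0, nu = pi / 4)
  expect_equal(as.numeric(ultimate_survival(pA0)), 0.01 / 0.5)

  # tied frequencies nu = -r (maximum) and nu = r (minimum)
  q2 <- 0.5; r <- -0.01; s <- r + 2 * q2; A <- 0.1
  pp <- bp_params_rq(r, q2, A = A, nu = pi / 4)
  up <- as.numeric(ultimate_survival(pp, tie_nu = "-r"))
  dn <- as.numeric(ultimate_survival(pp, tie_nu = "r"))
  expect_equal(up, -r / q2 + A * s / (2 * q2), tolerance = 1e-12)
  expect_equal(dn, -r / q2 - A * s / (2 * q2), tolerance = 1e-12)

  # subcritical: limit 0 with an exponential envelope
  ps <- bp_params_rq(r = 0.05, q2 = 0.45, A = 0.02, nu = pi / 4)
  u <- ultimate_survival(ps)
  expect_equal(as.numeric(u), 0)
  env <- attr(u, "envelope")
  expect_equal(env(0), 1 / (1 + 0.45 / 0.05))
  expect_lt(env(200), 1e-3)

  expect_error(ultimate_survival(crit_params()), "critical")

  # continuity of onset: ultimate survival -> 0 as r -> 0^- at fixed nu
  vals <- vapply(c(-1e-2, -1e-3, -1e-4), function(r) {
    as.numeric(ultimate_survival(bp_params_rq(r, 0.5, A = 0.05, nu = pi / 4)))
  }, numeric(1))
  expect_true(all(diff(abs(vals)) < 0))
  expect_lt(abs(vals[3]), 1e-3)
})

test_that("shape profiles normalise to unit area and refuse degenerate input", {
  tau <- seq(0, 1, length.out = 51)
  v <- 1 + sin(pi * tau)
  sp <- shape_profile(tau, v, T = 8)
  area <- sum(diff(tau) * (head(sp$value, -1) + tail(sp$value, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-12)
  expect_error(shape_profile(tau, rep(0, 51), T = 8), "area")
  expect_error(shape_profile(tau, -v, T = 8), "non-negative")
})

test_that("duration-averaged shapes behave per the averaging identity", {
  p0 <- crit_params(A = 0)
  tau <- seq(0, 1, length.out = 21)
  one <- shape_oracle(p0, T = 10, tau_grid = tau, tol = 1e-8)
  # single profile: averaging returns it area-normalised
  avg1 <- shape_averaged(list(one), weights = "analytic", params = p0)
  expect_equal(avg1$value, one$value, tolerance = 1e-12)

  Ts <- exp(seq(log(1), log(120), length.out = 12))
  profs <- lapply(Ts, function(T) shape_oracle(p0, T, tau, tol = 1e-8))
  avg <- shape_averaged(profs, weights = "analytic", params = p0)
  area <- sum(diff(tau) * (head(avg$value, -1) + tail(avg$value, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-12)
  # the A = 0 critical average is symmetric and single-humped (parabola-like)
  expect_equal(avg$value, rev(avg$value), tolerance = 0.05)

  # small amplitude: the averaged shape stays close to the A = 0 average
  pA <- crit_params(A = 0.02)
  profsA <- lapply(Ts, function(T) shape_oracle(pA, T, tau, tol = 1e-8))
  avgA <- shape_averaged(profsA, weights = "analytic", params = pA)
  expect_lt(max(abs(avgA$value - avg$value)), 0.05 * max(avg$value))
})
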