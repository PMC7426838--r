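test_that("identical seed and parameters reproduce the event log bitwise", {
  p <- crit_params()
  a <- simulate_avalanche(p, horizon = 50, seed = 123)
  b <- simulate_avalanche(p, horizon = 50, seed = 123)
  expect_identical(a$events, b$events)
  c <- simulate_avalanche(p, horizon = 50, seed = 124)
  expect_false(identical(a$events, c$events))
})

test_that("avalanche records count events per the bookkeeping conventions", {
  mk_log <- function(events, n0 = 1L, terminated = TRUE, horizon = 10) {
    structure(list(events = events, params = bp_params(1, 0.5, n0 = n0),
                   seed = 1L, horizon = horizon, terminated = terminated),
              class = "bp_eventlog")
  }
  rec <- as_avalanche_record(mk_log(tibble::tibble(
    time = 0.3, kind = "extinct", n_after = 0L)))
  expect_equal(rec$T, 0.3)
  expect_equal(rec$S, 1)
  expect_equal(rec$peak, 1)
  expect_false(rec$censored)

  rec2 <- as_avalanche_record(mk_log(tibble::tibble(
    time = c(0.2, 0.5, 0.9), kind = c("branch", "extinct", "extinct"),
    n_after = c(2L, 1L, 0L))))
  expect_equal(rec2$T, 0.9)
  expect_equal(rec2$S, 2)
  expect_equal(rec2$peak, 2)

  rec3 <- as_avalanche_record(mk_log(tibble::tibble(
    time = 0.2, kind = "branch", n_after = 2L), terminated = FALSE))
  expect_true(rec3$censored)
  expect_true(is.na(rec3$T))
})

test_that("simulated logs satisfy the structural invariants", {
  p <- crit_params(A = 0.3)
  for (seed in 1:25) {
    log <- simulate_avalanche(p, horizon = 40, seed = seed)
    ev <- log$events
    if (nrow(ev) == 0) next
    expect_true(all(diff(ev$time) > 0))
    expect_true(all(ev$time >= p$t0))
    step <- ifelse(ev$kind == "branch", 1L, -1L)
    expect_equal(ev$n_after, p$n0 + cumsum(step))
    expect_true(all(ev$n_after >= 0))
    if (log$terminated) expect_equal(ev$n_after[nrow(ev)], 0L)
    # binary process: extinctions = size when not censored
    if (log$terminated) {
      expect_equal(sum(ev$kind == "extinct"), as_avalanche_record(log)$S)
    }
  }
})

test_that("population profiles are right-continuous and integrate consistently", {
  p <- crit_params(A = 0.2)
  log <- simulate_avalanche(p, horizon = 40, seed = 3)  # long realisation
  ev <- log$events
  expect_gt(nrow(ev), 50)
  # before the first event: n0; exactly at an event: post-event value
  expect_equal(sample_profile(log, ev$time[1] / 2)$n, p$n0)
  expect_equal(sample_profile(log, ev$time[2])$n, ev$n_after[2])
  # Riemann sum over a fine grid vs exact event-log integration of N dt
  t_end <- ev$time[nrow(ev)]
  exact <- sum(c(p$n0, utils::head(ev$n_after, -1)) *
                 diff(c(p$t0, ev$time)))
  grid <- seq(p$t0, t_end, length.out = 200001)
  riemann <- sum(sample_profile(log, utils::head(grid, -1))$n) * diff(grid)[1]
  expect_equal(riemann, exact, tolerance = 1e-3)
})

test_that("pure-death survival matches the inhomogeneous-exponential law", {
  # p2 = 0: a single particle dies at hazard s*(1 - A*sin(nu*t)); its death
  # time has the closed-form survival exp(-s*t - (A*s/nu)*(cos(nu*t) - 1))
  p <- bp_params(s = 1, p2 = 0, A = 0.05, nu = pi / 4)
  n <- 1e5
  ens <- run_ensemble(p, n_runs = n, horizon = 60, seed = 31)
  T_obs <- ens$records$T
  expect_false(any(ens$records$censored))
  for (t in c(0.5, 1, 2, 4, 8)) {
    surv_true <- exp(-t - (0.05 / (pi / 4)) * (cos(pi * t / 4) - 1))
    se <- sqrt(surv_true * (1 - surv_true) / n)
    expect_within_3se(mean(T_obs > t), surv_true, se)
  }
  # full-distribution check (Kolmogorov-Smirnov at alpha = 0.01)
  cdf <- function(t) 1 - exp(-t - (0.05 / (pi / 4)) * (cos(pi * t / 4) - 1))
  expect_gt(stats::ks.test(T_obs, cdf)$p.value, 0.01)

  # A = 0 reduction: plain exponential
  p0 <- bp_params(s = 1, p2 = 0, A = 0, nu = pi / 4)
  ens0 <- run_ensemble(p0, n_runs = 1e5, horizon = 60, seed = 32)
  expect_gt(stats::ks.test(ens0$records$T, stats::pexp, 1)$p.value, 0.01)
})

test_that("standard-branching limits are recovered at A = 0", {
  # subcritical mean E[N(t)] = exp(-r t); critical survival 1/(1 + q2 t)
  pr <- subcrit_params()
  grid <- c(2, 5, 10, 20)
  ens <- run_ensemble(pr, n_runs = 2e5, horizon = 30, grid = grid, seed = 5)
  m <- ens$moments
  expect_within_3se(m$mean_n, exp(-pr$r * grid), m$se_n)

  pc <- crit_params(A = 0)
  ensc <- run_ensemble(pc, n_runs = 2e5, horizon = 30, grid = grid, seed = 6)
  mc <- ensc$moments
  expect_within_3se(mc$survival, 1 / (1 + pc$q2 * grid), mc$se_survival)
})

test_that("event logs round-trip through TSV", {
  p <- crit_params(A = 0.1)
  log <- simulate_avalanche(p, horizon = 30, seed = 17)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eventlog(log, path)
  back <- read_eventlog(path)
  expect_equal(back$events, log$events)
  expect_equal(back$params, log$params)
  expect_equal(back$seed, log$seed)
  expect_equal(back$terminated, log$terminated)
})

test_that("the explosion guard trips on supercritical runaway", {
  p <- bp_params_rq(r = -0.5, q2 = 1)
  expect_error(simulate_avalanche(p, horizon = 1e4, seed = 2, max_pop = 100),
               "exploded")
})
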