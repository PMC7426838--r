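# Non-perturbative numerical oracle via the probability generating function
# F(x; t0, t) = E[x^N(t) | N(t0) = 1] of the time-inhomogeneous binary
# branching process.
#
# F satisfies the backward evolution equation in the starting time u,
#   dF/du = (q2 + eps(u)) F - q2 F^2 - eps(u),   F(u = t) = x,
# integrated from the terminal condition at u = t down to u = t0. x = 1 is a
# fixed point (F = 1). Derivatives of F with respect to x obey the linear
# variational equations
#   dF1/du = (q2 + eps(u) - 2 q2 F) F1,          F1(t) = 1,
#   dF2/du = (q2 + eps(u) - 2 q2 F) F2 - 2 q2 F1^2,  F2(t) = 0,
# integrated alongside (no finite differences), giving exact moments and the
# termination-time conditioned avalanche shape.

gf_rhs <- function(u, y, parms) {
  eps <- parms$s * (parms$p0 - parms$A * sin(parms$nu * u))
  lam <- parms$q2 + eps
  dF <- lam * y[1] - parms$q2 * y[1]^2 - eps
  jac <- lam - 2 * parms$q2 * y[1]
  dF1 <- jac * y[2]
  dF2 <- jac * y[3] - 2 * parms$q2 * y[2]^2
  list(c(dF, dF1, dF2))
}

gf_integrate <- function(params, x, times_desc, tol) {
  y0 <- c(F = x, F1 = 1, F2 = 0)
  sol <- deSolve::ode(
    y = y0, times = times_desc, func = gf_rhs, parms = params,
    method = "lsoda", rtol = tol, atol = tol)
  if (attr(sol, "istate")[1] < 0) {
    stop("generating-function ODE solver failed (istate = ",
         attr(sol, "istate")[1], ")")
  }
  sol
}

#' Solve for the probability generating function of the population size
#'
#' Computes `F(x; t0, t) = E[x^N(t) | N(t0) = 1]` together with its first
#' and second derivatives in `x`, by backward integration of the
#' Riccati-type evolution equation from the terminal condition `F = x` at
#' the end time down to the start time (see the source header for the
#' equations). This is exact to solver tolerance for any amplitude — no
#' expansion in `A` — and serves as the package's independent oracle for
#' the closed-form and perturbative observables.
#'
#' @param params A [bp_params()] with `n0 = 1`.
#' @param x Argument of the generating function, in `[0, 1]`.
#' @param t End time.
#' @param t0 Start time (defaults to `params$t0`).
#' @param tol Solver relative and absolute tolerance (default `1e-10`).
#' @return A list of class `gf_solution`: `x`, `t0`, `t`, `F`, `dF_dx`,
#'   `d2F_dx2`, `tol`.
#' @examples
#' p <- bp_params(s = 1, p2 = 0.5, A = 0, nu = pi / 4)
#' gf_solve(p, x = 0, t = 2)$F  # extinction probability q2*t/(1+q2*t) = 0.5
#' @export
gf_solve <- function(params, x, t, t0 = params$t0, tol = 1e-10) {
  check_analytic_params(params)
  stopifnot(length(x) == 1, x >= 0, x <= 1, t >= t0)
  if (t == t0) {
    return(structure(list(x = x, t0 = t0, t = t, F = x, dF_dx = 1,
                          d2F_dx2 = 0, tol = tol), class = "gf_solution"))
  }
  sol <- gf_integrate(params, x, c(t, t0), tol)
  last <- sol[nrow(sol), ]
  structure(list(x = x, t0 = t0, t = t, F = unname(last["F"]),
                 dF_dx = unname(last["F1"]), d2F_dx2 = unname(last["F2"]),
                 tol = tol),
            class = "gf_solution")
}

#' @export
print.gf_solution <- function(x, ...) {
  cat(sprintf("<gf_solution> F(%.6g; %g, %g) = %.10g\n", x$x, x$t0, x$t, x$F))
  cat(sprintf("  dF/dx = %.10g   d2F/dx2 = %.10g  (tol %g)\n",
              x$dF_dx, x$d2F_dx2, x$tol))
  invisible(x)
}

#' Exact survival probability from the generating function
#'
#' `P_s(t0, t) = 1 - F(0; t0, t)`: one minus the extinction probability by
#' time `t`. Valid for any mass `r` and any admissible amplitude, unlike the
#' first-order closed form.
#'
#' @inheritParams gf_solve
#' @param t Time(s) `>= t0` (vectorised).
#' @return Numeric vector of survival probabilities.
#' @export
survival_exact <- function(params, t, tol = 1e-10) {
  check_analytic_params(params)
  vapply(t, function(tt) {
    if (tt == params$t0) return(1)
    1 - gf_solve(params, x = 0, t = tt, tol = tol)$F
  }, numeric(1))
}

# extinction probability (by time T) of a single particle alive at each of
# the times `ts` (sorted increasing, all <= T): one backward solve from T
gf_extinction_by <- function(params, ts, T, tol = 1e-10) {
  stopifnot(all(ts <= T), !is.unsorted(ts))
  times_desc <- unique(c(T, rev(ts)))
  sol <- gf_integrate(params, 0, times_desc, tol)
  unname(sol[match(ts, sol[, "time"]), "F"])
}

#' Avalanche shape conditioned on the termination time (exact)
#'
#' The expected population at time `t` conditioned on the avalanche going
#' spontaneously extinct exactly at `T`,
#' \deqn{V(t, T) = E[N(t) \mid \text{death at } T]
#'   = 1 + q\,\frac{G''(q)}{G'(q)},}
#' where `q = F(0; t, T)` is the probability that one particle alive at `t`
#' dies out by `T`, and `G(x) = F(x; t0, t)` is the generating function of
#' `N(t)`, with derivatives from the variational equations. The death-time
#' density cancels in the conditioning, so no numerical differentiation in
#' `T` is involved. Exact (to solver tolerance) at any amplitude; at
#' `A = 0`, r = 0 the profile is symmetric under `t <-> T - t`, while the
#' oscillating extinction imposes characteristic, generally asymmetric humps.
#'
#' @inheritParams gf_solve
#' @param t Time(s) in `[t0, T]` (vectorised).
#' @param T Termination time.
#' @return Numeric vector `V(t, T)`.
#' @export
shape_conditioned <- function(params, t, T, tol = 1e-10) {
  check_analytic_params(params)
  stopifnot(T > params$t0, all(t >= params$t0), all(t <= T))
  ord <- order(t)
  ts <- t[ord]
  qv <- gf_extinction_by(params, ts, T, tol)
  V <- vapply(seq_along(ts), function(i) {
    tt <- ts[i]
    if (tt == params$t0) return(1)
    g <- gf_solve(params, x = min(max(qv[i], 0), 1), t = tt, tol = tol)
    if (g$dF_dx <= 0) stop("G'(q) vanished at t = ", tt)
    1 + qv[i] * g$d2F_dx2 / g$dF_dx
  }, numeric(1))
  out <- numeric(length(t))
  out[ord] <- V
  out
}

#' Oracle avalanche-shape profile on a rescaled time grid
#'
#' Convenience wrapper: evaluates [shape_conditioned()] on `tau * T` for
#' `tau` in `[0, 1]` and packages the result as an area-normalised
#' [shape_profile()].
#'
#' @inheritParams shape_conditioned
#' @param tau_grid Grid on `[0, 1]` (default 101 uniform points).
#' @return A `bp_shape`.
#' @export
shape_oracle <- function(params, T, tau_grid = seq(0, 1, length.out = 101),
                         tol = 1e-10) {
  V <- shape_conditioned(params, params$t0 + tau_grid * (T - params$t0), T,
                         tol = tol)
  shape_profile(tau_grid, V, T = T)
}

#' Duration-averaged oracle shape
#'
#' Builds oracle shape profiles on a log-spaced grid of termination times
#' `T in [0.5, 200]/q2` and averages them with first-order duration-density
#' weights via [shape_averaged()].
#'
#' @inheritParams shape_oracle
#' @param T_grid Termination-time grid (default 25 log-spaced points on
#'   `[0.5, 200]/q2`).
#' @param n_T Number of grid points when `T_grid` is not supplied.
#' @return A `bp_shape` with `T = "averaged"`.
#' @export
shape_oracle_averaged <- function(params,
                                  tau_grid = seq(0, 1, length.out = 51),
                                  T_grid = NULL, n_T = 25, tol = 1e-8) {
  T_grid <- T_grid %||%
    exp(seq(log(0.5 / params$q2), log(200 / params$q2), length.out = n_T))
  profiles <- purrr::map(T_grid, function(T)
    shape_oracle(params, T, tau_grid, tol = tol))
  shape_averaged(profiles, weights = "analytic", params = params)
}
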