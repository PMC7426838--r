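# Closed-form and perturbative moments of the oscillating branching process.
#
# Notation: m(t) = E[N(t)], r = s(p0 - p2), q2 = s*p2, and a = A*s/nu is the
# dimensionless strength of the first-order oscillation correction.

#' Expected population size (exact)
#'
#' The first moment of the process started from one particle at `t0`:
#' \deqn{E[N(t)] = \exp\left(-r(t-t_0) - \frac{As}{\nu}
#'   (\cos\nu t - \cos\nu t_0)\right),}
#' the solution of \eqn{\dot m = (q_2 - \epsilon(t))\,m}. For `t < t0` the
#' process has not started and 0 is returned. At criticality (r = 0) the
#' mean oscillates indefinitely about values `>= 1` (for `A > 0`) and never
#' converges.
#'
#' @param params A [bp_params()] with `n0 = 1`.
#' @param t Time(s).
#' @return Numeric vector of expectations.
#' @examples
#' p <- bp_params(s = 1, p2 = 0.5, A = 0.05, nu = pi / 4)
#' first_moment(p, c(0, 4, 8))  # 1, exp(2*A*s*4/pi), 1
#' @export
first_moment <- function(params, t) {
  check_analytic_params(params)
  a <- a_over_nu(params)
  out <- exp(-params$r * (t - params$t0) -
               a * (cos(params$nu * t) - cos(params$nu * params$t0)))
  out[t < params$t0] <- 0
  out
}

# integrate f over [lower, upper] splitting at oscillation-period boundaries
# so the adaptive rule never sees more than one period per panel; exploits
# exact periodicity of the integrand when `periodic = TRUE` (r = 0 paths)
integrate_osc <- function(f, lower, upper, nu, tol = 1e-10,
                          periodic = FALSE) {
  if (upper <= lower) return(list(value = 0, abs_error = 0))
  period <- if (nu != 0) 2 * pi / abs(nu) else Inf
  width <- upper - lower
  if (!is.finite(period) || width <= period) {
    q <- stats::integrate(f, lower, upper, abs.tol = tol, rel.tol = tol,
                          subdivisions = 400L)
    if (q$message != "OK") {
      stop("quadrature failed: ", q$message, " (abs.error = ",
           format(q$abs.error), ")")
    }
    return(list(value = q$value, abs_error = q$abs.error))
  }
  n_full <- floor(width / period)
  if (periodic) {
    q1 <- stats::integrate(f, lower, lower + period, abs.tol = tol,
                           rel.tol = tol, subdivisions = 400L)
    q2 <- stats::integrate(f, lower + n_full * period, upper,
                           abs.tol = tol, rel.tol = tol, subdivisions = 400L)
    if (q1$message != "OK" || q2$message != "OK") {
      stop("quadrature failed: ", q1$message, " / ", q2$message)
    }
    return(list(value = n_full * q1$value + q2$value,
                abs_error = n_full * q1$abs.error + q2$abs.error))
  }
  brk <- seq(lower, by = period, length.out = n_full + 1)
  brk <- c(brk, upper)
  # per-panel tolerance floored near machine precision: thousands of panels
  # must not drive the requested tolerance below what the rule can deliver
  tol_i <- max(tol / length(brk), 1e-12)
  rtol_i <- max(tol, 1e-11)
  val <- 0; err <- 0
  for (i in seq_len(length(brk) - 1)) {
    q <- tryCatch(
      stats::integrate(f, brk[i], brk[i + 1], abs.tol = tol_i,
                       rel.tol = rtol_i, subdivisions = 400L),
      error = function(e) stats::integrate(f, brk[i], brk[i + 1],
                                           abs.tol = 100 * tol_i,
                                           rel.tol = 100 * rtol_i,
                                           subdivisions = 400L))
    if (q$message != "OK") {
      stop("quadrature failed on [", brk[i], ", ", brk[i + 1], "]: ",
           q$message)
    }
    val <- val + q$value; err <- err + q$abs.error
  }
  list(value = val, abs_error = err)
}

#' Second moment of the population size (exact, by quadrature)
#'
#' Evaluates the exact second moment
#' \deqn{E[N^2(t)] = m(t)\Big[1 + 2 q_2 \int_{t_0}^{t}
#'   e^{-r(t-u) - \frac{As}{\nu}(\cos\nu t - \cos\nu u)}\,\mathrm{d}u\Big],}
#' where the integral (a convolution of the mean against itself) has no
#' closed form for `A != 0` and is computed by adaptive quadrature split at
#' oscillation-period boundaries. At criticality the integrand is periodic in
#' `u` and the full periods are summed exactly, so very large `t` (e.g.
#' `q2*t = 1e4`) costs no more than a few panels.
#'
#' @inheritParams first_moment
#' @param t A single time `>= t0`.
#' @param tol Absolute quadrature tolerance (default `1e-10`).
#' @return The expectation `E[N^2(t)]`, with attribute `"abs_error"` carrying
#'   the achieved quadrature error estimate.
#' @examples
#' p0 <- bp_params(s = 1, p2 = 0.5, A = 0, nu = pi / 4)
#' second_moment_exact(p0, 10)  # 1 + 2*q2*t = 11 at A = 0, r = 0
#' @export
second_moment_exact <- function(params, t, tol = 1e-10) {
  check_analytic_params(params)
  stopifnot(length(t) == 1)
  if (t < params$t0) return(0)
  a <- a_over_nu(params)
  nu <- params$nu
  m_t <- first_moment(params, t)
  f <- function(u) {
    exp(-params$r * (t - u) - a * (cos(nu * t) - cos(nu * u)))
  }
  q <- integrate_osc(f, params$t0, t, nu, tol = tol,
                     periodic = (params$r == 0))
  out <- m_t * (1 + 2 * params$q2 * q$value)
  attr(out, "abs_error") <- m_t * 2 * params$q2 * q$abs_error
  out
}

#' Second moment to first order in the oscillation amplitude
#'
#' The critical-point (r = 0) expansion
#' \deqn{E[N^2(t)] = 1 + 2 q_2 t + \frac{As}{\nu}\Big[1 + 2 q_2 t
#'   + \frac{2 q_2}{\nu}\sin\nu t - (1 + 4 q_2 t)\cos\nu t\Big] + O(A^2),}
#' which diverges linearly in `t` with a mildly oscillating amplitude: for
#' large `q2*t` the ratio to `1 + 2*q2*t` approaches
#' `1 - (As/nu)*(2*cos(nu*t) - 1)`. Printed only at criticality; the
#' operation refuses r != 0 rather than extrapolating.
#'
#' @inheritParams first_moment
#' @return Numeric vector of expectations.
#' @export
second_moment_first_order <- function(params, t) {
  check_analytic_params(params)
  require_critical(params)
  require_origin(params)
  q2 <- params$q2; nu <- params$nu; a <- a_over_nu(params)
  1 + 2 * q2 * t +
    a * (1 + 2 * q2 * t + (2 * q2 / nu) * sin(nu * t) -
           (1 + 4 * q2 * t) * cos(nu * t))
}

require_critical <- function(params) {
  if (abs(params$r) > 1e-12 * params$s) {
    stop("this first-order expression is available only at criticality ",
         "(r = 0); got r = ", params$r)
  }
  invisible(params)
}

require_origin <- function(params) {
  if (params$t0 != 0) {
    stop("this expression assumes initialisation at t0 = 0 (the oscillation ",
         "phase is tied to the origin); got t0 = ", params$t0)
  }
  invisible(params)
}

#' Factorial moments of the population size
#'
#' The n-th factorial moment `g_n(t0, t) = E[N(N-1)...(N-n+1)]` expanded in
#' powers of the oscillation amplitude, `g_n = g_n^{(0)} + A g_n^{(1)} +
#' O(A^2)`.
#'
#' `factorial_moment_g0()` is the amplitude-free (standard branching) term
#' \deqn{g_n^{(0)} = n!\, e^{-r\Delta} \left(\frac{q_2}{r}
#'   (1 - e^{-r\Delta})\right)^{n-1}, \qquad \Delta = t - t_0,}
#' with the critical limit `(q2*Delta)^{n-1}` taken analytically (via
#' `expm1`, not small-r substitution, to avoid catastrophic cancellation).
#'
#' `factorial_moment_g1()` is the first-order coefficient
#' \deqn{g_n^{(1)} = g_n^{(0)}\, s \int_0^{\Delta} \sin(\nu(t - t'))
#'   \left[1 + (n-1)\frac{e^{-rt'} - e^{-r\Delta}}{1 - e^{-r\Delta}}\right]
#'   \mathrm{d}t',}
#' computed by adaptive quadrature; at r = 0 the bracket's fraction is
#' replaced by its limit `1 - t'/Delta`. Note `g_n^{(1)}` itself does not
#' contain `A`; the amplitude enters as the prefactor in the expansion.
#'
#' @param params A [bp_params()] with `n0 = 1`.
#' @param n Moment order, positive integer.
#' @param t End time.
#' @param t0 Initial time (defaults to `params$t0`).
#' @param tol Absolute quadrature tolerance for `g1`.
#' @return The factorial-moment term (numeric scalar).
#' @examples
#' p <- bp_params(s = 1, p2 = 0.5, A = 0, nu = pi / 4)
#' factorial_moment_g0(p, n = 3, t = 4)  # 3! * (q2*t)^2 = 24 at r = 0
#' @export
factorial_moment_g0 <- function(params, n, t, t0 = params$t0) {
  check_analytic_params(params)
  stopifnot(n >= 1, n == round(n))
  delta <- t - t0
  if (delta < 0) return(0)
  r <- params$r
  # (q2/r)(1 - e^{-r d}) = q2 * d * phi(r d),  phi(x) = -expm1(-x)/x, phi(0)=1
  x <- r * delta
  phi <- if (abs(x) < 1e-12) 1 else -expm1(-x) / x
  factorial(n) * exp(-x) * (params$q2 * delta * phi)^(n - 1)
}

#' @rdname factorial_moment_g0
#' @export
factorial_moment_g1 <- function(params, n, t, t0 = params$t0, tol = 1e-10) {
  check_analytic_params(params)
  stopifnot(n >= 1, n == round(n))
  delta <- t - t0
  if (delta <= 0) return(0)
  r <- params$r; nu <- params$nu; s <- params$s
  x <- r * delta
  w <- if (abs(x) < 1e-8) {
    function(tp) 1 - tp / delta            # r -> 0 limit of the bracket term
  } else {
    function(tp) (expm1(-r * tp) - expm1(-x)) / (-expm1(-x))
  }
  f <- function(tp) sin(nu * (t - tp)) * (1 + (n - 1) * w(tp))
  q <- integrate_osc(f, 0, delta, nu, tol = tol)
  factorial_moment_g0(params, n, t, t0) * s * q$value
}

# Stirling numbers of the second kind, S(n, 0..n), by the standard recurrence
stirling2_row <- function(n) {
  row <- c(1)                              # S(0,0)
  if (n == 0) return(row)
  for (m in seq_len(n)) {
    prev <- c(0, row, 0)
    row <- numeric(m + 1)
    for (k in seq_len(m + 1)) {
      # S(m,k) = k*S(m-1,k) + S(m-1,k-1), with k running 0..m
      kk <- k - 1
      row[k] <- kk * prev[k + 1] + prev[k]
    }
  }
  row
}

#' Raw moments from the factorial-moment expansion
#'
#' Converts factorial moments to raw moments through Stirling numbers of the
#' second kind,
#' \deqn{E[N^n(t)] = \sum_{\ell=0}^{n} {n \brace \ell} g_\ell(t_0, t),}
#' with each `g_l` truncated at the requested order in the amplitude `A`
#' (`max_order_in_A = 0` or `1`).
#'
#' @inheritParams factorial_moment_g0
#' @param max_order_in_A Truncation order of the amplitude expansion, 0 or 1.
#' @return The approximate raw moment `E[N^n(t)]`.
#' @export
moment_from_factorial <- function(params, n, t, t0 = params$t0,
                                  max_order_in_A = 1, tol = 1e-10) {
  check_analytic_params(params)
  stopifnot(n >= 1, n == round(n))
  if (!max_order_in_A %in% c(0, 1)) {
    stop("`max_order_in_A` must be 0 or 1; higher orders are not available")
  }
  st <- stirling2_row(n)                   # S(n, 0..n); S(n,0) = 0 for n >= 1
  total <- 0
  for (l in seq_len(n)) {
    g <- factorial_moment_g0(params, l, t, t0)
    if (max_order_in_A == 1 && params$A != 0) {
      g <- g + params$A * factorial_moment_g1(params, l, t, t0, tol = tol)
    }
    total <- total + st[l + 1] * g
  }
  total
}

#' Two-time covariance of the population size (exact, by quadrature)
#'
#' The autocovariance
#' \deqn{\mathrm{Cov}(N(t_1), N(t_2)) = -m(t_1)\,m(t_2) +
#'   m(t_{\max})\Big[1 + 2 q_2 \int_{t_0}^{t_{\min}}
#'   e^{-r(t_{\min}-u) - \frac{As}{\nu}(\cos\nu t_{\min} - \cos\nu u)}
#'   \mathrm{d}u\Big],}
#' which follows from the branching (Markov) property
#' `Cov = (m(tmax)/m(tmin)) * (E[N^2(tmin)] - m(tmin)^2)` together with the
#' exact first and second moments. It is symmetric in `(t1, t2)` and vanishes
#' whenever `min(t1, t2) = t0` (the initial count is deterministic). At
#' `A = 0` and `t1 = t2 = t` it reduces to the standard branching result
#' `(2*q2/r + 1)*(exp(-r*t) - exp(-2*r*t))`.
#'
#' @inheritParams first_moment
#' @param t1,t2 Times `>= t0`.
#' @param tol Absolute quadrature tolerance.
#' @return Covariance value with attribute `"abs_error"`.
#' @export
covariance <- function(params, t1, t2, tol = 1e-10) {
  check_analytic_params(params)
  stopifnot(length(t1) == 1, length(t2) == 1)
  if (t1 < params$t0 || t2 < params$t0) stop("t1, t2 must be >= t0")
  tmin <- min(t1, t2); tmax <- max(t1, t2)
  a <- a_over_nu(params); nu <- params$nu
  f <- function(u) {
    exp(-params$r * (tmin - u) - a * (cos(nu * tmin) - cos(nu * u)))
  }
  q <- integrate_osc(f, params$t0, tmin, nu, tol = tol,
                     periodic = (params$r == 0))
  m1 <- first_moment(params, t1)
  m2 <- first_moment(params, t2)
  m_max <- first_moment(params, tmax)
  out <- m_max * (1 + 2 * params$q2 * q$value) - m1 * m2
  attr(out, "abs_error") <- m_max * 2 * params$q2 * q$abs_error
  out
}

#' Moment curves on a time grid
#'
#' Convenience wrapper evaluating a moment of chosen order and method on a
#' grid, returned in tidy form for plotting and export. Methods: `"exact"`
#' (orders 1 and 2 only), `"first_order"` (amplitude expansion truncated at
#' `O(A)`), `"zeroth_order"` (`A = 0` factorial-moment formulas).
#'
#' @inheritParams first_moment
#' @param times Time grid.
#' @param order Moment order `n >= 1`.
#' @param method One of `"exact"`, `"first_order"`, `"zeroth_order"`.
#' @param tol Quadrature tolerance where applicable.
#' @return A tibble with columns `time`, `st` (dimensionless time), `value`,
#'   `order`, `method`. If `|A|*s/nu > 0.5` a warning flags that the
#'   first-order expansion is outside its comfort zone.
#' @export
moment_series <- function(params, times, order = 1,
                          method = c("exact", "first_order", "zeroth_order"),
                          tol = 1e-10) {
  check_analytic_params(params)
  method <- match.arg(method)
  if (method == "first_order" && abs(a_over_nu(params)) > 0.5) {
    warning("|A|*s/nu = ", format(abs(a_over_nu(params))),
            " > 0.5: the first-order amplitude expansion may be inaccurate")
  }
  values <- switch(
    method,
    exact = {
      if (order == 1) {
        first_moment(params, times)
      } else if (order == 2) {
        vapply(times, function(t) as.numeric(second_moment_exact(params, t,
                                                                 tol)),
               numeric(1))
      } else {
        stop("exact moments are available for orders 1 and 2 only; use ",
             "method = 'first_order' for higher orders")
      }
    },
    first_order = vapply(
      times, function(t) moment_from_factorial(params, order, t,
                                               max_order_in_A = 1, tol = tol),
      numeric(1)),
    zeroth_order = vapply(
      times, function(t) moment_from_factorial(params, order, t,
                                               max_order_in_A = 0),
      numeric(1))
  )
  tibble::tibble(time = times, st = params$s * times, value = values,
                 order = order, method = method)
}
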