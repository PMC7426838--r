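# Survival probability, avalanche-duration density, ultimate survival and
# duration-averaged avalanche shapes.

#' Survival probability at criticality, first order in the amplitude
#'
#' Probability that the avalanche is still alive at time `t`, for the
#' critical process (r = 0) started from one particle at `t0 = 0`:
#' \deqn{P_s(0,t) = \frac{1}{1+q_2 t} + \frac{As}{\nu}\left(
#'   \frac{1}{1+q_2 t} - \frac{\cos\nu t + \frac{q_2}{\nu}\sin\nu t}
#'   {(1+q_2 t)^2}\right) + O(A^2).}
#' The amplitude-free term is the classical critical-branching survival; the
#' correction has the sign of `A` at all `t > 0`: an initial suppression of
#' extinction (`A > 0`) lifts the survival probability at all later times.
#' Being a truncated expansion the value may exit `[0, 1]` by `O(A^2)`; set
#' `clip = TRUE` for presentation only.
#'
#' @param params A [bp_params()] with r = 0, `t0 = 0`, `n0 = 1`.
#' @param t Time(s) `>= 0`.
#' @param clip Clip the result into `[0, 1]` (default `FALSE`).
#' @return Numeric vector of probabilities (to first order).
#' @examples
#' p <- bp_params(s = 1, p2 = 0.5, A = 0.05, nu = pi / 4)
#' survival_first_order(p, c(0, 2, 10))
#' @export
survival_first_order <- function(params, t, clip = FALSE) {
  check_analytic_params(params)
  require_critical(params)
  require_origin(params)
  q2 <- params$q2; nu <- params$nu; a <- a_over_nu(params)
  base <- 1 / (1 + q2 * t)
  out <- base + a * (base - (cos(nu * t) + (q2 / nu) * sin(nu * t)) /
                       (1 + q2 * t)^2)
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' Avalanche-duration density at criticality, first order in the amplitude
#'
#' Density of the termination time `T` (the time of death of an avalanche
#' started at `t = 0`), `P_T(t) = -dP_s/dt`:
#' \deqn{P_T(t) = \frac{q_2}{(1+q_2 t)^2}\left(1+\frac{As}{\nu}\right) +
#'   \frac{As}{\nu}\left(\frac{-\nu\sin\nu t + q_2\cos\nu t}{(1+q_2 t)^2}
#'   - 2 q_2 \frac{\cos\nu t + \frac{q_2}{\nu}\sin\nu t}{(1+q_2 t)^3}\right)
#'   + O(A^2).}
#' The envelope keeps the classical `t^{-2}` duration power law; the
#' oscillations are superimposed on it and average out under log-binning.
#'
#' @inheritParams survival_first_order
#' @param t Time(s) `> 0`.
#' @return Numeric vector of density values (to first order).
#' @export
duration_density <- function(params, t) {
  check_analytic_params(params)
  require_critical(params)
  require_origin(params)
  q2 <- params$q2; nu <- params$nu; a <- a_over_nu(params)
  d <- 1 + q2 * t
  q2 / d^2 * (1 + a) +
    a * ((-nu * sin(nu * t) + q2 * cos(nu * t)) / d^2 -
           2 * q2 * (cos(nu * t) + (q2 / nu) * sin(nu * t)) / d^3)
}

#' Ultimate survival probability
#'
#' The `t -> Inf` limit of the survival probability, to first order in the
#' amplitude. For the subcritical process (r > 0) the limit is 0 and the
#' value carries the large-`t` envelope
#' \deqn{P_s(0,t) \simeq \frac{e^{-rt}}{1+q_2/r}\Big(1 +
#'   \frac{As}{\nu}(1-\cos\nu t)\Big)}
#' as the attribute `"envelope"` (a function of `t`). For the supercritical
#' process (r < 0) the limit is positive,
#' \deqn{\lim_{t\to\infty} P_s = -\frac{r}{q_2}\Big(1 +
#'   \frac{As\nu}{r^2+\nu^2}\Big) + O(A^2),}
#' understood as the analytic continuation of the subcritical result. The
#' effect of the oscillations is most pronounced at the tied frequencies
#' `nu = r` (minimum, `-r/q2 - As/(2 q2)`) and `nu = -r` (maximum,
#' `-r/q2 + As/(2 q2)`); `tie_nu` re-evaluates with `nu` pinned to `r` or
#' `-r` before taking the limit, which is how the non-vanishing
#' r -> 0^- value (e.g. `1/4` at `As = q2/2`) arises. The order of limits
#' matters: here `t -> Inf` is always taken at fixed `r`; at r = 0 itself
#' ultimate survival is 0 (the critical survival decays as `1/(q2 t)`) and
#' the operation refuses with an informative error.
#'
#' @param params A [bp_params()] with r != 0, `n0 = 1`.
#' @param tie_nu `NULL` (use `params$nu`), `"r"` or `"-r"`: evaluate the
#'   analytic continuation with the oscillation frequency tied to the mass.
#' @return The limiting probability (0 for r > 0), with attributes
#'   `"branch"` (`"subcritical"`/`"supercritical"`) and, for r > 0,
#'   `"envelope"`.
#' @examples
#' p <- bp_params_rq(r = -0.01, q2 = 0.5, A = 0, nu = pi / 4)
#' ultimate_survival(p)  # -r/q2 = 0.02
#' @export
ultimate_survival <- function(params, tie_nu = NULL) {
  check_analytic_params(params)
  r <- params$r; q2 <- params$q2; s <- params$s; A <- params$A
  if (r == 0) {
    stop("critical point: ultimate survival is 0, approached as the 1/(q2 t) ",
         "decay of survival_first_order(); see also the r -> 0^- limit via ",
         "`tie_nu`")
  }
  nu <- params$nu
  if (!is.null(tie_nu)) {
    nu <- switch(match.arg(tie_nu, c("r", "-r")), "r" = r, "-r" = -r)
  }
  if (r > 0) {
    a <- if (A == 0) 0 else A * s / nu
    env <- function(t) exp(-r * t) / (1 + q2 / r) * (1 + a * (1 - cos(nu * t)))
    out <- 0
    attr(out, "branch") <- "subcritical"
    attr(out, "envelope") <- env
    return(out)
  }
  out <- -r / q2 * (1 + A * s * nu / (r^2 + nu^2))
  attr(out, "branch") <- "supercritical"
  attr(out, "tie_nu") <- if (is.null(tie_nu)) NA_character_ else tie_nu
  out
}

#' Survival curves on a time grid
#'
#' Evaluates the survival probability on a grid either from the first-order
#' closed form ([survival_first_order()], r = 0 only) or from the exact
#' generating-function oracle ([survival_exact()], any `r`).
#'
#' @inheritParams survival_first_order
#' @param times Time grid.
#' @param method `"first_order"` or `"gf_exact"`.
#' @param tol Solver tolerance for the oracle method.
#' @return A tibble with columns `time`, `st`, `p_s`, `method`.
#' @export
survival_curve <- function(params, times,
                           method = c("first_order", "gf_exact"),
                           clip = FALSE, tol = 1e-10) {
  method <- match.arg(method)
  p_s <- switch(method,
    first_order = survival_first_order(params, times, clip = clip),
    gf_exact = survival_exact(params, times, tol = tol)
  )
  tibble::tibble(time = times, st = params$s * times, p_s = p_s,
                 method = method)
}

#' Construct an area-normalised avalanche-shape profile
#'
#' An avalanche shape is the expected population `V(t, T)` conditioned on
#' termination at `T`, sampled on the rescaled time `tau = t/T` in `[0, 1]`
#' and normalised so that its trapezoidal area over `tau` is 1.
#'
#' @param tau Grid on `[0, 1]`, increasing.
#' @param value Raw (unnormalised) profile values, `>= 0`.
#' @param T Termination time the profile is conditioned on, or the string
#'   `"averaged"`.
#' @param se Optional standard errors of the raw values (same length);
#'   rescaled by the same normalisation constant.
#' @param n Optional number of avalanches per grid point.
#' @return A tibble of class `bp_shape` with columns `tau`, `value`
#'   (area-normalised), `se`, `n`, and attributes `T` and `raw` (the
#'   unnormalised values).
#' @export
shape_profile <- function(tau, value, T, se = NULL, n = NULL) {
  stopifnot(length(tau) == length(value), !is.unsorted(tau),
            all(tau >= 0), all(tau <= 1))
  if (any(value < 0)) stop("shape values must be non-negative")
  area <- trapz(tau, value)
  if (area <= 0) stop("degenerate profile: zero area")
  out <- tibble::tibble(
    tau = tau,
    value = value / area,
    se = if (is.null(se)) NA_real_ else se / area,
    n = if (is.null(n)) NA_integer_ else n
  )
  attr(out, "T") <- T
  attr(out, "raw") <- value
  class(out) <- c("bp_shape", class(out))
  out
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Average avalanche shapes over the termination time
#'
#' Computes the duration-averaged, duration-rescaled shape
#' \deqn{\bar V(\tau) = \frac{\int_0^\infty P_T(T)\, V(\tau T, T)\,
#'   \mathrm{d}T}{\int_0^1\int_0^\infty P_T(T)\, V(\tau T, T)\,
#'   \mathrm{d}T\,\mathrm{d}\tau},}
#' from a set of shape profiles conditioned on different `T` and sharing one
#' `tau` grid. With `weights = "analytic"` the `T` integral is evaluated by
#' the trapezoidal rule over the profiles' `T` values (a log-spaced grid is
#' recommended, e.g. `T in [0.5, 200]/q2`) with the first-order duration
#' density [duration_density()] as weight; with `weights = "empirical"` the
#' profiles' avalanche counts are used instead (durations drawn from the
#' process already carry the `P_T` weighting). The raw (unnormalised)
#' profile values stored by [shape_profile()] enter the average; the result
#' is area-normalised at the end. Averaging over `T` washes the
#' oscillation-locked humps out: as criticality is approached the averaged
#' shape tends to the universal parabola-like profile.
#'
#' @param profiles List of `bp_shape` objects with numeric `T` attributes,
#'   all on the same `tau` grid.
#' @param weights `"analytic"` (requires `params`, r = 0) or
#'   `"empirical"` (requires counts in the profiles).
#' @param params A [bp_params()], needed for analytic weights.
#' @return A `bp_shape` with attribute `T = "averaged"`.
#' @export
shape_averaged <- function(profiles, weights = c("analytic", "empirical"),
                           params = NULL) {
  weights <- match.arg(weights)
  if (length(profiles) == 0) stop("no profiles supplied")
  tau <- profiles[[1]]$tau
  ok <- purrr::map_lgl(profiles, function(p) inherits(p, "bp_shape") &&
                         length(p$tau) == length(tau) && all(p$tau == tau))
  if (!all(ok)) stop("all profiles must be bp_shape objects on one tau grid")
  Ts <- purrr::map_dbl(profiles, function(p) as.numeric(attr(p, "T")))
  if (anyNA(Ts)) stop("profiles must carry numeric termination times")
  raw <- do.call(rbind, purrr::map(profiles, function(p) attr(p, "raw")))
  if (length(profiles) == 1) {
    return(shape_profile(tau, raw[1, ], T = "averaged"))
  }
  if (weights == "analytic") {
    if (is.null(params)) stop("analytic weights require `params`")
    ord <- order(Ts)
    Ts <- Ts[ord]; raw <- raw[ord, , drop = FALSE]
    pT <- duration_density(params, Ts)
    # trapezoidal weights on the (possibly log-spaced) T grid
    dT <- diff(Ts)
    wT <- c(dT[1] / 2, (dT[-1] + dT[-length(dT)]) / 2,
            dT[length(dT)] / 2)
    w <- pT * wT
  } else {
    counts <- purrr::map_dbl(profiles, function(p) sum(p$n[1], na.rm = TRUE))
    if (any(is.na(counts)) || sum(counts) == 0) {
      stop("empirical weights require avalanche counts in the profiles")
    }
    w <- counts
  }
  vbar <- colSums(raw * w) / sum(w)
  shape_profile(tau, vbar, T = "averaged")
}
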