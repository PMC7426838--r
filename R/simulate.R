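#' Simulate one avalanche of the oscillating branching process
#'
#' Draws a single realisation of the binary branching process with
#' time-dependent extinction rate `s*(p0 - A*sin(nu*t))`, from `n0` particles
#' at `t0` until either absorption at `N = 0` or the simulation `horizon`.
#'
#' The sampler is exact: it uses Ogata/Lewis thinning with the global
#' per-particle proposal rate `s*(1 + |A|)`, which bounds the true
#' per-particle event rate `s*(1 - A*sin(nu*t))` at all times. A proposal at
#' time `t` is accepted with probability `(1 - A*sin(nu*t))/(1 + |A|)` and
#' then classified as a branching with probability `p2/(1 - A*sin(nu*t))`,
#' an extinction otherwise. No time discretisation is involved.
#'
#' @param params A [bp_params()] object.
#' @param horizon Absolute end time of the simulation; trajectories still
#'   alive at `horizon` are flagged censored. Defaults to ten oscillation
#'   periods past `t0` (or `20/s` when `A = 0` and the period is undefined).
#' @param seed Integer seed (mandatory: no silent nondeterminism). The same
#'   seed and parameters reproduce the event log bitwise.
#' @param max_pop Population-explosion guard: the simulation aborts with an
#'   error if `N` exceeds this (default `1e6`). Relevant only for
#'   supercritical misuse (r < 0).
#' @return A `bp_eventlog`: a list with `events` (tibble with columns `time`,
#'   `kind` (`"branch"`/`"extinct"`), `n_after`), `params`, `seed`,
#'   `horizon`, and `terminated` (`TRUE` if absorbed before `horizon`).
#' @examples
#' p <- bp_params(s = 1, p2 = 0.5, A = 0.05, nu = pi / 4)
#' log <- simulate_avalanche(p, seed = 1)
#' as_avalanche_record(log)
#' @export
simulate_avalanche <- function(params, horizon = NULL, seed,
                               max_pop = 1e6) {
  stopifnot(inherits(params, "bp_params"))
  if (missing(seed)) stop("`seed` is required for stochastic operations")
  horizon <- horizon %||% default_horizon(params)
  if (horizon <= params$t0) stop("`horizon` must exceed t0")
  set.seed(seed)
  raw <- cpp_simulate_log(params$s, params$p2, params$A, params$nu,
                          params$t0, params$n0, horizon, as.integer(max_pop))
  events <- tibble::tibble(
    time = raw$time,
    kind = ifelse(raw$kind == 1L, "branch", "extinct"),
    n_after = raw$n_after
  )
  structure(
    list(events = events, params = params, seed = as.integer(seed),
         horizon = horizon, terminated = !raw$censored),
    class = "bp_eventlog"
  )
}

default_horizon <- function(params) {
  if (params$A != 0 && params$nu != 0) {
    params$t0 + 10 * 2 * pi / abs(params$nu)
  } else {
    params$t0 + 20 / params$s
  }
}

#' @export
print.bp_eventlog <- function(x, ...) {
  cat(sprintf("<bp_eventlog>  %d events, %s (seed %d)\n",
              nrow(x$events),
              if (x$terminated) "terminated" else "censored at horizon",
              x$seed))
  print(x$events, n = 6)
  invisible(x)
}

#' Summarise an event log into an avalanche record
#'
#' Reduces one realisation to the quantities the avalanche statistics are
#' built from: the termination time `T` (time of the event that set `N` to 0,
#' measured from `t0`), the size `S` (total number of particles that ever
#' existed, `n0` + number of branching events — the total-progeny convention
#' under which the critical size exponent is 3/2), the population peak, and a
#' censoring flag. For a censored log `T` is `NA`.
#'
#' @param log A `bp_eventlog` from [simulate_avalanche()].
#' @return A one-row tibble with columns `T`, `S`, `peak`, `censored`.
#' @export
as_avalanche_record <- function(log) {
  stopifnot(inherits(log, "bp_eventlog"))
  ev <- log$events
  n0 <- log$params$n0
  branches <- sum(ev$kind == "branch")
  tibble::tibble(
    T = if (log$terminated) ev$time[nrow(ev)] - log$params$t0 else NA_real_,
    S = n0 + branches,
    peak = max(c(n0, ev$n_after)),
    censored = !log$terminated
  )
}

#' Evaluate the population step function N(t) on a time grid
#'
#' `N(t)` is right-continuous: at an event time the post-event value is
#' returned. Grid points before the first event give `n0`; points after
#' absorption give 0.
#'
#' @param log A `bp_eventlog`.
#' @param grid Numeric vector of absolute times within `[t0, horizon]`.
#' @return A tibble with columns `time` and `n`.
#' @export
sample_profile <- function(log, grid) {
  stopifnot(inherits(log, "bp_eventlog"))
  if (any(grid < log$params$t0) || any(grid > log$horizon)) {
    stop("`grid` must lie within [t0, horizon]")
  }
  ord <- order(grid)
  n <- numeric(length(grid))
  ev <- log$events
  n[ord] <- step_eval(ev$time, ev$n_after, log$params$n0, grid[ord])
  tibble::tibble(time = grid, n = n)
}

# step evaluation for sorted queries; right-continuous, or left limits N(t-)
step_eval <- function(times, n_after, n0, queries, left_limit = FALSE) {
  vals <- c(n0, n_after)
  idx <- findInterval(queries, times, left.open = left_limit) + 1L
  vals[idx]
}

#' Write or read an event log as tab-separated text
#'
#' The TSV carries a `#`-prefixed header with the parameters and seed so a
#' log round-trips exactly (floats at 17 significant digits).
#'
#' @param log A `bp_eventlog`.
#' @param path File path.
#' @return `write_eventlog()` returns `path` invisibly; `read_eventlog()`
#'   returns a `bp_eventlog`.
#' @export
write_eventlog <- function(log, path) {
  stopifnot(inherits(log, "bp_eventlog"))
  p <- log$params
  hdr <- sprintf(
    "# s=%.17g p2=%.17g A=%.17g nu=%.17g t0=%.17g n0=%d seed=%d horizon=%.17g terminated=%d",
    p$s, p$p2, p$A, p$nu, p$t0, p$n0, log$seed, log$horizon,
    as.integer(log$terminated))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time\tkind\tn_after", con)
  ev <- log$events
  if (nrow(ev) > 0) {
    writeLines(sprintf("%.17g\t%s\t%d", ev$time, ev$kind, ev$n_after), con)
  }
  invisible(path)
}

#' @rdname write_eventlog
#' @export
read_eventlog <- function(path) {
  lines <- readLines(path)
  hdr <- sub("^# ", "", lines[1])
  kv <- strsplit(strsplit(hdr, " ")[[1]], "=")
  vals <- stats::setNames(
    vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
    vapply(kv, `[`, character(1), 1))
  params <- bp_params(s = vals[["s"]], p2 = vals[["p2"]], A = vals[["A"]],
                      nu = vals[["nu"]], t0 = vals[["t0"]],
                      n0 = as.integer(vals[["n0"]]))
  body <- lines[-(1:2)]
  if (length(body) > 0) {
    parts <- strsplit(body, "\t")
    events <- tibble::tibble(
      time = as.numeric(vapply(parts, `[`, character(1), 1)),
      kind = vapply(parts, `[`, character(1), 2),
      n_after = as.integer(vapply(parts, `[`, character(1), 3))
    )
  } else {
    events <- tibble::tibble(time = numeric(), kind = character(),
                             n_after = integer())
  }
  structure(
    list(events = events, params = params, seed = as.integer(vals[["seed"]]),
         horizon = vals[["horizon"]],
         terminated = as.logical(vals[["terminated"]])),
    class = "bp_eventlog"
  )
}
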