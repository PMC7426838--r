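# oscbranch

Branching processes with oscillating extinction rates — a minimal stochastic
model of neuronal avalanches co-existing with brain-wave-like oscillations.

Multielectrode recordings of cortical activity show avalanches with
apparently scale-free size and duration statistics (the fingerprint of a
critical branching process) *and* oscillations that visibly modulate the
avalanche's temporal profile. `oscbranch` implements the continuous-time
binary branching process in which each particle branches ($B \to 2B$) at
constant rate $q_2 = s p_2$ and goes extinct at the sinusoidally modulated
rate

$$\epsilon(t) = s\,(p_0 - A \sin \nu t), \qquad p_0 = 1 - p_2,
\quad |A| \le p_0,$$

with mass $r = s(p_0 - p_2)$ controlling criticality ($r = 0$ critical).
The package is aimed at researchers in computational neuroscience and
stochastic processes who want to simulate this model exactly, evaluate its
closed-form and first-order perturbative observables, and reproduce its
avalanche statistics.

It provides, as tidy, pipe-friendly functions returning tibbles:

* **Exact simulation** — `simulate_avalanche()`, `run_ensemble()`:
  event-driven Ogata/Lewis thinning (no time discretisation), with a
  compiled core that draws 10⁶ critical avalanches to $st = 600$ in under
  a minute; bitwise-reproducible from a seed.
* **Analytics** — `first_moment()`, `second_moment_exact()`,
  `covariance()` (exact, quadrature where needed);
  `factorial_moment_g0()/g1()`, `moment_from_factorial()`,
  `second_moment_first_order()`, `survival_first_order()`,
  `duration_density()`, `ultimate_survival()` (first order in the
  amplitude $A$).
* **A non-perturbative oracle** — `gf_solve()`, `survival_exact()`,
  `shape_conditioned()`: the probability generating function from a
  backward Riccati-type ODE with exact variational derivatives, giving
  exact survival and the termination-time conditioned avalanche shape
  $V(t,T) = 1 + q\,G''(q)/G'(q)$ at any amplitude.
* **Estimators** — `estimate_shape()` (the $sT \pm 0.2$ conditioning
  protocol), `shape_averaged()` (duration-averaged universal profile),
  `fit_power_law()` (maximum-likelihood tail exponents for durations and
  sizes, with a crossover-aware shifted power-law family and bootstrap
  CIs), plus `tidy()`/`glance()` accessors and `autoplot()` methods.
* **A thin CLI** — `inst/cli/oscbranch` with subcommands `simulate`,
  `moments`, `covariance`, `survival`, `oracle`, `shape`,
  `shape-average`, `fit`, writing TSV outputs with provenance sidecars.

## Worked example

The critical process at the canonical parameters ($s = 1$, $p_2 = 0.5$,
$A = 0.05$, $\nu/s = \pi/4$):

```r
library(oscbranch)

p <- bp_params(s = 1, p2 = 0.5, A = 0.05, nu = pi / 4)
first_moment(p, 4)                      # 1.135785
as.numeric(second_moment_exact(p, 8))   # 8.514185
survival_first_order(p, 10)             # 0.1761512
survival_exact(p, 10)                   # 0.1762819 (oracle, exact in A)
```

At $st = 4$ (half an oscillation period) the mean population is 13.6 %
*above* the constant-rate critical value 1: the early suppression of
extinction leaves a permanent positive imprint, although the extinction
rate is unchanged on average. The first-order survival curve agrees with
the exact oracle value to $O(A^2) \sim 10^{-4}$.

Avalanche statistics from a 10⁵-run ensemble:

```r
ens <- run_ensemble(p, n_runs = 1e5, horizon = 600, seed = 1)
glance(ens)
#> # A tibble: 1 × 6
#>   n_runs n_censored mean_T mean_S  max_S max_peak
#>    <dbl>      <int>  <dbl>  <dbl>  <dbl>    <dbl>
#> 1 100000        356   9.98   314. 311500     2822

fit_power_law(ens$records, "duration", fit_range = c(5, 500))
#> <bp_powerlaw_fit>  duration exponent 1.9259 [1.8970, 1.9503] (continuous truncated MLE, fitted crossover)
#>   n = 30584 in fit range [5, 500] (of 99644 uncensored)

fit_power_law(ens$records, "size", fit_range = c(10, 1e4))
#> <bp_powerlaw_fit>  size exponent 1.5025 [1.4930, 1.5099] (discrete truncated MLE, fitted crossover)
#>   n = 19232 in fit range [10, 10000] (of 99644 uncensored)
```

The duration exponent estimates the critical $t^{-2}$ law and the size
exponent the total-progeny $S^{-3/2}$ law; both survive the small
oscillation, whose ripples average out under binning. Shapes conditioned
on the termination time show the oscillation instead:

```r
ens16 <- run_ensemble(p, n_runs = 2e5, horizon = 16.5, seed = 2,
                      shape_T = 16, shape_window = 0.2)
est <- estimate_shape(ens16)          # empirical, area-normalised
orc <- shape_oracle(p, T = 16)        # exact conditional shape
autoplot(est, params = p)
```

See `vignettes/oscillating-avalanches.Rmd` for the model, the numerical
choices, the estimator design (including why the power-law fits carry a
crossover parameter), and known limitations.

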