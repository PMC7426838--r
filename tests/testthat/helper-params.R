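# shared parameter sets: the critical oscillating process at the amplitudes
# and frequency used throughout (nu/s = pi/4)
crit_params <- function(A = 0.05, s = 1, nu = pi / 4) {
  bp_params(s = s, p2 = 0.5, A = A, nu = nu)
}

# subcritical set with r/s = 0.01 (q2/s = (1 - r/s)/2 = 0.495)
subcrit_params <- function(A = 0, s = 1, nu = pi / 4) {
  bp_params(s = s, p2 = 0.495, A = A, nu = nu)
}

expect_within_3se <- function(est, truth, se, slack = 0) {
  expect_true(all(abs(est - truth) <= 3 * se + slack),
              label = sprintf("max |est - truth| = %.4g vs 3*SE + slack = %.4g",
                              max(abs(est - truth)),
                              max(3 * se + slack)))
}
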