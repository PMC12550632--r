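# Shared fixtures, all built in code.

# Default assay protocol: 2 min gravity interval, then a 4 pN/s ramp to
# 480 pN (just under the 3000 rpm ceiling) held for `hold` seconds.
assay_protocol <- function(hold = 420) {
  design_ramp(4, f_max = 480, t_start = 120, hold_duration = hold)
}

# Noiseless stretched-exponential curve in the detachment-curve schema.
se_curve <- function(g, tau, beta, times = seq(0, 300, by = 0.5)) {
  data.frame(time_s = times, fraction_bound = stretched_exp(times, g, tau, beta))
}

# Count trace with constant-rate exponential decay of true counts (no
# detection noise), for detachment-module arithmetic tests.
decay_trace <- function(n0 = 200, rate = 0, times = seq(0, 240, by = 0.25)) {
  count_trace(times, round(n0 * exp(-rate * times)))
}

# Bell-hazard closed forms for a single bond under a linear ramp F = r t.
bell_ramp_cdf <- function(f, k0, f_beta, rate) {
  1 - exp(-(k0 * f_beta / rate) * (exp(f / f_beta) - 1))
}
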