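# Synthetic trace builders used across test files.

# Wrap two raw series into an hdc_trace (internal constructor: tests need
# traces that never came from the simulator).
make_trace <- function(x_human, x_vp, dt = 0.01, metronome_cutoff = 0) {
  n <- length(x_human)
  hdclamp:::new_trace(seq(0, by = dt, length.out = n), x_human, x_vp,
                      dt, metronome_cutoff)
}

# Sinusoidal dyad with fixed relative phase `phi` (human leads) and
# per-channel amplitudes.
sine_trace <- function(phi = 0, amp_h = 1, amp_vp = 1, freq = 1,
                       duration = 20, dt = 0.01, metronome_cutoff = 3) {
  t <- seq(0, duration, by = dt)
  make_trace(amp_h * cos(2 * pi * freq * t + phi),
             amp_vp * cos(2 * pi * freq * t),
             dt, metronome_cutoff)
}

# A profile list with directly controllable response parameters.
test_profile <- function(age = 12, motor_gain = 1, motor_noise_sd = 1,
                         compliance = 1, attribution_intercept = 2,
                         attribution_age_slope = 0, humanness_intercept = 0,
                         humanness_age_slope = 0) {
  list(participant_id = "T001", group = "TD", age = age,
       motor_gain = motor_gain, motor_noise_sd = motor_noise_sd,
       compliance = compliance,
       attribution_intercept = attribution_intercept,
       attribution_age_slope = attribution_age_slope,
       humanness_intercept = humanness_intercept,
       humanness_age_slope = humanness_age_slope)
}

# Short-trial config keeping simulation-heavy tests fast.
fast_config <- function(duration_s = 8, ...) {
  sim_config(duration_s = duration_s, ...)
}

# Late-window circular mean of a dyad's relative phase.
late_phase <- function(trace, frac = 0.25) {
  rp <- relative_phase(trace)
  n <- length(rp$relative_phase)
  keep <- seq.int(floor(n * (1 - frac)) + 1L, n)
  Arg(mean(exp(1i * rp$relative_phase[keep])))
}
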