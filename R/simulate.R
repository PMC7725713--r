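# Dyad simulation: the offline counterpart of the real-time clamp loop.

new_trace <- function(t, x_human, x_vp, dt, metronome_cutoff,
                      params = list(), seed = NULL) {
  tr <- tibble(t = t, x_human = x_human, x_vp = x_vp)
  attr(tr, "dt") <- as.numeric(dt)
  attr(tr, "metronome_cutoff") <- as.numeric(metronome_cutoff)
  attr(tr, "params") <- params
  attr(tr, "seed") <- seed
  class(tr) <- c("hdc_trace", class(tr))
  validate_trace(tr)
}

validate_trace <- function(tr) {
  if (nrow(tr) < 2L) stop_hdc("a trace needs at least 2 samples")
  dt <- attr(tr, "dt")
  mc <- attr(tr, "metronome_cutoff")
  check_number(dt, "dt", lower = 1e-12)
  check_number(mc, "metronome_cutoff", lower = 0)
  if (mc >= max(tr$t)) stop_hdc("metronome_cutoff must be shorter than the trial")
  tr
}

# Low-level integration returning velocities too (needed internally for the
# state-phase stability term); public simulate_dyad() strips them.
dyad_integrate <- function(human_osc, human_cpl, vp_osc, vp_cpl,
                           duration_s, dt, noise_sd, init_offset) {
  n_steps <- round(duration_s / dt)
  r_h <- limit_cycle_amplitude(human_osc)
  r_v <- limit_cycle_amplitude(vp_osc)
  if (!is.finite(r_h) || !is.finite(r_v)) {
    stop_hdc("oscillator parameters admit no finite limit cycle")
  }
  # human starts at phase 0 (metronome-locked), VP offset by init_offset
  state0 <- c(r_h, 0,
              r_v * cos(init_offset), -vp_osc$omega * r_v * sin(init_offset))
  res <- dyad_integrate_cpp(
    n_steps, dt, state0,
    c(human_osc$alpha, human_osc$beta, human_osc$gamma, human_osc$omega),
    c(human_cpl$a, human_cpl$b, human_cpl$mu),
    c(vp_osc$alpha, vp_osc$beta, vp_osc$gamma, vp_osc$omega),
    c(vp_cpl$a, vp_cpl$b, vp_cpl$mu),
    noise_sd
  )
  if (res$diverged_at > 0) {
    stop_hdc("dyad integration diverged at step %d (t = %.3f s); reduce dt or coupling gains",
             res$diverged_at, res$diverged_at * dt)
  }
  res$t <- seq(0, by = dt, length.out = n_steps + 1L)
  res
}

#' Simulate a coupled human--virtual-partner trial
#'
#' Integrates the bidirectionally coupled pair of hybrid oscillators with
#' fixed-step RK4; Gaussian acceleration noise (standard deviation
#' `noise_sd`, Euler--Maruyama injection) perturbs the synthetic human only,
#' mirroring the deterministic real-time virtual partner. The human starts
#' phase-locked at 0 (the metronome lead-in) and the virtual partner at
#' `init_offset` radians.
#'
#' @param human_osc,vp_osc [oscillator_params()] for the two effectors.
#' @param human_cpl,vp_cpl [coupling_params()]; each side's `mu_goal` is its
#'   own coordination goal.
#' @param duration_s Trial duration in seconds (default 20).
#' @param dt Integration step in seconds; must be at most 0.02.
#' @param noise_sd Acceleration noise standard deviation (units/s^2) on the
#'   human effector.
#' @param seed Optional integer seed; identical seeds give identical traces.
#' @param metronome_cutoff Lead-in (s) excluded from downstream scoring.
#' @param init_offset Initial VP phase offset (radians).
#' @return An `"hdc_trace"`: a tibble with columns `t`, `x_human`, `x_vp` and
#'   attributes `dt`, `metronome_cutoff`, `params`, `seed`.
#' @examples
#' tr <- simulate_dyad(duration_s = 10, seed = 1)
#' relative_phase(tr)$mean_resultant_length
#' @export
simulate_dyad <- function(human_osc = oscillator_params(),
                          human_cpl = coupling_params(),
                          vp_osc = oscillator_params(),
                          vp_cpl = coupling_params(),
                          duration_s = 20, dt = 0.01, noise_sd = 0,
                          seed = NULL, metronome_cutoff = 3,
                          init_offset = pi / 3) {
  check_number(duration_s, "duration_s", lower = 1e-9)
  check_number(dt, "dt", lower = 1e-9, upper = 0.02)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (duration_s <= metronome_cutoff) {
    stop_hdc("duration_s (%.2f) must exceed the metronome lead-in (%.2f)",
             duration_s, metronome_cutoff)
  }
  res <- with_seed_if(seed, dyad_integrate(
    human_osc, human_cpl, vp_osc, vp_cpl, duration_s, dt, noise_sd, init_offset
  ))
  new_trace(res$t, res$x1, res$x2, dt, metronome_cutoff,
            params = list(human_osc = unclass(human_osc),
                          human_cpl = unclass(human_cpl),
                          vp_osc = unclass(vp_osc),
                          vp_cpl = unclass(vp_cpl),
                          noise_sd = noise_sd, init_offset = init_offset),
            seed = seed)
}

#' @export
print.hdc_trace <- function(x, ...) {
  cat(sprintf("<hdc_trace> %d samples, dt = %g s, %.1f s (%g s metronome lead-in)\n",
              nrow(x), attr(x, "dt"), max(x$t), attr(x, "metronome_cutoff")))
  NextMethod()
}

#' @describeIn simulate_dyad Plot both channels of a trace against time.
#' @param object An `"hdc_trace"`.
#' @param ... Unused.
#' @export
autoplot.hdc_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("x_human", "x_vp"),
                              names_to = "channel", values_to = "position")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$position,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "metronome_cutoff"),
                        linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "position (units)", colour = NULL)
}
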