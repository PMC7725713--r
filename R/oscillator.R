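#' Oscillator parameters for one effector
#'
#' Parameters of the hybrid Rayleigh--van der Pol oscillator
#' \deqn{\ddot x + (\alpha x^2 + \beta \dot x^2 - \gamma)\dot x + \omega^2 x = C(t)}
#' used for both the synthetic human and the virtual partner. With
#' \eqn{\gamma > 0} the origin is unstable and the system settles on a limit
#' cycle of amplitude \eqn{r = \sqrt{4\gamma / (\alpha + 3\beta\omega^2)}}
#' (rotating-wave approximation). The defaults calibrate \eqn{r = 2} units at
#' 1 Hz, which puts the HKB coupling gains of [coupling_params()] in direct
#' correspondence with the reduced phase equation of [hkb_fixed_points()].
#'
#' @param alpha Position-nonlinearity damping coefficient (dimensionless).
#' @param gamma Linear negative-damping coefficient (1/s); must be positive
#'   for self-sustained oscillation.
#' @param omega Natural angular frequency (rad/s); must be positive.
#' @param beta Velocity-nonlinearity damping coefficient. The default
#'   \eqn{(\gamma - \alpha)/(3\omega^2)} calibrates the limit-cycle amplitude
#'   to 2 units.
#' @return An object of class `"hdc_osc"`: a named list with fields `alpha`,
#'   `beta`, `gamma`, `omega`.
#' @examples
#' osc <- oscillator_params()
#' limit_cycle_amplitude(osc) # 2
#' @export
oscillator_params <- function(alpha = 0.5, gamma = 1, omega = 2 * pi,
                              beta = (gamma - alpha) / (3 * omega^2)) {
  check_number(omega, "omega", lower = 1e-12)
  check_number(gamma, "gamma")
  if (gamma <= 0) {
    stop_hdc("`gamma` must be > 0 for self-sustained oscillation (got %g)", gamma)
  }
  check_number(alpha, "alpha")
  check_number(beta, "beta")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 gamma = as.numeric(gamma), omega = as.numeric(omega)),
            class = "hdc_osc")
}

#' @rdname oscillator_params
#' @param osc An `"hdc_osc"` object.
#' @export
limit_cycle_amplitude <- function(osc) {
  stopifnot(inherits(osc, "hdc_osc"))
  denom <- osc$alpha + 3 * osc$beta * osc$omega^2
  if (denom <= 0) return(Inf)
  sqrt(4 * osc$gamma / denom)
}

#' HKB coupling parameters
#'
#' Gains of the Haken--Kelso--Bunz style coupling force
#' \deqn{C = -(\dot x - \mu \dot x_o)\,[a - b (x - \mu x_o)^2]}
#' exerted on an effector by its partner's state \eqn{(x_o, \dot x_o)}. The
#' intended-phase parameter \eqn{\mu} is +1 when the effector aims for
#' in-phase coordination and -1 for anti-phase (the coupling then binds to the
#' mirrored partner coordinate). At the calibrated limit-cycle amplitude of 2
#' units the rotating-wave reduction of a symmetric dyad is
#' \eqn{\dot\phi = \Delta\omega - a_\mathrm{red}\sin\phi - 2 b_\mathrm{red}\sin 2\phi}
#' with \eqn{a_\mathrm{red} = a - 2b}, \eqn{b_\mathrm{red} = b/2}, so
#' anti-phase is stable precisely when \eqn{b/a > 1/4}, as in the reduced
#' model with the same gains.
#'
#' @param a_coupling Linear coupling gain (1/s); non-negative.
#' @param b_coupling Nonlinear coupling gain (1/(s units^2)); non-negative.
#' @param mu_goal Intended-phase parameter, `+1` (in-phase goal) or `-1`
#'   (anti-phase goal).
#' @return An object of class `"hdc_cpl"` with fields `a`, `b`, `mu`.
#' @export
coupling_params <- function(a_coupling = 0.5, b_coupling = 0.05, mu_goal = 1) {
  check_number(a_coupling, "a_coupling", lower = 0)
  check_number(b_coupling, "b_coupling", lower = 0)
  if (!mu_goal %in% c(-1, 1)) {
    stop_hdc("`mu_goal` must be +1 (in-phase) or -1 (anti-phase)")
  }
  structure(list(a = a_coupling, b = b_coupling, mu = mu_goal),
            class = "hdc_cpl")
}

#' Advance the virtual partner by one integration step
#'
#' Performs one fixed-step fourth-order Runge--Kutta step of the virtual
#' partner's oscillator, holding the human sample -- and hence the coupling
#' force computed from it -- constant over the step (the real-time clamp
#' receives a new sensor frame once per step and recomputes the force then).
#' In particular, when the two states coincide under an in-phase goal the
#' coupling force is exactly zero and the step equals the uncoupled step.
#'
#' @param vp_position,vp_velocity Current VP state.
#' @param human_position,human_velocity Human sample held constant over the step.
#' @param osc [oscillator_params()] of the VP.
#' @param cpl [coupling_params()] of the VP (its `mu_goal` is the VP's own
#'   coordination goal).
#' @param dt Step size in seconds; must be positive.
#' @return Named numeric vector `c(position = , velocity = )`.
#' @examples
#' vp_step(1, 0, 1, 0, oscillator_params(), coupling_params(), dt = 0.01)
#' @export
vp_step <- function(vp_position, vp_velocity, human_position, human_velocity,
                    osc, cpl, dt) {
  check_number(dt, "dt", lower = 1e-12)
  stopifnot(inherits(osc, "hdc_osc"), inherits(cpl, "hdc_cpl"))
  st <- c(vp_position, vp_velocity, human_position, human_velocity)
  if (any(!is.finite(st))) stop_hdc("non-finite state passed to vp_step()")
  force <- -(vp_velocity - cpl$mu * human_velocity) *
    (cpl$a - cpl$b * (vp_position - cpl$mu * human_position)^2)
  f <- function(s) {
    c(s[2],
      -(osc$alpha * s[1]^2 + osc$beta * s[2]^2 - osc$gamma) * s[2] -
        osc$omega^2 * s[1] + force)
  }
  s <- c(vp_position, vp_velocity)
  k1 <- f(s)
  k2 <- f(s + dt / 2 * k1)
  k3 <- f(s + dt / 2 * k2)
  k4 <- f(s + dt * k3)
  out <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (any(!is.finite(out))) {
    stop_hdc("vp_step() produced a non-finite state: numerical blow-up, reduce dt")
  }
  c(position = out[1], velocity = out[2])
}

#' Fixed points of the reduced HKB relative-phase equation
#'
#' Finds all roots of
#' \eqn{\dot\phi = \Delta\omega - a\sin\phi - 2b\sin 2\phi}
#' on \eqn{(-\pi, \pi]} and classifies their stability from the sign of the
#' derivative. In the phase-drift regime (detuning too large for the coupling)
#' there are no roots and an empty table is returned.
#'
#' @param a_coupling,b_coupling Reduced-equation coupling gains; non-negative.
#' @param delta_omega Frequency detuning \eqn{\Delta\omega} (rad/s).
#' @return A tibble with columns `phase` (radians in \eqn{(-\pi, \pi]}) and
#'   `stable` (logical), ordered by phase. Zero rows when the equation has no
#'   roots.
#' @examples
#' hkb_fixed_points(1, 1, 0)    # in-phase and anti-phase both stable
#' hkb_fixed_points(1, 0.1, 0)  # anti-phase unstable: b/a < 1/4
#' @export
hkb_fixed_points <- function(a_coupling, b_coupling, delta_omega = 0) {
  check_number(a_coupling, "a_coupling", lower = 0)
  check_number(b_coupling, "b_coupling", lower = 0)
  check_number(delta_omega, "delta_omega")
  f <- function(phi) delta_omega - a_coupling * sin(phi) - 2 * b_coupling * sin(2 * phi)
  fp <- function(phi) -a_coupling * cos(phi) - 4 * b_coupling * cos(2 * phi)

  # sample one full period plus margins so roots sitting exactly on the
  # (-pi, pi] boundary are caught as ordinary sign changes
  h <- 2 * pi / 4096
  grid <- seq(-pi - 8 * h, pi + 8 * h, by = h)
  vals <- f(grid)
  if (all(abs(vals) < 1e-12)) {
    # identically zero (uncoupled, no detuning): neutral continuum, no
    # isolated fixed points to report
    return(tibble(phase = numeric(), stable = logical()))
  }
  roots <- numeric()
  for (i in seq_len(length(grid) - 1L)) {
    if (abs(vals[i]) < 1e-14) {
      roots <- c(roots, grid[i])
    } else if (vals[i] * vals[i + 1L] < 0) {
      roots <- c(roots, stats::uniroot(f, c(grid[i], grid[i + 1L]),
                                       tol = 1e-12)$root)
    }
  }
  roots <- sort(wrap_phase(roots))
  # collapse near-duplicates (the same root found from both margins)
  if (length(roots) > 1) {
    keep <- c(TRUE, diff(roots) > 1e-6)
    roots <- roots[keep]
    if (abs(roots[1] + pi) < 1e-6 && abs(roots[length(roots)] - pi) < 1e-6) {
      roots <- roots[-1]
    }
  }
  tibble(phase = roots, stable = fp(roots) < 0)
}
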