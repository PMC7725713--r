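# Analytic-signal phase extraction and relative phase.

# Analytic signal via the frequency-domain construction: zero the negative
# frequencies, double the positive ones.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of an oscillatory series
#'
#' Analytic-signal (Hilbert) phase of the mean-centered series, unwrapped to a
#' continuous phase in radians. The first and last 5% of samples are flagged
#' for exclusion (attribute `"interior"`) because the transform is unreliable
#' near the window edges.
#'
#' @param series Numeric vector sampled on a uniform grid.
#' @param dt Sample step in seconds.
#' @param osc_floor Minimum peak-to-peak range below which the series is
#'   rejected as non-oscillatory.
#' @return Numeric vector of unwrapped phase (radians) with a logical
#'   attribute `"interior"` marking samples outside the trimmed edges.
#' @examples
#' t <- seq(0, 10, by = 0.01)
#' ph <- instantaneous_phase(sin(2 * pi * t), dt = 0.01)
#' @export
instantaneous_phase <- function(series, dt, osc_floor = 1e-3) {
  check_number(dt, "dt", lower = 1e-12)
  if (length(series) < 8L) stop_hdc("series too short for phase extraction")
  if (any(!is.finite(series))) stop_hdc("series contains non-finite values")
  if (diff(range(series)) < osc_floor) {
    stop_hdc("no oscillation detected: peak-to-peak range %.3g below floor %.3g",
             diff(range(series)), osc_floor)
  }
  z <- analytic_signal(series - mean(series))
  ph <- Arg(z)
  dp <- wrap_phase(diff(ph))
  unwrapped <- ph[1] + c(0, cumsum(dp))
  n <- length(series)
  edge <- max(1L, floor(0.05 * n))
  interior <- rep(TRUE, n)
  interior[seq_len(edge)] <- FALSE
  interior[seq.int(n - edge + 1L, n)] <- FALSE
  attr(unwrapped, "interior") <- interior
  unwrapped
}

#' Relative phase of a human--virtual-partner trace
#'
#' Computes \eqn{\phi_{rel}(t) = \mathrm{wrap}(\phi_{human} - \phi_{vp})} from
#' the analytic-signal phases of the two channels, retaining only samples
#' after the metronome lead-in and inside the 5% edge trim, together with the
#' mean resultant length (phase-locking value)
#' \eqn{R = |\langle e^{i\phi_{rel}}\rangle|}.
#'
#' @param trace An `"hdc_trace"` from [simulate_dyad()] or [read_trace()].
#' @param osc_floor Passed to [instantaneous_phase()].
#' @return An object of class `"hdc_phase"`: list with `t` and
#'   `relative_phase` (radians in \eqn{(-\pi, \pi]}) on the retained samples,
#'   and scalar `mean_resultant_length` in \[0, 1\].
#' @export
relative_phase <- function(trace, osc_floor = 1e-3) {
  stopifnot(inherits(trace, "hdc_trace"))
  dt <- attr(trace, "dt")
  ph_h <- instantaneous_phase(trace$x_human, dt, osc_floor)
  ph_v <- instantaneous_phase(trace$x_vp, dt, osc_floor)
  keep <- attr(ph_h, "interior") & attr(ph_v, "interior") &
    trace$t > attr(trace, "metronome_cutoff")
  if (!any(keep)) stop_hdc("no samples retained after trimming")
  phi <- wrap_phase(ph_h[keep] - ph_v[keep])
  structure(
    list(t = trace$t[keep], relative_phase = phi,
         mean_resultant_length = Mod(mean(exp(1i * phi)))),
    class = "hdc_phase"
  )
}

#' @export
print.hdc_phase <- function(x, ...) {
  cat(sprintf(
    "<hdc_phase> %d samples, circular mean %.3f rad, mean resultant length %.3f\n",
    length(x$relative_phase),
    Arg(mean(exp(1i * x$relative_phase))),
    x$mean_resultant_length))
  invisible(x)
}

# State-space relative phase (atan2(-v/omega, x)) mean resultant length;
# cheap stability index available during simulation without a second pass.
state_phase_mrl <- function(res, omega_h, omega_v, t_min) {
  keep <- res$t > t_min
  ph <- atan2(-res$v1[keep] / omega_h, res$x1[keep]) -
    atan2(-res$v2[keep] / omega_v, res$x2[keep])
  Mod(mean(exp(1i * ph)))
}
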