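# Full-session simulation: one participant through the whole protocol.

#' Simulation configuration
#'
#' Collects the physical and response-model constants of a session
#' simulation. Defaults: 20 s trials (3 s metronome lead-in + 17 s
#' interaction) at dt = 0.01 s; coupling gains a = 0.5, b = 0.05 for both
#' sides (with the intended pattern encoded by `mu_goal`, both coordination
#' patterns are attractors; b is kept small so the nonlinear coupling term
#' stays a perturbation during transients); a 5% probability of
#' an "unsure" intention rating; and a humanness judgment whose logit gains
#' `humanness_stability_coef` * (trial stability - 0.5), where trial
#' stability is the state-phase mean resultant length of the trial.
#'
#' @param duration_s,dt,metronome_cutoff Trial timing (seconds).
#' @param human_osc,vp_osc Baseline [oscillator_params()]; the human's are
#'   rescaled per participant by `motor_gain`.
#' @param a_coupling,b_coupling HKB gains used for both sides; the human's
#'   `a` is additionally multiplied by the participant's `compliance`.
#' @param unsure_prob Probability of an "unsure" (0) intention rating.
#' @param humanness_stability_coef Weight of the trial-stability term in the
#'   humanness logit.
#' @return An object of class `"hdc_sim_config"`.
#' @export
sim_config <- function(duration_s = 20, dt = 0.01, metronome_cutoff = 3,
                       human_osc = oscillator_params(),
                       vp_osc = oscillator_params(),
                       a_coupling = 0.5, b_coupling = 0.05,
                       unsure_prob = 0.05, humanness_stability_coef = 1.5) {
  check_number(duration_s, "duration_s", lower = 1)
  check_number(dt, "dt", lower = 1e-9, upper = 0.02)
  check_number(unsure_prob, "unsure_prob", lower = 0, upper = 1)
  duration_s <- as.numeric(duration_s)
  dt <- as.numeric(dt)
  metronome_cutoff <- as.numeric(metronome_cutoff)
  a_coupling <- as.numeric(a_coupling)
  b_coupling <- as.numeric(b_coupling)
  unsure_prob <- as.numeric(unsure_prob)
  humanness_stability_coef <- as.numeric(humanness_stability_coef)
  structure(
    list(duration_s = duration_s, dt = dt, metronome_cutoff = metronome_cutoff,
         human_osc = human_osc, vp_osc = vp_osc,
         a_coupling = a_coupling, b_coupling = b_coupling,
         unsure_prob = unsure_prob,
         humanness_stability_coef = humanness_stability_coef),
    class = "hdc_sim_config"
  )
}

# Rescale an oscillator's limit-cycle amplitude by `gain` (alpha and beta
# jointly divided by gain^2 leaves gamma, omega -- hence the relaxation rate
# and frequency -- untouched).
scale_amplitude <- function(osc, gain) {
  oscillator_params(alpha = osc$alpha / gain^2, gamma = osc$gamma,
                    omega = osc$omega, beta = osc$beta / gain^2)
}

as_profile <- function(profile) {
  if (is_tibble(profile) || is.data.frame(profile)) {
    if (nrow(profile) != 1L) stop_hdc("`profile` must be a single participant row")
    profile <- as.list(profile)
  }
  needed <- c("age", "motor_gain", "motor_noise_sd", "compliance",
              "attribution_intercept", "attribution_age_slope",
              "humanness_intercept", "humanness_age_slope")
  missing <- setdiff(needed, names(profile))
  if (length(missing)) {
    stop_hdc("profile is missing fields: %s", paste(missing, collapse = ", "))
  }
  profile
}

#' Simulate one participant's full session
#'
#' Runs every trial of the protocol through the dyad simulator and the
#' sociocognitive response models. Per trial: the human oscillator amplitude
#' is scaled by the participant's `motor_gain`, the human coupling gain by
#' `compliance`, acceleration noise has standard deviation `motor_noise_sd`,
#' the human's `mu_goal` follows the instruction and the virtual partner's
#' follows its cooperative/competitive goal. The end-of-trial intention
#' rating is correct with probability
#' `plogis(attribution_intercept + attribution_age_slope * age)` (inverted
#' otherwise, "unsure" with probability `unsure_prob`); the humanness
#' judgment is "human" with probability
#' `plogis(humanness_intercept + humanness_age_slope * age + stability term)`.
#'
#' @param profile One participant row of [sample_cohort()] (or an equivalent
#'   named list).
#' @param protocol A [build_protocol()] table.
#' @param config A [sim_config()].
#' @param seed Integer seed; the same (profile, protocol, seed) triple
#'   reproduces the session exactly.
#' @param keep_traces Set `FALSE` to drop the movement traces (the per-trial
#'   ratings, judgments and stability summary are kept).
#' @return An object of class `"hdc_session"`: list with `profile`,
#'   `trials` (protocol plus per-trial `intention_rating` in \{-1, 0, +1\},
#'   `humanness_judgment` in \{"robot", "human"\} and `stability`),
#'   `traces` (list of `"hdc_trace"`, unless dropped), `config`, `seed`.
#' @export
simulate_session <- function(profile, protocol = build_protocol(),
                             config = sim_config(), seed = NULL,
                             keep_traces = TRUE) {
  stopifnot(inherits(config, "hdc_sim_config"))
  profile <- as_profile(profile)
  n_trials <- nrow(protocol)

  human_osc <- scale_amplitude(config$human_osc, profile$motor_gain)
  vp_osc <- config$vp_osc
  a_h <- config$a_coupling * profile$compliance
  p_correct <- plogis(profile$attribution_intercept +
                        profile$attribution_age_slope * profile$age)
  h_logit0 <- profile$humanness_intercept +
    profile$humanness_age_slope * profile$age

  n_steps <- round(config$duration_s / config$dt)
  # first 0-based sample index with t strictly past the metronome lead-in
  cut_idx <- floor(config$metronome_cutoff / config$dt) + 1L

  res <- with_seed_if(seed, {
    offsets <- runif(n_trials, -pi, pi)
    out <- session_integrate_cpp(
      n_trials, n_steps, config$dt, cut_idx,
      c(human_osc$alpha, human_osc$beta, human_osc$gamma, human_osc$omega),
      c(vp_osc$alpha, vp_osc$beta, vp_osc$gamma, vp_osc$omega),
      a_h, config$a_coupling, config$b_coupling,
      protocol$human_goal, protocol$vp_goal, offsets,
      profile$motor_noise_sd, keep_traces
    )
    out$u_unsure <- runif(n_trials)
    out$u_correct <- runif(n_trials)
    out$u_human <- runif(n_trials)
    out
  })
  if (any(res$diverged > 0)) {
    i <- which(res$diverged > 0)[1]
    stop_hdc("trial %d diverged at step %d; reduce dt or coupling gains",
             i, res$diverged[i])
  }

  correct_sign <- ifelse(protocol$vp_behavior == "cooperative", 1L, -1L)
  trials <- protocol
  trials$intention_rating <- ifelse(
    res$u_unsure < config$unsure_prob, 0L,
    ifelse(res$u_correct < p_correct, correct_sign, -correct_sign))
  p_human <- plogis(h_logit0 +
                      config$humanness_stability_coef * (res$mrl - 0.5))
  trials$humanness_judgment <- ifelse(res$u_human < p_human, "human", "robot")
  trials$stability <- res$mrl
  trials$amp_human <- res$amp_h
  trials$amp_vp <- res$amp_v

  traces <- NULL
  if (keep_traces) {
    t_grid <- seq(0, by = config$dt, length.out = n_steps + 1L)
    traces <- lapply(seq_len(n_trials), function(i) {
      M <- res$traces[[i]]
      tr <- tibble::new_tibble(
        list(t = t_grid, x_human = M[, 1], x_vp = M[, 2]),
        nrow = n_steps + 1L, class = "hdc_trace")
      attr(tr, "dt") <- config$dt
      attr(tr, "metronome_cutoff") <- config$metronome_cutoff
      attr(tr, "params") <- list(trial = i)
      attr(tr, "seed") <- NULL
      tr
    })
  }
  structure(
    list(profile = profile, trials = trials, traces = traces,
         config = config, seed = seed),
    class = "hdc_session"
  )
}

#' @export
print.hdc_session <- function(x, ...) {
  cat(sprintf("<hdc_session> %s: %d trials%s\n",
              x$profile$participant_id %||% "participant",
              nrow(x$trials),
              if (is.null(x$traces)) " (traces dropped)" else ""))
  invisible(x)
}

#' Simulate sessions for a whole cohort
#'
#' Convenience wrapper: one randomized protocol and one session per
#' participant, with per-participant seeds derived from `seed`.
#'
#' @param cohort A [sample_cohort()] table.
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @param keep_traces Keep movement traces in each session (memory scales
#'   with cohort size; see [score_cohort()] for the streaming alternative).
#' @return A list of `"hdc_session"` objects, one per cohort row.
#' @export
simulate_cohort <- function(cohort, config = sim_config(), seed = 1,
                            keep_traces = TRUE) {
  lapply(seq_len(nrow(cohort)), function(i) {
    simulate_session(cohort[i, ],
                     protocol = build_protocol(derive_seed(seed, i, 1)),
                     config = config, seed = derive_seed(seed, i, 2),
                     keep_traces = keep_traces)
  })
}
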