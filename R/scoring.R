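# The five normalized HDC scores, per trial and aggregated.

ALL_SCORES <- c("motor", "coordination", "task", "intention", "humanness")
CELL_LEVELS <- c("inphase_coop", "inphase_comp", "antiphase_coop", "antiphase_comp")

post_metronome <- function(trace) {
  keep <- trace$t > attr(trace, "metronome_cutoff")
  list(x_human = trace$x_human[keep], x_vp = trace$x_vp[keep])
}

median_cycle_amplitude <- function(x) {
  amps <- cycle_amplitudes_cpp(x - mean(x))
  if (length(amps) == 0) 0 else median(amps)
}

#' Motor score: amplitude matching of imitative gestures
#'
#' Compares the median per-cycle peak-to-peak amplitude of the human and
#' virtual-partner channels on the post-metronome segment:
#' `clamp(1 - |A_h - A_vp| / A_vp, 0, 1)`. 1 means amplitudes match; 0 means
#' the human's amplitude misses the partner's by 100% or more (e.g. an
#' immobile participant).
#'
#' @param trace An `"hdc_trace"`.
#' @param osc_floor Peak-to-peak floor below which the VP channel is treated
#'   as flat (a simulator fault).
#' @return A number in \[0, 1\].
#' @export
motor_score <- function(trace, osc_floor = 1e-3) {
  stopifnot(inherits(trace, "hdc_trace"))
  seg <- post_metronome(trace)
  if (diff(range(seg$x_vp)) < osc_floor) {
    stop_hdc("virtual-partner channel is flat: simulator fault")
  }
  a_vp <- median_cycle_amplitude(seg$x_vp)
  a_h <- median_cycle_amplitude(seg$x_human)
  min(1, max(0, 1 - abs(a_h - a_vp) / a_vp))
}

#' Coordination score: phase-locking value
#'
#' The mean resultant length of the relative-phase series of the trial
#' (1 = perfectly locked at any constant relative phase, 0 = uniform
#' drifting phase). This is the temporal index of imitation, agnostic to
#' *which* phase relation is held.
#'
#' @inheritParams motor_score
#' @return A number in \[0, 1\].
#' @export
coordination_score <- function(trace, osc_floor = 1e-3) {
  relative_phase(trace, osc_floor)$mean_resultant_length
}

#' Task score: instruction-conditional phase matching
#'
#' Mean over retained samples of `(1 + cos(phi_rel - phi_target)) / 2` with
#' the target 0 rad under the in-phase instruction and pi under anti-phase:
#' 1 when the participant holds exactly the instructed relation, 0 when
#' locked onto its opposite, 0.5 when in quadrature or drifting uniformly.
#'
#' @inheritParams motor_score
#' @param instruction `"in_phase"` or `"anti_phase"`.
#' @return A number in \[0, 1\].
#' @export
task_score <- function(trace, instruction = c("in_phase", "anti_phase"),
                       osc_floor = 1e-3) {
  instruction <- match.arg(instruction)
  target <- if (instruction == "in_phase") 0 else pi
  phi <- relative_phase(trace, osc_floor)$relative_phase
  mean((1 + cos(phi - target)) / 2)
}

#' Intention score: attributing cooperativeness correctly
#'
#' Per-trial credit of 1 when the sign of the participant's rating (+1
#' cooperative, -1 competitive) matches the virtual partner's true behavior,
#' 0.5 for an "unsure" rating of 0, 0 otherwise; averaged over trials.
#'
#' @param ratings Integer vector of end-of-trial ratings in \{-1, 0, +1\}.
#' @param trial_specs Either a protocol table with a `vp_behavior` column or
#'   a character vector of `"cooperative"`/`"competitive"`.
#' @return A number in \[0, 1\].
#' @export
intention_score <- function(ratings, trial_specs) {
  behavior <- if (is.data.frame(trial_specs)) trial_specs$vp_behavior else trial_specs
  if (length(ratings) != length(behavior)) {
    stop_hdc("ratings (%d) and trial specs (%d) differ in length",
             length(ratings), length(behavior))
  }
  if (!all(ratings %in% c(-1, 0, 1))) stop_hdc("ratings must be in {-1, 0, +1}")
  mean(intention_credit(ratings, behavior))
}

intention_credit <- function(ratings, behavior) {
  true_sign <- ifelse(behavior == "cooperative", 1, -1)
  ifelse(ratings == 0, 0.5, as.numeric(ratings == true_sign))
}

#' Humanness score: fraction of trials judged human
#'
#' A participant judging the partner human on every trial scores 1; one
#' always answering robot scores 0.
#'
#' @param judgments Character vector of `"human"`/`"robot"` judgments.
#' @return A number in \[0, 1\].
#' @export
humanness_score <- function(judgments) {
  if (length(judgments) == 0) stop_hdc("empty judgment list")
  judgments <- as.character(judgments)
  if (!all(judgments %in% c("human", "robot"))) {
    stop_hdc('judgments must be "human" or "robot"')
  }
  mean(judgments == "human")
}

#' Per-trial scores of a session
#'
#' @param session An `"hdc_session"`.
#' @param scores Subset of scores to compute (kinematic scores need traces).
#' @return A tibble with one row per trial: `trial`, `instruction`,
#'   `vp_behavior`, and one column per requested score (per-trial values).
#' @export
score_trials <- function(session, scores = ALL_SCORES) {
  stopifnot(inherits(session, "hdc_session"))
  scores <- match.arg(scores, ALL_SCORES, several.ok = TRUE)
  tr <- session$trials
  out <- tibble(trial = tr$trial, instruction = tr$instruction,
                vp_behavior = tr$vp_behavior)
  kinematic <- intersect(scores, c("motor", "coordination", "task"))
  # motor can fall back on the per-trial amplitude summaries recorded at
  # simulation time (same cycle-amplitude statistic, no trace needed)
  motor_from_summary <- is.null(session$traces) &&
    all(c("amp_human", "amp_vp") %in% names(tr))
  needs_traces <- setdiff(kinematic, if (motor_from_summary) "motor")
  if (length(needs_traces) && is.null(session$traces)) {
    stop_hdc("session has no traces: cannot compute %s",
             paste(needs_traces, collapse = ", "))
  }
  score_one <- function(i, fn) {
    tryCatch(fn(i), error = function(e) {
      stop_hdc("trial %d: %s", i, conditionMessage(e))
    })
  }
  if ("motor" %in% scores) {
    out$motor <- if (motor_from_summary) {
      if (any(tr$amp_vp < 1e-3)) stop_hdc("virtual-partner channel is flat")
      pmin(1, pmax(0, 1 - abs(tr$amp_human - tr$amp_vp) / tr$amp_vp))
    } else {
      vapply(tr$trial, score_one, numeric(1),
             fn = function(i) motor_score(session$traces[[i]]))
    }
  }
  if ("coordination" %in% scores) {
    out$coordination <- vapply(tr$trial, score_one, numeric(1),
                               fn = function(i) coordination_score(session$traces[[i]]))
  }
  if ("task" %in% scores) {
    out$task <- vapply(tr$trial, score_one, numeric(1),
                       fn = function(i) task_score(session$traces[[i]],
                                                   tr$instruction[i]))
  }
  if ("intention" %in% scores) {
    out$intention <- intention_credit(tr$intention_rating, tr$vp_behavior)
  }
  if ("humanness" %in% scores) {
    out$humanness <- as.numeric(tr$humanness_judgment == "human")
  }
  out
}

cell_label <- function(instruction, vp_behavior) {
  paste0(ifelse(instruction == "in_phase", "inphase", "antiphase"), "_",
         ifelse(vp_behavior == "cooperative", "coop", "comp"))
}

#' Aggregate a session into its score set
#'
#' Averages the per-trial scores globally (every trial weighted equally) and
#' within each of the four instruction-by-behavior subcondition cells. A cell
#' the protocol never visited is reported as `NA`, never zero-filled.
#'
#' @inheritParams score_trials
#' @return A one-row tibble with columns `<score>_global`,
#'   `<score>_<cell>` for each cell in
#'   `inphase_coop`, `inphase_comp`, `antiphase_coop`, `antiphase_comp`,
#'   and trial counts `n_<cell>`.
#' @examples
#' prof <- sample_cohort(cohort_spec(n_asd = 1, n_td = 1), seed = 1)[2, ]
#' sess <- simulate_session(prof, build_protocol(seed = 1),
#'                          sim_config(duration_s = 8), seed = 1)
#' score_session(sess)
#' @export
score_session <- function(session, scores = ALL_SCORES) {
  per_trial <- score_trials(session, scores)
  aggregate_trial_scores(per_trial, scores)
}

aggregate_trial_scores <- function(per_trial, scores = ALL_SCORES) {
  scores <- intersect(ALL_SCORES, names(per_trial))
  cell <- cell_label(per_trial$instruction, per_trial$vp_behavior)
  out <- list()
  for (s in scores) {
    out[[paste0(s, "_global")]] <- mean(per_trial[[s]])
    for (cl in CELL_LEVELS) {
      v <- per_trial[[s]][cell == cl]
      out[[paste0(s, "_", cl)]] <- if (length(v)) mean(v) else NA_real_
    }
  }
  for (cl in CELL_LEVELS) out[[paste0("n_", cl)]] <- sum(cell == cl)
  as_tibble(out)
}

#' Simulate and score a whole cohort, streaming
#'
#' For each participant: build a randomized protocol, simulate the session,
#' score it, and discard the traces before moving on, so memory stays flat in
#' cohort size. Sub-seeds derive deterministically from `seed`.
#'
#' @param cohort A [sample_cohort()] table.
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @param scores Subset of the five scores to compute (restricting to
#'   `"motor"` skips the phase transform and is considerably faster).
#' @return The cohort's demographic columns joined with one [score_session()]
#'   row per participant.
#' @export
score_cohort <- function(cohort, config = sim_config(), seed = 1,
                         scores = ALL_SCORES) {
  demo_cols <- intersect(
    c("participant_id", "group", "sex", "age", "handedness", "iq", "srs_t",
      "nepsy_tom", "nepsy_af", "purdue_z"),
    names(cohort)
  )
  need_traces <- any(c("coordination", "task") %in% scores)
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    sess <- simulate_session(cohort[i, ],
                             protocol = build_protocol(derive_seed(seed, i, 1)),
                             config = config, seed = derive_seed(seed, i, 2),
                             keep_traces = need_traces)
    score_session(sess, scores)
  })
  dplyr::bind_cols(cohort[, demo_cols], dplyr::bind_rows(rows))
}
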