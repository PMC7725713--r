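#' Build the 40-trial block protocol
#'
#' The default session protocol is 4 blocks of 10 trials. The instruction
#' (in-phase vs anti-phase) is constant within a block and alternates between
#' consecutive blocks; which instruction opens the session is randomized.
#' Virtual-partner behavior (cooperative vs competitive) is an independent
#' fair coin on every trial, disregarding block structure: a cooperative
#' partner adopts the participant's instructed goal, a competitive one the
#' opposite.
#'
#' @param seed Optional integer seed fixing the first-block instruction and
#'   the per-trial behavior draws.
#' @param n_blocks,trials_per_block Protocol dimensions (defaults 4 and 10).
#' @return A tibble with one row per trial: `trial`, `block`, `instruction`
#'   (`"in_phase"`/`"anti_phase"`), `vp_behavior`
#'   (`"cooperative"`/`"competitive"`), `human_goal` (+1/-1) and `vp_goal`
#'   (+1/-1).
#' @examples
#' build_protocol(seed = 1)
#' @export
build_protocol <- function(seed = NULL, n_blocks = 4, trials_per_block = 10) {
  check_number(n_blocks, "n_blocks", lower = 1)
  check_number(trials_per_block, "trials_per_block", lower = 1)
  n_trials <- n_blocks * trials_per_block
  with_seed_if(seed, {
    first <- sample(c("in_phase", "anti_phase"), 1L)
    other <- setdiff(c("in_phase", "anti_phase"), first)
    instruction <- rep(rep(c(first, other), length.out = n_blocks),
                       each = trials_per_block)
    vp_behavior <- sample(c("cooperative", "competitive"), n_trials,
                          replace = TRUE)
    human_goal <- ifelse(instruction == "in_phase", 1, -1)
    tibble(
      trial = seq_len(n_trials),
      block = rep(seq_len(n_blocks), each = trials_per_block),
      instruction = instruction,
      vp_behavior = vp_behavior,
      human_goal = human_goal,
      vp_goal = ifelse(vp_behavior == "cooperative", human_goal, -human_goal)
    )
  })
}
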