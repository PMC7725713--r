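test_that("motor score reflects the amplitude ratio", {
  expect_equal(motor_score(sine_trace(amp_h = 1, amp_vp = 1)), 1)
  expect_equal(motor_score(sine_trace(amp_h = 0.5, amp_vp = 1)), 0.5,
               tolerance = 1e-6)
  # immobile participant: zero credit
  flat <- make_trace(rep(0, 2001), cos(2 * pi * seq(0, 20, by = 0.01)),
                     metronome_cutoff = 3)
  expect_equal(motor_score(flat), 0)
  # overshooting by more than 100% also floors at 0
  expect_equal(motor_score(sine_trace(amp_h = 2.5, amp_vp = 1)), 0)
  # flat VP channel is a simulator fault
  vp_flat <- make_trace(cos(2 * pi * seq(0, 20, by = 0.01)), rep(0, 2001),
                        metronome_cutoff = 3)
  expect_error(motor_score(vp_flat), "flat")
})

test_that("coordination score is the phase-locking value", {
  # locked at any constant angle: 1
  for (phi in c(0, pi / 3, pi)) {
    expect_equal(coordination_score(sine_trace(phi = phi)), 1,
                 tolerance = 1e-6)
  }
  # incommensurate frequencies drift through all phases: near 0
  t <- seq(0, 20, by = 0.01)
  drift <- make_trace(cos(2 * pi * 1.31 * t), cos(2 * pi * t),
                      metronome_cutoff = 3)
  expect_lt(coordination_score(drift), 0.05)
})

test_that("task score matches the cosine profile of the target mismatch", {
  expect_equal(task_score(sine_trace(phi = 0), "in_phase"), 1, tolerance = 1e-6)
  expect_equal(task_score(sine_trace(phi = pi), "in_phase"), 0, tolerance = 1e-6)
  expect_equal(task_score(sine_trace(phi = pi), "anti_phase"), 1, tolerance = 1e-6)
  expect_equal(task_score(sine_trace(phi = pi / 2), "in_phase"), 0.5,
               tolerance = 1e-3)
  expect_equal(task_score(sine_trace(phi = pi / 2), "anti_phase"), 0.5,
               tolerance = 1e-3)
})

test_that("perfect quadrature locking decouples task from coordination", {
  tr <- sine_trace(phi = pi / 2)
  expect_equal(coordination_score(tr), 1, tolerance = 1e-6)
  expect_equal(task_score(tr, "in_phase"), 0.5, tolerance = 1e-3)
  expect_equal(task_score(tr, "anti_phase"), 0.5, tolerance = 1e-3)
})

test_that("mirroring one channel swaps the task targets", {
  withr::with_seed(21, {
    for (i in 1:5) {
      phi <- runif(1, -pi, pi)
      tr <- sine_trace(phi = phi)
      mirrored <- make_trace(tr$x_human, -tr$x_vp, metronome_cutoff = 3)
      expect_equal(task_score(tr, "in_phase"), task_score(mirrored, "anti_phase"),
                   tolerance = 1e-6)
      expect_equal(task_score(tr, "anti_phase"), task_score(mirrored, "in_phase"),
                   tolerance = 1e-6)
    }
  })
})

test_that("intention score credits correct attributions and half for unsure", {
  beh <- rep(c("cooperative", "competitive"), each = 20)
  right <- ifelse(beh == "cooperative", 1, -1)
  expect_equal(intention_score(right, beh), 1)
  expect_equal(intention_score(-right, beh), 0)
  expect_equal(intention_score(rep(0, 40), beh), 0.5)
  mixed <- right
  mixed[1:10] <- -mixed[1:10] # 30 correct, 10 wrong of 40
  expect_equal(intention_score(mixed, beh), 0.75)
  expect_error(intention_score(right[-1], beh), "length")
  expect_error(intention_score(c(2, right[-1]), beh), "ratings")
})

test_that("humanness score is the fraction of human judgments", {
  expect_equal(humanness_score(rep("human", 40)), 1)
  expect_equal(humanness_score(rep("robot", 40)), 0)
  expect_equal(humanness_score(rep(c("human", "robot"), 20)), 0.5)
  expect_error(humanness_score(character(0)), "empty")
  expect_error(humanness_score(c("human", "cyborg")), "judgments")
})

test_that("score_session aggregates per cell and flags empty cells", {
  # hand-built four-trial session, one trial per subcondition cell
  proto <- tibble::tibble(
    trial = 1:4, block = 1:4,
    instruction = c("in_phase", "in_phase", "anti_phase", "anti_phase"),
    vp_behavior = c("cooperative", "competitive", "cooperative", "competitive"),
    human_goal = c(1, 1, -1, -1), vp_goal = c(1, -1, -1, 1)
  )
  amps_h <- c(1, 0.5, 0, 0.5) # per-trial motor scores 1.0 / 0.5 / 0.0 / 0.5
  traces <- lapply(amps_h, function(a) sine_trace(amp_h = a, amp_vp = 1))
  sess <- structure(
    list(profile = test_profile(),
         trials = dplyr::mutate(proto, intention_rating = c(1L, -1L, 0L, 1L),
                                humanness_judgment = rep("human", 4)),
         traces = traces, config = sim_config(), seed = 1),
    class = "hdc_session"
  )
  sc <- score_session(sess, c("motor", "intention", "humanness"))
  expect_equal(sc$motor_global, 0.5, tolerance = 1e-6)
  expect_equal(sc$motor_inphase_coop, 1, tolerance = 1e-6)
  expect_equal(sc$motor_inphase_comp, 0.5, tolerance = 1e-6)
  expect_equal(sc$motor_antiphase_coop, 0, tolerance = 1e-6)
  expect_equal(sc$motor_antiphase_comp, 0.5, tolerance = 1e-6)
  expect_equal(sc$humanness_global, 1)
  expect_identical(sc$n_inphase_coop, 1L)

  # all trials in one cell: the others are missing, never zero-filled
  proto1 <- dplyr::mutate(proto, instruction = "in_phase",
                          vp_behavior = "cooperative",
                          human_goal = 1, vp_goal = 1)
  sess1 <- sess
  sess1$trials <- dplyr::mutate(proto1, intention_rating = 1L,
                                humanness_judgment = "human")
  sc1 <- score_session(sess1, c("motor", "intention", "humanness"))
  expect_true(is.na(sc1$motor_antiphase_comp))
  expect_identical(sc1$n_antiphase_comp, 0L)
  expect_equal(sc1$motor_inphase_coop, sc1$motor_global)
})

test_that("every score stays in [0, 1] across randomized sessions", {
  cfg <- fast_config()
  score_cols <- function(sc) {
    unlist(sc[grepl("^(motor|coordination|task|intention|humanness)_", names(sc))])
  }
  for (s in 1:6) {
    prof <- withr::with_seed(s, test_profile(
      age = runif(1, 5, 25), motor_gain = runif(1, 0.3, 1.8),
      motor_noise_sd = runif(1, 0, 10), compliance = runif(1, 0, 2),
      attribution_intercept = runif(1, -3, 3),
      humanness_intercept = runif(1, -3, 3)
    ))
    sess <- simulate_session(prof, build_protocol(seed = s), cfg, seed = s)
    vals <- score_cols(score_session(sess))
    vals <- vals[!is.na(vals)]
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("more motor noise never helps coordination, on seed averages", {
  mean_coord <- function(noise_sd) {
    mean(vapply(1:50, function(s) {
      tr <- simulate_dyad(duration_s = 10, noise_sd = noise_sd, seed = s)
      coordination_score(tr)
    }, numeric(1)))
  }
  coords <- vapply(c(0.5, 3, 8), mean_coord, numeric(1))
  expect_true(all(diff(coords) < 0))
})
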