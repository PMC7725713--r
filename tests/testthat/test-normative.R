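test_that("constant control scores give a constant predictive mean", {
  ages <- seq(6, 24, length.out = 30)
  m <- fit_normative(ages, rep(0.7, 30), seed = 1)
  pr <- predict(m, c(5, 12, 28))
  expect_equal(pr$.pred, rep(0.7, 3), tolerance = 1e-6)
})

test_that("the GP recovers a smooth developmental trend", {
  withr::with_seed(3, {
    ages <- runif(200, 6, 24)
    y <- 0.02 * ages + rnorm(200, 0, 0.05)
  })
  m <- fit_normative(ages, y, seed = 1)
  grid <- seq(7, 23, length.out = 50)
  expect_lt(max(abs(predict(m, grid)$.pred - 0.02 * grid)), 0.02)
})

test_that("fitting is deterministic given the seed", {
  withr::with_seed(5, {
    ages <- runif(40, 5, 25)
    y <- 0.5 + 0.01 * ages + rnorm(40, 0, 0.05)
  })
  m1 <- fit_normative(ages, y, seed = 9)
  m2 <- fit_normative(ages, y, seed = 9)
  expect_identical(tidy(m1), tidy(m2))
})

test_that("degenerate normative inputs are rejected", {
  expect_error(fit_normative(1:5, 1:5, seed = 1), "at least 10")
  expect_error(fit_normative(c(1:9, NA), rnorm(10), seed = 1), "finite")
})

test_that("deviation z is the standardized deviation by definition", {
  withr::with_seed(2, {
    ages <- runif(30, 5, 25)
    y <- rnorm(30, 0.6, 0.1)
  })
  m <- fit_normative(ages, y, seed = 1)
  pr <- predict(m, 12)
  expect_equal(deviation_z(m, 12, pr$.pred)$z, 0, tolerance = 1e-10)
  expect_equal(deviation_z(m, 12, pr$.pred + 2 * pr$.pred_sd)$z, 2,
               tolerance = 1e-10)
  # extrapolation widens the predictive spread
  expect_gt(predict(m, 60)$.pred_sd, pr$.pred_sd)
})

test_that("held-out control z-scores are calibrated", {
  withr::with_seed(11, {
    truth <- function(a) 0.6 + 0.1 * sin(a / 4)
    ages_tr <- runif(150, 5, 25)
    y_tr <- truth(ages_tr) + rnorm(150, 0, 0.08)
    ages_te <- runif(500, 5, 25)
    y_te <- truth(ages_te) + rnorm(500, 0, 0.08)
  })
  m <- fit_normative(ages_tr, y_tr, seed = 1)
  z <- deviation_z(m, ages_te, y_te)$z
  expect_lt(abs(mean(z)), 0.1)
  expect_true(sd(z) > 0.85 && sd(z) < 1.15)
  frac <- mean(abs(z) > 1.96)
  expect_true(frac > 0.025 && frac < 0.085)
})

test_that("posterior mean matches an independent GP implementation", {
  skip_if_not_installed("kernlab")
  withr::with_seed(4, {
    ages <- runif(60, 5, 25)
    y <- 0.5 + 0.015 * ages + rnorm(60, 0, 0.06)
  })
  m <- fit_normative(ages, y, seed = 1)
  grid <- seq(6, 24, length.out = 30)
  mine <- predict(m, grid)$.pred
  # same kernel and regularization: k_se with sigma = 1/(2 ell^2), ridge
  # sigma_n^2 / sigma_f^2 on the mean-centered targets
  kl <- kernlab::gausspr(
    x = matrix(ages), y = y - m$y_mean, scaled = FALSE,
    kernel = "rbfdot", kpar = list(sigma = 1 / (2 * m$ell^2)),
    var = m$sigma_n2 / m$sigma_f2, tol = 1e-8
  )
  theirs <- m$y_mean + kernlab::predict(kl, matrix(grid))
  expect_equal(mine, as.numeric(theirs), tolerance = 1e-4)
})

test_that("z-scores are affine-equivariant and monotone in the score", {
  withr::with_seed(6, {
    ages <- runif(60, 5, 25)
    y <- 0.5 + 0.01 * ages + rnorm(60, 0, 0.08)
  })
  m <- fit_normative(ages, y, seed = 2)
  m_scaled <- fit_normative(ages, 2 * y + 3, seed = 2)
  q_ages <- c(8, 15, 22)
  q_y <- c(0.55, 0.6, 0.7)
  expect_equal(deviation_z(m, q_ages, q_y)$z,
               deviation_z(m_scaled, q_ages, 2 * q_y + 3)$z, tolerance = 1e-4)
  zs <- deviation_z(m, rep(12, 5), seq(0.3, 0.9, length.out = 5))$z
  expect_true(all(diff(zs) > 0))
})

test_that("apply_normative corrects both groups and stays local", {
  withr::with_seed(8, {
    n <- 60
    tab <- tibble::tibble(
      participant_id = sprintf("P%02d", 1:n),
      group = rep(c("TD", "ASD"), each = n / 2),
      age = runif(n, 5, 25),
      motor_global = 0.6 + 0.01 * runif(n, 5, 25) + rnorm(n, 0, 0.05)
    )
  })
  nm <- apply_normative(tab, score_cols = "motor_global", seed = 1)
  expect_true(all(is.finite(nm$motor_global_nm)))
  # shifting one case's score moves only that case's z
  tab2 <- tab
  i <- which(tab2$group == "ASD")[1]
  tab2$motor_global[i] <- tab2$motor_global[i] + 0.3
  nm2 <- apply_normative(tab2, score_cols = "motor_global", seed = 1)
  expect_gt(nm2$motor_global_nm[i], nm$motor_global_nm[i])
  expect_equal(nm2$motor_global_nm[-i], nm$motor_global_nm[-i], tolerance = 1e-10)
  # missing scores propagate as missing z
  tab3 <- tab
  tab3$motor_global[i] <- NA
  nm3 <- apply_normative(tab3, score_cols = "motor_global", seed = 1)
  expect_true(is.na(nm3$motor_global_nm[i]))
})

test_that("leave-one-out control z-scores are near-standard under the null", {
  withr::with_seed(13, {
    n <- 200
    tab <- tibble::tibble(
      participant_id = sprintf("P%03d", 1:n),
      group = "TD",
      age = runif(n, 5, 25),
      s = rnorm(n, 0.7, 0.1)
    )
  })
  nm <- apply_normative(tab, score_cols = "s", seed = 3)
  z <- nm$s_nm
  expect_lt(abs(mean(z)), 0.1)
  expect_true(sd(z) > 0.85 && sd(z) < 1.15)
})

test_that("percentile ranks match the counting definition", {
  expect_equal(percentile_ranks(1:11, 6), 50)
  expect_lt(percentile_ranks(1:11, 0), 100 / 11)
  expect_error(percentile_ranks(1:5, 3), "at least 10")
  withr::with_seed(10, {
    for (i in 1:10) {
      ref <- sample(0:20, 30, replace = TRUE)
      q <- sample(0:20, 5, replace = TRUE)
      oracle <- vapply(q, function(v) {
        100 * (sum(ref < v) + 0.5 * sum(ref == v)) / length(ref)
      }, numeric(1))
      expect_identical(percentile_ranks(ref, q), oracle)
    }
  })
})
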