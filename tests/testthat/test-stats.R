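test_that("Yates chi-square matches the closed form and the worked table", {
  # reference cohort sex table: printed statistic 9.37
  expect_equal(chi_square_yates(matrix(c(96, 25, 18, 17), 2)), 9.37,
               tolerance = 0.01)
  expect_equal(chi_square_yates(matrix(c(10, 10, 10, 10), 2)), 0)
  yates_oracle <- function(tab) {
    n <- sum(tab)
    # the corrected deviation is floored at zero before squaring
    dev <- max(0, abs(tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1]) - n / 2)
    n * dev^2 / prod(rowSums(tab)) / prod(colSums(tab))
  }
  withr::with_seed(14, {
    for (i in 1:20) {
      tab <- matrix(rpois(4, 20) + 1, 2)
      expect_equal(chi_square_yates(tab), yates_oracle(tab), tolerance = 1e-10)
    }
  })
  expect_error(chi_square_yates(matrix(c(0, 0, 5, 5), 2)), "margins")
})

test_that("group_compare reports pooled-SD Cohen's d with the case-minus-control sign", {
  same <- group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$cohen_d, 0)
  d <- group_compare(c(0, 1), c(1, 2))
  expect_equal(d$cohen_d, -sqrt(2), tolerance = 1e-10)
  expect_error(group_compare(c(1, 1), c(1, 1)), "pooled variance")
})

test_that("permutation p matches exhaustive enumeration on a small problem", {
  x <- c(0.1, 1.2, 0.8, 1.9)
  y <- c(2.0, 2.5, 3.1)
  obs <- mean(x) - mean(y)
  pooled <- c(x, y)
  combos <- utils::combn(7, 4)
  diffs <- apply(combos, 2, function(idx) mean(pooled[idx]) - mean(pooled[-idx]))
  exact <- mean(abs(diffs) >= abs(obs) - 1e-12)
  perm <- group_compare(x, y, method = "permutation", n_perm = 10000, seed = 2)
  expect_equal(perm$p_value, exact, tolerance = 0.02)
  # seeded: reproducible
  perm2 <- group_compare(x, y, method = "permutation", n_perm = 10000, seed = 2)
  expect_identical(perm$p_value, perm2$p_value)
})

test_that("all three group tests agree on an obvious separation", {
  withr::with_seed(15, {
    x <- rnorm(40, 0, 1)
    y <- rnorm(40, 2, 1)
  })
  for (m in c("welch_t", "mann_whitney", "permutation")) {
    res <- group_compare(x, y, method = m, seed = 1)
    expect_lt(res$p_value, 0.001)
    expect_lt(res$cohen_d, -1)
    expect_true(res$p_value >= 0 && res$p_value <= 1)
  }
})

test_that("pearson_with_p matches the arithmetic definition", {
  x <- c(1, 2, 4, 7, 11)
  y <- c(2.2, 2.9, 5.4, 6.1, 9.0)
  res <- pearson_with_p(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  tstat <- r_oracle * sqrt(3 / (1 - r_oracle^2))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), 3), tolerance = 1e-12)

  expect_equal(pearson_with_p(1:10, 2 * (1:10) + 1)$r, 1)
  withr::with_seed(16, {
    big <- pearson_with_p(rnorm(10000), rnorm(10000))
  })
  expect_lt(abs(big$r), 0.03)
  expect_error(pearson_with_p(1:5, rep(1, 5)), "variance")
})

test_that("subcondition regression recovers coefficients and degrees of freedom", {
  withr::with_seed(17, {
    long <- tidyr::expand_grid(
      participant_id = sprintf("P%03d", 1:156),
      behavior = c(0, 1), task = c(0, 1)
    )
    long$diagnosis <- rep(rep(c(0, 1), c(113, 43)), each = 4)
    long$age <- rep(runif(156, 5, 25), each = 4)
    long$outcome <- 0.4 * long$diagnosis + 0.27 * long$task
  })
  fit <- subcondition_regression(long)
  g <- suppressWarnings(glance(fit))
  expect_identical(c(g$df_model, g$df_residual), c(5L, 618L))
  td <- suppressWarnings(tidy(fit))
  expect_equal(td$estimate[td$term == "diagnosis"], 0.4, tolerance = 1e-10)
  expect_equal(td$estimate[td$term == "task"], 0.27, tolerance = 1e-10)
  expect_equal(td$estimate[td$term == "age"], 0, tolerance = 1e-10)

  # flipping the diagnosis coding exactly negates its coefficient
  flipped <- long
  flipped$diagnosis <- 1 - flipped$diagnosis
  fit2 <- subcondition_regression(flipped)
  td2 <- suppressWarnings(tidy(fit2))
  expect_equal(td2$estimate[td2$term == "diagnosis"],
               -td$estimate[td$term == "diagnosis"], tolerance = 1e-10)

  # collinear design is refused with the offending column named
  collinear <- long
  collinear$age <- collinear$diagnosis * 2
  expect_error(subcondition_regression(collinear), "collinear")
})

test_that("regression coefficients match the normal-equations oracle", {
  withr::with_seed(18, {
    n <- 80
    long <- tibble::tibble(
      diagnosis = rbinom(n, 1, 0.5), age = runif(n, 5, 25),
      behavior = rbinom(n, 1, 0.5), task = rbinom(n, 1, 0.5),
      outcome = rnorm(n)
    )
  })
  fit <- subcondition_regression(long)
  X <- cbind(1, long$diagnosis, long$age, long$behavior, long$task,
             long$behavior * long$task)
  beta <- solve(t(X) %*% X, t(X) %*% long$outcome)
  expect_equal(unname(tidy(fit)$estimate), drop(beta), tolerance = 1e-8)
})

test_that("table3_report flags nothing on duplicated groups", {
  withr::with_seed(19, {
    n <- 30
    half <- tibble::tibble(
      participant_id = sprintf("A%02d", 1:n), group = "ASD",
      age = runif(n, 5, 25),
      motor_inphase_coop_nm = rnorm(n), motor_inphase_comp_nm = rnorm(n),
      motor_antiphase_coop_nm = rnorm(n), motor_antiphase_comp_nm = rnorm(n)
    )
  })
  dup <- dplyr::bind_rows(half, dplyr::mutate(half, group = "TD"))
  t3 <- table3_report(dup, scores = "motor", method = "welch_t",
                      alternative = "two.sided")
  expect_identical(nrow(t3), 4L)
  expect_true(all(abs(t3$cohen_d) < 1e-12))
})

test_that("an injected in-phase-only deficit localizes in the in-phase cells", {
  hits <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      n <- 60
      base <- tibble::tibble(
        participant_id = sprintf("P%02d", 1:n),
        group = rep(c("ASD", "TD"), each = n / 2),
        motor_inphase_coop_nm = rnorm(n) - 0.8 * (rep(c(1, 0), each = n / 2)),
        motor_inphase_comp_nm = rnorm(n) - 0.8 * (rep(c(1, 0), each = n / 2)),
        motor_antiphase_coop_nm = rnorm(n),
        motor_antiphase_comp_nm = rnorm(n)
      )
    })
    t3 <- table3_report(base, scores = "motor", method = "welch_t",
                        alternative = "two.sided")
    worst <- t3[which.max(abs(t3$cohen_d)), ]
    worst$task == "in_phase"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("stratification separates well-separated blobs and respects labels", {
  withr::with_seed(20, {
    X <- rbind(matrix(rnorm(100, 0), ncol = 2), matrix(rnorm(100, 6), ncol = 2))
  })
  diag <- rep(c("a", "b"), each = 50)
  st <- stratify(X, diag)
  expect_equal(st$ari, 1)
  expect_lt(st$fisher_p, 1e-10)
  # cluster labels are arbitrary: permuting them leaves ARI unchanged
  expect_equal(mclust::adjustedRandIndex(3 - st$labels, diag), st$ari)
  # shuffled diagnosis: chance agreement
  aris <- vapply(1:20, function(s) {
    withr::with_seed(s, stratify(X, sample(diag))$ari)
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.05)
  expect_error(stratify(X[1:3, ], diag[1:3]), "at least 4")
})

test_that("classification is perfect on separable data, chance on shuffled labels", {
  withr::with_seed(22, {
    X <- data.frame(
      signal = c(rnorm(40, 0, 0.2), rnorm(40, 5, 0.2)),
      noise = rnorm(80)
    )
  })
  y <- rep(c("ASD", "TD"), each = 40)
  res <- classify_diagnosis(X, y, seed = 1)
  expect_equal(res$auc[res$feature == "signal"], 1)
  expect_equal(res$auc[res$feature == "all"], 1)
  expect_lt(res$auc[res$feature == "noise"], 0.7)
  # determinism
  expect_identical(res, classify_diagnosis(X, y, seed = 1))
  # label shuffles give chance AUC on average
  aucs <- vapply(1:15, function(s) {
    ys <- withr::with_seed(s, sample(y))
    mean(classify_diagnosis(X["noise"], ys, seed = s)$auc[1])
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("demographics table runs the matching tests per variable", {
  coh <- sample_cohort(cohort_spec(), seed = 2)
  tab <- demographics_table(coh)
  expect_true(all(c("sex", "age", "srs_t", "iq") %in% tab$variable))
  expect_identical(tab$test[tab$variable == "sex"], "chi_square_yates")
  expect_identical(tab$test[tab$variable == "age"], "welch_t")
  # the srs separation is large by construction
  expect_lt(tab$p_value[tab$variable == "srs_t"], 1e-10)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1, na.rm = TRUE))
})
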