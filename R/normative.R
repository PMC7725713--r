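# Gaussian-process normative modeling: control-group reference surface over
# age, deviation z-scores, percentile norms.
#
# Exact GP regression with a squared-exponential kernel plus independent
# noise,
#   k(x, x') = sf2 * exp(-(x - x')^2 / (2 l^2)) + sn2 * 1[x = x'],
# a constant mean fixed at the training mean, and hyperparameters from
# multi-start maximization of the log marginal likelihood (analytic
# gradients in log-parameter space, L-BFGS-B within bounds).

gp_nlml <- function(theta, x, yc) {
  sf2 <- exp(theta[1]); ell <- exp(theta[2]); sn2 <- exp(theta[3])
  n <- length(x)
  D2 <- outer(x, x, "-")^2
  Kse <- sf2 * exp(-D2 / (2 * ell^2))
  K <- Kse + diag(sn2, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(list(value = 1e10, gradient = c(0, 0, 0)))
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  nlml <- 0.5 * sum(yc * alpha) + sum(log(diag(L))) + n / 2 * log(2 * pi)
  Kinv <- chol2inv(L)
  A <- Kinv - tcrossprod(alpha)      # d(nlml)/dK = A / 2
  g <- c(
    0.5 * sum(A * Kse),              # wrt log sf2
    0.5 * sum(A * (Kse * D2 / ell^2)), # wrt log ell
    0.5 * sum(diag(A)) * sn2         # wrt log sn2
  )
  list(value = nlml, gradient = g)
}

gp_fit_optim <- function(x, yc, starts, bounds) {
  # optim calls fn and gr at the same point back to back; cache one evaluation
  last <- list(theta = NULL, res = NULL)
  eval_cached <- function(th) {
    if (is.null(last$theta) || !identical(th, last$theta)) {
      last <<- list(theta = th, res = gp_nlml(th, x, yc))
    }
    last$res
  }
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[s, ],
            fn = function(th) eval_cached(th)$value,
            gr = function(th) eval_cached(th)$gradient,
            method = "L-BFGS-B",
            lower = bounds$lower, upper = bounds$upper,
            control = list(maxit = 200)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop_hdc("GP hyperparameter optimization failed")
  best
}

#' Fit a normative Gaussian-process model
#'
#' Fits the control-group score distribution over age. The model separates a
#' smooth population trajectory (squared-exponential component, length-scale
#' `ell` in years), population heterogeneity plus measurement noise
#' (independent noise variance), and the uncertainty of the fit itself (the
#' posterior variance, which widens away from the training ages).
#'
#' @param ages Numeric vector of covariates (years), controls only.
#' @param scores Numeric vector of observed scores, same length.
#' @param lengthscale_bounds,variance_bounds Hyperparameter box constraints;
#'   defaults: length-scale in \[1, 30\] years, variances in \[1e-6, 10\].
#' @param n_restarts Number of optimizer starts (1 heuristic + the rest
#'   random within bounds), seeded.
#' @param seed Integer seed making the restarts deterministic.
#' @param init Optional named list (`sigma_f2`, `ell`, `sigma_n2`) used as
#'   the first start (warm start for refits).
#' @return An object of class `"hdc_gp"`; see [tidy()] and [glance()]
#'   methods, [predict.hdc_gp()] and [deviation_z()].
#' @examples
#' m <- fit_normative(runif(30, 6, 24), rnorm(30, 0.7, 0.05), seed = 1)
#' glance(m)
#' @export
fit_normative <- function(ages, scores, lengthscale_bounds = c(1, 30),
                          variance_bounds = c(1e-6, 10), n_restarts = 5,
                          seed = 1, init = NULL) {
  if (length(ages) != length(scores)) stop_hdc("ages and scores differ in length")
  if (length(ages) < 10) {
    stop_hdc("need at least 10 control observations (got %d)", length(ages))
  }
  if (any(!is.finite(ages)) || any(!is.finite(scores))) {
    stop_hdc("ages and scores must be finite")
  }
  m <- mean(scores)
  yc <- scores - m
  vb <- sort(variance_bounds); lb <- sort(lengthscale_bounds)
  clip <- function(v, b) min(max(v, b[1]), b[2])
  bounds <- list(lower = log(c(vb[1], lb[1], vb[1])),
                 upper = log(c(vb[2], lb[2], vb[2])))
  vy <- clip(var(yc), vb)
  heuristic <- log(c(clip(max(vy, vb[1] * 10), vb),
                     clip(diff(range(ages)) / 3, lb),
                     clip(max(0.2 * vy, vb[1] * 10), vb)))
  starts <- with_seed_if(seed, {
    rand <- matrix(runif(3 * max(0, n_restarts - 1)), ncol = 3)
    rbind(heuristic,
          t(bounds$lower + t(rand) * (bounds$upper - bounds$lower)))
  })
  if (!is.null(init)) {
    starts <- rbind(log(c(init$sigma_f2, init$ell, init$sigma_n2)), starts)
  }
  best <- gp_fit_optim(ages, yc, starts, bounds)
  sf2 <- exp(best$par[1]); ell <- exp(best$par[2]); sn2 <- exp(best$par[3])
  n <- length(ages)
  K <- sf2 * exp(-outer(ages, ages, "-")^2 / (2 * ell^2)) + diag(sn2, n)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  structure(
    list(x = ages, y = scores, y_mean = m,
         sigma_f2 = sf2, ell = ell, sigma_n2 = sn2,
         L = L, alpha = alpha,
         log_marginal_likelihood = -best$value,
         bounds = list(lengthscale = lb, variance = vb)),
    class = "hdc_gp"
  )
}

#' Predict from a normative GP
#'
#' @param object An `"hdc_gp"` model.
#' @param newdata Numeric vector of ages (or a data frame with an `age`
#'   column).
#' @param include_noise Include the noise variance in the predictive spread
#'   (the total spread an individual observation is compared against).
#' @param ... Unused.
#' @return A tibble with `age`, `.pred` (predictive mean) and `.pred_sd`.
#' @export
predict.hdc_gp <- function(object, newdata, include_noise = TRUE, ...) {
  age <- if (is.data.frame(newdata)) newdata$age else newdata
  Ks <- object$sigma_f2 *
    exp(-outer(age, object$x, "-")^2 / (2 * object$ell^2))
  mu <- object$y_mean + drop(Ks %*% object$alpha)
  V <- forwardsolve(t(object$L), t(Ks))
  var_f <- pmax(0, object$sigma_f2 - colSums(V^2))
  sd_tot <- sqrt(var_f + if (include_noise) object$sigma_n2 else 0)
  tibble(age = age, .pred = mu, .pred_sd = sd_tot)
}

#' Deviation z-score under a normative model
#'
#' Standardized deviation of an observed score from the normative predictive
#' distribution at the participant's age:
#' `z = (score - predictive_mean) / predictive_sd`, the predictive sd
#' including the noise variance. Ages outside the training range are allowed;
#' the predictive sd widens toward the prior there.
#'
#' @param model A fitted `"hdc_gp"`.
#' @param age,score Numeric vectors (recycled to common length).
#' @return A tibble with `z`, `predictive_mean`, `predictive_sd`.
#' @export
deviation_z <- function(model, age, score) {
  if (!inherits(model, "hdc_gp")) stop_hdc("`model` must be a fitted hdc_gp")
  n <- max(length(age), length(score))
  age <- rep_len(age, n); score <- rep_len(score, n)
  pr <- predict(model, age)
  tibble(z = (score - pr$.pred) / pr$.pred_sd,
         predictive_mean = pr$.pred, predictive_sd = pr$.pred_sd)
}

#' @export
print.hdc_gp <- function(x, ...) {
  cat(sprintf(
    "<hdc_gp> n = %d; signal sd %.3g, length-scale %.3g yr, noise sd %.3g; lml %.2f\n",
    length(x$x), sqrt(x$sigma_f2), x$ell, sqrt(x$sigma_n2),
    x$log_marginal_likelihood))
  invisible(x)
}

#' @rdname fit_normative
#' @param x An `"hdc_gp"`.
#' @param ... Unused.
#' @export
tidy.hdc_gp <- function(x, ...) {
  tibble(term = c("signal_variance", "length_scale", "noise_variance"),
         estimate = c(x$sigma_f2, x$ell, x$sigma_n2))
}

#' @rdname fit_normative
#' @export
glance.hdc_gp <- function(x, ...) {
  tibble(n = length(x$x), log_marginal_likelihood = x$log_marginal_likelihood,
         signal_sd = sqrt(x$sigma_f2), length_scale = x$ell,
         noise_sd = sqrt(x$sigma_n2))
}

#' @rdname fit_normative
#' @param object An `"hdc_gp"`.
#' @export
autoplot.hdc_gp <- function(object, ...) {
  grid <- seq(min(object$x) - 2, max(object$x) + 2, length.out = 200)
  pr <- predict(object, grid)
  ggplot2::ggplot(pr, ggplot2::aes(.data$age, .data$.pred)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$.pred - 1.96 * .data$.pred_sd,
                                      ymax = .data$.pred + 1.96 * .data$.pred_sd),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = tibble(age = object$x, .pred = object$y)) +
    ggplot2::labs(x = "age (years)", y = "score",
                  title = "Normative trajectory (95% predictive band)")
}

#' Apply normative models to a cohort score table
#'
#' Fits one normative GP per score column on the control group and appends a
#' `<column>_nm` deviation z-score column for every participant. Controls are
#' scored by leave-one-out refits (each control's z comes from a model fitted
#' without it) to avoid in-sample shrinkage; cases are scored against the
#' full control fit. Missing scores (e.g. an unvisited subcondition cell)
#' propagate as missing z.
#'
#' @param score_table Output of [score_cohort()] (or any table with `age`,
#'   a group column and score columns).
#' @param score_cols Character vector of score columns to correct; default:
#'   every `<score>_<global|cell>` column present.
#' @param group_col,control_group Column and level identifying controls.
#' @param loo Leave-one-out refits for controls (`TRUE` by default).
#' @param n_restarts,seed Passed to [fit_normative()].
#' @return `score_table` with `_nm` columns appended; fitted models are
#'   attached as attribute `"models"`.
#' @export
apply_normative <- function(score_table, score_cols = NULL,
                            group_col = "group", control_group = "TD",
                            loo = TRUE, n_restarts = 5, seed = 1) {
  if (is.null(score_cols)) {
    score_cols <- grep(paste0("^(", paste(ALL_SCORES, collapse = "|"),
                              ")_(global|", paste(CELL_LEVELS, collapse = "|"), ")$"),
                       names(score_table), value = TRUE)
  }
  if (!length(score_cols)) stop_hdc("no score columns found")
  if (!group_col %in% names(score_table)) {
    stop_hdc("column `%s` not found", group_col)
  }
  is_ctrl <- score_table[[group_col]] == control_group
  age <- score_table$age
  models <- list()
  out <- score_table
  for (col in score_cols) {
    y <- score_table[[col]]
    ok <- is_ctrl & is.finite(y) & is.finite(age)
    fit <- fit_normative(age[ok], y[ok], n_restarts = n_restarts,
                         seed = derive_seed(seed, match(col, score_cols)))
    models[[col]] <- fit
    z <- rep(NA_real_, nrow(score_table))
    case <- !is_ctrl & is.finite(y) & is.finite(age)
    if (any(case)) z[case] <- deviation_z(fit, age[case], y[case])$z
    ctrl_idx <- which(ok)
    if (loo) {
      warm <- list(sigma_f2 = fit$sigma_f2, ell = fit$ell,
                   sigma_n2 = fit$sigma_n2)
      for (j in seq_along(ctrl_idx)) {
        i <- ctrl_idx[j]
        refit <- fit_normative(age[ctrl_idx[-j]], y[ctrl_idx[-j]],
                               n_restarts = 1,
                               seed = derive_seed(seed, match(col, score_cols), j),
                               init = warm)
        z[i] <- deviation_z(refit, age[i], y[i])$z
      }
    } else {
      z[ctrl_idx] <- deviation_z(fit, age[ctrl_idx], y[ctrl_idx])$z
    }
    out[[paste0(col, "_nm")]] <- z
  }
  attr(out, "models") <- models
  out
}

#' Percentile rank against a control reference
#'
#' Midpoint percentile: `100 * (n_below + 0.5 * n_equal) / n`.
#'
#' @param reference Numeric vector of control scores (at least 10).
#' @param query Numeric vector of scores to rank.
#' @return Numeric vector of percentiles in (0, 100).
#' @examples
#' percentile_ranks(1:11, 6) # 50
#' @export
percentile_ranks <- function(reference, query) {
  if (length(reference) < 10) stop_hdc("need at least 10 reference values")
  vapply(query, function(q) {
    100 * (sum(reference < q) + 0.5 * sum(reference == q)) / length(reference)
  }, numeric(1))
}
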