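# The downstream statistical battery: demographics tests, developmental
# correlations, normative group comparisons, coded-covariate regressions,
# per-cell grids, stratification, classification.

#' Yates-corrected chi-square statistic for a 2x2 table
#'
#' Continuity-corrected chi-square,
#' \eqn{n(|ad - bc| - n/2)^2 / (r_1 r_2 c_1 c_2)}, the corrected deviation
#' \eqn{|ad - bc| - n/2} floored at 0 before squaring (delegates to
#' [stats::chisq.test()] with `correct = TRUE`).
#'
#' @param table_2x2 A 2x2 matrix of non-negative integer counts with all
#'   margins positive.
#' @return The chi-square statistic (single number).
#' @examples
#' chi_square_yates(matrix(c(96, 25, 18, 17), 2)) # ~9.38
#' @export
chi_square_yates <- function(table_2x2) {
  tab <- as.matrix(table_2x2)
  if (!all(dim(tab) == c(2, 2))) stop_hdc("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop_hdc("counts must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_hdc("all margins must be positive")
  }
  unname(suppressWarnings(chisq.test(tab, correct = TRUE)$statistic))
}

cohens_d_pooled <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop_hdc("zero pooled variance: Cohen's d undefined")
  (mean(x) - mean(y)) / sqrt(sp2)
}

perm_p_value <- function(x, y, n_perm, alternative, seed) {
  obs <- mean(x) - mean(y)
  pooled <- c(x, y)
  n1 <- length(x)
  diffs <- with_seed_if(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pooled), n1)
    mean(pooled[idx]) - mean(pooled[-idx])
  }, numeric(1)))
  # add-one correction keeps p > 0
  switch(alternative,
    two.sided = (1 + sum(abs(diffs) >= abs(obs))) / (n_perm + 1),
    greater   = (1 + sum(diffs >= obs)) / (n_perm + 1),
    less      = (1 + sum(diffs <= obs)) / (n_perm + 1),
    observed  = (1 + sum(sign(obs) * diffs >= abs(obs))) / (n_perm + 1)
  )
}

#' Compare two groups: Cohen's d and a p-value
#'
#' Always reports the pooled-SD Cohen's d with the convention "cases minus
#' controls" (negative d means the ASD group is lower); the p-value comes
#' from the selected test. The permutation test uses `n_perm` seeded
#' resamples of the group labels; `alternative = "observed"` directs a
#' one-sided permutation test toward the sign of the observed difference.
#'
#' @param values_asd,values_td Numeric vectors (at least 2 each).
#' @param method `"welch_t"`, `"mann_whitney"` or `"permutation"`.
#' @param alternative `"two.sided"`, `"greater"`, `"less"`, or (permutation
#'   only) `"observed"`.
#' @param n_perm,seed Permutation resamples and seed.
#' @return A one-row tibble: `cohen_d`, `p_value`, `test`, `n_asd`, `n_td`.
#' @examples
#' group_compare(c(0, 1), c(1, 2)) # d = -1.414
#' @export
group_compare <- function(values_asd, values_td,
                          method = c("welch_t", "mann_whitney", "permutation"),
                          alternative = "two.sided",
                          n_perm = 10000, seed = 1) {
  method <- match.arg(method)
  x <- values_asd[is.finite(values_asd)]
  y <- values_td[is.finite(values_td)]
  if (length(x) < 2 || length(y) < 2) stop_hdc("need at least 2 values per group")
  d <- cohens_d_pooled(x, y)
  p <- switch(method,
    welch_t = t.test(x, y, alternative =
                       if (alternative == "observed") "two.sided" else alternative)$p.value,
    mann_whitney = suppressWarnings(
      wilcox.test(x, y, alternative =
                    if (alternative == "observed") "two.sided" else alternative)$p.value),
    permutation = perm_p_value(x, y, n_perm, alternative, seed)
  )
  tibble(cohen_d = d, p_value = p, test = method,
         n_asd = length(x), n_td = length(y))
}

#' Pearson correlation with its two-sided p-value
#'
#' Product-moment correlation; p from the t transform with n - 2 degrees of
#' freedom.
#'
#' @param x,y Numeric vectors, n >= 3, finite (pairwise-complete rows used).
#' @return A one-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_hdc("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop_hdc("zero variance: correlation undefined")
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  tibble(r = r, p_value = 2 * pt(-abs(tstat), n - 2), n = n)
}

#' Build the long participant-by-cell table for subcondition regression
#'
#' Pivots a normative score table into one row per participant and
#' subcondition cell, with the coded covariates of the subcondition
#' analysis: `diagnosis` (0 = ASD, 1 = CTR), `age` (years), `behavior`
#' (0 = competitive, 1 = cooperative), `task` (0 = anti-phase,
#' 1 = in-phase), and the chosen score's cell value as `outcome`.
#'
#' @param nm_table Output of [apply_normative()] (or a raw score table).
#' @param score One of the five score names.
#' @param use_nm Use the `_nm` deviation columns (default) or raw cell scores.
#' @return A tibble with `participant_id`, `diagnosis`, `age`, `behavior`,
#'   `task`, `outcome` (one row per participant x cell; 4 cells).
#' @export
subcondition_long <- function(nm_table, score = "motor", use_nm = TRUE) {
  score <- match.arg(score, ALL_SCORES)
  suffix <- if (use_nm) "_nm" else ""
  cols <- paste0(score, "_", CELL_LEVELS, suffix)
  missing <- setdiff(cols, names(nm_table))
  if (length(missing)) stop_hdc("missing columns: %s", paste(missing, collapse = ", "))
  long <- tidyr::pivot_longer(
    nm_table[, c("participant_id", "group", "age", cols)],
    dplyr::all_of(cols), names_to = "cell", values_to = "outcome"
  )
  cell <- sub(paste0("^", score, "_"), "", sub(paste0(suffix, "$"), "", long$cell))
  tibble(
    participant_id = long$participant_id,
    diagnosis = as.numeric(long$group != "ASD"),
    age = long$age,
    behavior = as.numeric(grepl("_coop$", cell)),
    task = as.numeric(grepl("^inphase", cell)),
    outcome = long$outcome
  )
}

#' Coded-covariate multiple regression over subcondition cells
#'
#' Ordinary least squares with intercept on the coded design
#' `outcome ~ diagnosis + age + behavior + task` plus, by default, the
#' `behavior:task` interaction as fifth predictor (624 rows at a 156 x 4
#' scale give residual df 618).
#'
#' @param long_table A [subcondition_long()] table (rows with missing
#'   outcome are dropped).
#' @param predictors Names of the coded predictor columns.
#' @param outcome Name of the outcome column.
#' @param interaction Include the `behavior:task` interaction (when both are
#'   among the predictors).
#' @return An `"hdc_regression"` wrapping the [lm] fit with the coding map;
#'   see its [tidy()] and [glance()] methods.
#' @export
subcondition_regression <- function(long_table,
                                    predictors = c("diagnosis", "age",
                                                   "behavior", "task"),
                                    outcome = "outcome",
                                    interaction = TRUE) {
  missing <- setdiff(c(predictors, outcome), names(long_table))
  if (length(missing)) stop_hdc("missing columns: %s", paste(missing, collapse = ", "))
  dat <- long_table[complete.cases(long_table[, c(predictors, outcome)]), ]
  terms <- predictors
  if (interaction && all(c("behavior", "task") %in% predictors)) {
    terms <- c(terms, "behavior:task")
  }
  fml <- as.formula(paste(outcome, "~", paste(terms, collapse = " + ")))
  mm <- model.matrix(fml, dat)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[seq.int(qr_mm$rank + 1L, ncol(mm))]]
    stop_hdc("rank-deficient design: collinear columns %s",
             paste(bad, collapse = ", "))
  }
  fit <- lm(fml, data = dat)
  structure(
    list(fit = fit,
         coding = c(diagnosis = "0 = ASD / 1 = CTR",
                    behavior = "0 = competitive / 1 = cooperative",
                    task = "0 = anti-phase / 1 = in-phase",
                    age = "years")),
    class = "hdc_regression"
  )
}

#' @export
print.hdc_regression <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<hdc_regression> F(%d, %d) = %.3f, p = %.3g\n",
              g$df_model, g$df_residual, g$f_statistic, g$p_value))
  print(tidy(x))
  invisible(x)
}

#' @rdname subcondition_regression
#' @param x,object An `"hdc_regression"`.
#' @param ... Unused.
#' @export
tidy.hdc_regression <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = unname(s[, 1]),
         std_error = unname(s[, 2]), statistic = unname(s[, 3]),
         p_value = unname(s[, 4]))
}

#' @rdname subcondition_regression
#' @export
glance.hdc_regression <- function(x, ...) {
  s <- summary(x$fit)
  f <- s$fstatistic
  tibble(r_squared = s$r.squared,
         f_statistic = unname(f[1]),
         df_model = as.integer(f[2]), df_residual = as.integer(f[3]),
         p_value = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
         n = length(s$residuals))
}

#' Per-cell group comparison grid (Table-3 style)
#'
#' Runs [group_compare()] on every instruction-by-behavior cell for every
#' score, on the normative deviation columns. Default test: one-sided
#' permutation with the direction taken from the observed d.
#'
#' @param nm_table Output of [apply_normative()].
#' @param scores Scores to include.
#' @param method,alternative,n_perm,seed Passed to [group_compare()].
#' @param group_col,case_group Grouping column and case level.
#' @return A tibble with one row per score x cell: `score`, `task`,
#'   `behavior`, `cohen_d`, `p_value`, `n_asd`, `n_td` (missing cells give
#'   NA rows).
#' @export
table3_report <- function(nm_table, scores = ALL_SCORES,
                          method = "permutation", alternative = "observed",
                          n_perm = 10000, seed = 1,
                          group_col = "group", case_group = "ASD") {
  is_case <- nm_table[[group_col]] == case_group
  rows <- list()
  for (s in scores) {
    for (cl in CELL_LEVELS) {
      col <- paste0(s, "_", cl, "_nm")
      if (!col %in% names(nm_table)) next
      task <- if (grepl("^inphase", cl)) "in_phase" else "anti_phase"
      beh <- if (grepl("_coop$", cl)) "cooperative" else "competitive"
      v <- nm_table[[col]]
      cmp <- tryCatch(
        group_compare(v[is_case], v[!is_case], method = method,
                      alternative = alternative, n_perm = n_perm,
                      seed = derive_seed(seed, match(s, scores), match(cl, CELL_LEVELS))),
        error = function(e) tibble(cohen_d = NA_real_, p_value = NA_real_,
                                   test = method,
                                   n_asd = sum(is.finite(v[is_case])),
                                   n_td = sum(is.finite(v[!is_case])))
      )
      rows[[paste(s, cl)]] <- dplyr::bind_cols(
        tibble(score = s, task = task, behavior = beh), cmp)
    }
  }
  dplyr::bind_rows(rows)
}

#' Ward hierarchical stratification of normative scores
#'
#' Standardizes the normative score matrix, builds a Ward-linkage hierarchy
#' (`ward.D2` on Euclidean distances), cuts it at k = 2 and quantifies
#' agreement with the diagnosis through the adjusted Rand index and a 2x2
#' Fisher exact test.
#'
#' @param nm_matrix Numeric matrix or data frame of normative scores
#'   (complete cases required).
#' @param diagnosis Vector of diagnostic labels (2 levels).
#' @param k Number of clusters to cut (default 2).
#' @return An `"hdc_strat"`: list with `labels`, `ari`, `fisher_p`, `tree`.
#' @export
stratify <- function(nm_matrix, diagnosis, k = 2) {
  X <- as.matrix(nm_matrix)
  if (nrow(X) < 4) stop_hdc("need at least 4 observations")
  if (any(!is.finite(X))) stop_hdc("complete-case matrix required")
  if (nrow(X) != length(diagnosis)) stop_hdc("diagnosis length mismatch")
  Xs <- scale(X)
  Xs[, !is.finite(colSums(Xs))] <- 0 # constant columns carry no signal
  tree <- hclust(dist(Xs), method = "ward.D2")
  labels <- cutree(tree, k = k)
  ari <- mclust::adjustedRandIndex(labels, diagnosis)
  fp <- if (k == 2 && length(unique(diagnosis)) == 2) {
    fisher.test(table(labels, diagnosis))$p.value
  } else {
    NA_real_
  }
  structure(list(labels = labels, ari = ari, fisher_p = fp, tree = tree),
            class = "hdc_strat")
}

#' @export
print.hdc_strat <- function(x, ...) {
  cat(sprintf("<hdc_strat> k = %d clusters, ARI = %.3f, Fisher p = %.3g\n",
              length(unique(x$labels)), x$ari, x$fisher_p))
  invisible(x)
}

#' @rdname stratify
#' @param x An `"hdc_strat"`.
#' @param ... Unused.
#' @export
tidy.hdc_strat <- function(x, ...) {
  tibble(cluster = x$labels)
}

#' @rdname stratify
#' @param object An `"hdc_strat"`.
#' @export
glance.hdc_strat <- function(object, ...) {
  tibble(ari = object$ari, fisher_p = object$fisher_p,
         n = length(object$labels))
}

stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' Cross-validated diagnostic classification from normative scores
#'
#' Logistic regression with stratified 5-fold cross-validation, reporting the
#' pooled out-of-fold AUC for each feature alone and for all features
#' combined.
#'
#' @param nm_matrix Numeric matrix/data frame of features (complete cases).
#' @param labels Two-level diagnostic labels.
#' @param seed Integer seed fixing the folds.
#' @param n_folds Number of folds (default 5).
#' @return A tibble with `feature` (each column and `"all"`) and `auc`.
#' @export
classify_diagnosis <- function(nm_matrix, labels, seed = 1, n_folds = 5) {
  X <- as.data.frame(nm_matrix)
  y <- factor(labels)
  if (nlevels(y) != 2) stop_hdc("need exactly two classes")
  if (any(!is.finite(as.matrix(X)))) stop_hdc("complete-case matrix required")
  for (attempt in 1:5) {
    fold <- with_seed_if(derive_seed(seed, attempt), stratified_folds(y, n_folds))
    ok <- all(vapply(seq_len(n_folds), function(f) {
      nlevels(droplevels(y[fold != f])) == 2 && sum(fold == f) > 0
    }, logical(1)))
    if (ok) break
    if (attempt == 5) stop_hdc("could not build folds with both classes present")
  }
  cv_auc <- function(cols) {
    pred <- numeric(length(y))
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      dat <- cbind(X[, cols, drop = FALSE], .y = as.numeric(y) - 1)
      fit <- suppressWarnings(glm(.y ~ ., data = dat[tr, , drop = FALSE],
                                  family = binomial()))
      pred[!tr] <- suppressWarnings(
        predict(fit, newdata = dat[!tr, , drop = FALSE], type = "response"))
    }
    as.numeric(pROC::auc(pROC::roc(y, pred, quiet = TRUE,
                                   levels = levels(y), direction = "<")))
  }
  feats <- names(X)
  tibble(
    feature = c(feats, "all"),
    auc = unname(c(vapply(feats, function(f) cv_auc(f), numeric(1)),
                   cv_auc(feats)))
  )
}

#' Demographics table (Table-1 style)
#'
#' Group-wise summaries with the matching test: Welch t for continuous
#' variables, Yates chi-square for sex and handedness.
#'
#' @param cohort A [sample_cohort()] table.
#' @return A tibble with `variable`, per-group summary strings, `statistic`,
#'   `test`, `p_value`.
#' @export
demographics_table <- function(cohort) {
  is_case <- cohort$group == "ASD"
  cont <- function(var) {
    x <- cohort[[var]][is_case]; y <- cohort[[var]][!is_case]
    tt <- t.test(x, y)
    tibble(variable = var,
           asd = sprintf("%.1f +/- %.1f", mean(x), sd(x)),
           td = sprintf("%.1f +/- %.1f", mean(y), sd(y)),
           statistic = unname(tt$statistic), test = "welch_t",
           p_value = tt$p.value)
  }
  cat2 <- function(var, level) {
    f <- as.character(cohort[[var]])
    lv <- c(level, setdiff(unique(f), level))
    tab <- rbind(asd = c(sum(is_case & f == lv[1]), sum(is_case & f != lv[1])),
                 td = c(sum(!is_case & f == lv[1]), sum(!is_case & f != lv[1])))
    tibble(variable = var,
           asd = paste(tab["asd", ], collapse = "/"),
           td = paste(tab["td", ], collapse = "/"),
           statistic = chi_square_yates(tab), test = "chi_square_yates",
           p_value = suppressWarnings(chisq.test(tab, correct = TRUE)$p.value))
  }
  dplyr::bind_rows(
    tibble(variable = "n", asd = as.character(sum(is_case)),
           td = as.character(sum(!is_case)), statistic = NA_real_,
           test = NA_character_, p_value = NA_real_),
    cat2("sex", "m"),
    cont("age"),
    if ("srs_t" %in% names(cohort)) cont("srs_t"),
    if ("iq" %in% names(cohort)) cont("iq"),
    if ("handedness" %in% names(cohort)) cat2("handedness", "right")
  )
}

#' Developmental correlations of scores with age (Figure-2 style)
#'
#' @param score_table A [score_cohort()] table.
#' @param scores Scores to correlate (their `_global` columns).
#' @param by_group Also report per-group correlations.
#' @return A tibble: `score`, `subset`, `r`, `p_value`, `n`.
#' @export
developmental_correlations <- function(score_table, scores = ALL_SCORES,
                                       by_group = TRUE) {
  one <- function(sub, label) {
    dplyr::bind_rows(lapply(scores, function(s) {
      col <- paste0(s, "_global")
      dplyr::bind_cols(tibble(score = s, subset = label),
                       pearson_with_p(sub$age, sub[[col]]))
    }))
  }
  out <- one(score_table, "all")
  if (by_group) {
    for (g in unique(score_table$group)) {
      out <- dplyr::bind_rows(out, one(score_table[score_table$group == g, ], g))
    }
  }
  out
}

#' Global normative group comparisons (Figure-4 style)
#'
#' [group_compare()] on each score's global normative deviation column,
#' ASD minus TD.
#'
#' @param nm_table Output of [apply_normative()].
#' @param scores Scores to compare.
#' @param method Test for the p-value (default Welch t).
#' @param seed Seed for the permutation variant.
#' @return A tibble: `score`, `cohen_d`, `p_value`, `test`, `n_asd`, `n_td`.
#' @export
nm_group_comparison <- function(nm_table, scores = ALL_SCORES,
                                method = "welch_t", seed = 1) {
  is_case <- nm_table$group == "ASD"
  dplyr::bind_rows(lapply(scores, function(s) {
    col <- paste0(s, "_global_nm")
    v <- nm_table[[col]]
    dplyr::bind_cols(tibble(score = s),
                     group_compare(v[is_case], v[!is_case], method = method,
                                   seed = derive_seed(seed, match(s, scores))))
  }))
}
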