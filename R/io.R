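# File formats and the end-to-end pipeline. Everything is plain text:
# traces CSV (t,x_human,x_vp) + JSON sidecar, session directories with one
# JSON of metadata, cohort/score/NM tables CSV, config YAML.

#' Write / read a movement trace
#'
#' The trace is a CSV with header `t,x_human,x_vp`; a JSON sidecar
#' (`<path>.json`) carries `dt`, `metronome_cutoff`, the simulation
#' parameters and the seed. Floating values round-trip at full precision.
#'
#' @param trace An `"hdc_trace"`.
#' @param path CSV path (sidecar written next to it).
#' @return `write_trace()` returns `path` invisibly; `read_trace()` the
#'   restored `"hdc_trace"`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "hdc_trace"))
  readr::write_csv(as_tibble(trace)[, c("t", "x_human", "x_vp")], path)
  meta <- list(dt = attr(trace, "dt"),
               metronome_cutoff = attr(trace, "metronome_cutoff"),
               params = attr(trace, "params"),
               seed = attr(trace, "seed"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop_hdc("trace file not found: %s", path)
  # base strtod parsing is correctly rounded, so the shortest-roundtrip
  # representation written by write_trace() restores values bit-exactly
  df <- utils::read.csv(path)
  if (!identical(names(df), c("t", "x_human", "x_vp"))) {
    stop_hdc("malformed trace file %s: expected columns t,x_human,x_vp", path)
  }
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop_hdc("missing sidecar for %s", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  new_trace(df$t, df$x_human, df$x_vp, meta$dt, meta$metronome_cutoff,
            params = meta$params, seed = meta$seed)
}

#' Write / read a full session
#'
#' One directory per participant: `session.json` (profile, trial table with
#' ratings and judgments, simulation config, seed) plus one trace CSV (and
#' sidecar) per trial, `trial_001.csv`, `trial_002.csv`, ...
#'
#' @param session An `"hdc_session"` with traces.
#' @param dir Target directory (created if needed).
#' @return `write_session()` returns `dir` invisibly; `read_session()` the
#'   restored `"hdc_session"`.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "hdc_session"))
  if (is.null(session$traces)) stop_hdc("session has no traces to persist")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(profile = session$profile,
               trials = as.list(session$trials),
               config = unclass_deep(session$config),
               seed = session$seed,
               n_trials = nrow(session$trials))
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (i in seq_along(session$traces)) {
    write_trace(session$traces[[i]], file.path(dir, sprintf("trial_%03d.csv", i)))
  }
  invisible(dir)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  meta_path <- file.path(dir, "session.json")
  if (!file.exists(meta_path)) stop_hdc("no session.json in %s", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("profile", "trials", "config", "n_trials")) {
    if (is.null(meta[[field]])) stop_hdc("session.json missing field `%s`", field)
  }
  trials <- as_tibble(meta$trials)
  for (col in intersect(c("trial", "block", "intention_rating"), names(trials))) {
    trials[[col]] <- as.integer(trials[[col]])
  }
  for (col in intersect(c("human_goal", "vp_goal", "stability",
                          "amp_human", "amp_vp"), names(trials))) {
    trials[[col]] <- as.numeric(trials[[col]])
  }
  if (nrow(trials) != meta$n_trials) {
    stop_hdc("session.json inconsistent: %d trial rows vs n_trials = %d",
             nrow(trials), meta$n_trials)
  }
  files <- file.path(dir, sprintf("trial_%03d.csv", seq_len(meta$n_trials)))
  missing <- !file.exists(files)
  if (any(missing)) {
    stop_hdc("trace missing for trial %d (%s)", which(missing)[1],
             files[which(missing)[1]])
  }
  cfg <- meta$config
  config <- sim_config(
    duration_s = cfg$duration_s, dt = cfg$dt,
    metronome_cutoff = cfg$metronome_cutoff,
    human_osc = do.call(oscillator_params, cfg$human_osc),
    vp_osc = do.call(oscillator_params, cfg$vp_osc),
    a_coupling = cfg$a_coupling, b_coupling = cfg$b_coupling,
    unsure_prob = cfg$unsure_prob,
    humanness_stability_coef = cfg$humanness_stability_coef
  )
  structure(
    list(profile = meta$profile, trials = trials,
         traces = lapply(files, read_trace),
         config = config, seed = meta$seed),
    class = "hdc_session"
  )
}

#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs. The master `seed` fully
#' determines all downstream randomness: every stage derives its sub-seeds
#' through the documented splitting rule (a fixed integer fold of the master
#' seed and the stage/unit index).
#'
#' @param cohort A [cohort_spec()].
#' @param sim A [sim_config()].
#' @param nm_loo,nm_restarts Normative-stage options (see [apply_normative()]).
#' @param table3_method,table3_n_perm Per-cell comparison test options.
#' @param comparison_method Global NM comparison test.
#' @param seed Master seed.
#' @return An object of class `"hdc_pipeline_config"`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), sim = sim_config(),
                            nm_loo = TRUE, nm_restarts = 5,
                            table3_method = "permutation",
                            table3_n_perm = 10000,
                            comparison_method = "welch_t", seed = 1) {
  stopifnot(inherits(cohort, "hdc_cohort_spec"), inherits(sim, "hdc_sim_config"))
  check_number(seed, "seed")
  structure(
    list(cohort = cohort, sim = sim, nm_loo = isTRUE(nm_loo),
         nm_restarts = nm_restarts, table3_method = table3_method,
         table3_n_perm = table3_n_perm,
         comparison_method = comparison_method, seed = as.integer(seed)),
    class = "hdc_pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML file with top-level keys matching the arguments
#'   (`cohort` and `sim` as nested maps of constructor arguments).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$cohort)) args$cohort <- do.call(cohort_spec, raw$cohort)
  if (!is.null(raw$sim)) {
    sim_args <- raw$sim
    for (f in c("human_osc", "vp_osc")) {
      if (!is.null(sim_args[[f]])) {
        sim_args[[f]] <- do.call(oscillator_params, sim_args[[f]])
      }
    }
    args$sim <- do.call(sim_config, sim_args)
  }
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes the four stages in order -- simulate-and-score the cohort,
#' normative modeling, statistical report -- writing every artifact under
#' `out_dir`:
#' `cohort.csv`, `scores.csv`, `scores_nm.csv`, `models.json`,
#' `demographics.csv`, `correlations.csv`, `nm_comparisons.csv`,
#' `regressions.csv`, `table3.csv`, `report.md`, and a `manifest.json`
#' recording the config hash, package version, per-stage seeds, produced
#' files and timestamps. Re-running with the same config and seed reproduces
#' byte-identical score and NM tables.
#'
#' @param config An [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the config's master seed.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = NULL) {
  stopifnot(inherits(config, "hdc_pipeline_config"))
  seed <- as.integer(seed %||% config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- jsonlite::toJSON(unclass_deep(unclass(config)), auto_unbox = TRUE,
                               digits = NA)
  manifest <- list(
    config_hash = config_hash(as.character(cfg_json)),
    package_version = as.character(utils::packageVersion("hdclamp")),
    master_seed = seed,
    stage_seeds = list(cohort = derive_seed(seed, 101),
                       score = derive_seed(seed, 102),
                       normative = derive_seed(seed, 103),
                       report = derive_seed(seed, 104)),
    files = character(), timestamps = list(started = format(Sys.time()))
  )
  emit <- function(obj, file) {
    readr::write_csv(obj, file.path(out_dir, file))
    manifest$files <<- c(manifest$files, file)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stop_hdc("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  cohort <- stage("cohort", {
    ch <- sample_cohort(config$cohort, seed = manifest$stage_seeds$cohort)
    emit(ch, "cohort.csv")
    ch
  })
  scores <- stage("score", {
    sc <- score_cohort(cohort, config$sim, seed = manifest$stage_seeds$score)
    emit(sc, "scores.csv")
    sc
  })
  nm <- stage("normative", {
    tab <- apply_normative(scores, loo = config$nm_loo,
                           n_restarts = config$nm_restarts,
                           seed = manifest$stage_seeds$normative)
    emit(tab, "scores_nm.csv")
    models <- attr(tab, "models")
    jsonlite::write_json(lapply(models, function(m) as.list(glance(m))),
                         file.path(out_dir, "models.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$files <- c(manifest$files, "models.json")
    tab
  })
  stage("report", {
    rseed <- manifest$stage_seeds$report
    emit(demographics_table(cohort), "demographics.csv")
    emit(developmental_correlations(scores), "correlations.csv")
    cmp <- nm_group_comparison(nm, method = config$comparison_method,
                               seed = derive_seed(rseed, 1))
    emit(cmp, "nm_comparisons.csv")
    regs <- dplyr::bind_rows(lapply(ALL_SCORES, function(s) {
      fit <- subcondition_regression(subcondition_long(nm, s))
      dplyr::bind_cols(tibble(score = s), glance(fit))
    }))
    emit(regs, "regressions.csv")
    t3 <- table3_report(nm, method = config$table3_method,
                        n_perm = config$table3_n_perm,
                        seed = derive_seed(rseed, 2))
    emit(t3, "table3.csv")
    render_report_md(file.path(out_dir, "report.md"), cohort, cmp, regs, t3)
    manifest$files <- c(manifest$files, "report.md")
  })
  manifest$timestamps$finished <- format(Sys.time())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

render_report_md <- function(path, cohort, cmp, regs, t3) {
  fmt <- function(df) {
    cols <- names(df)
    body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    c(paste0("| ", paste(cols, collapse = " | "), " |"),
      paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|"),
      body)
  }
  num <- function(df) dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                                      ~ signif(.x, 4)))
  lines <- c(
    "# HDC synthetic cohort report", "",
    sprintf("Participants: %d ASD / %d TD", sum(cohort$group == "ASD"),
            sum(cohort$group == "TD")), "",
    "## Normative group comparisons (global scores)", "", fmt(num(cmp)), "",
    "## Subcondition regressions", "", fmt(num(regs)), "",
    "## Per-cell comparisons", "", fmt(num(t3)), ""
  )
  writeLines(lines, path)
  invisible(path)
}
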