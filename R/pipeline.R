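# End-to-end orchestration: simulate -> condition -> segment -> metricize ->
# analyze, with deterministic seeding and plain-text artifacts.

#' Pipeline configuration
#'
#' One object holding everything [run_pipeline()] needs: course, cohort
#' size and spread, filter specification, segmentation and stepwise
#' criteria, master seed, and (optionally) an output directory for the
#' artifact tree.
#'
#' @param n_athletes Cohort size.
#' @param course A [course_config()].
#' @param spread Cohort parameter ranges, see [cohort_spread()].
#' @param filters A [filter_spec()].
#' @param first_turn,last_turn Analysis turn window.
#' @param min_turn_duration Minimum plausible turn duration, s.
#' @param enter_p,remove_p Stepwise regression criteria.
#' @param seed Master seed; every random draw in the pipeline derives from
#'   it.
#' @param out_dir Output directory for artifacts, or `NULL` to keep results
#'   in memory only.
#' @param athlete_args Extra arguments for [athlete_profile()] (e.g. noise
#'   levels).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_athletes = 15,
                            course = course_config(),
                            spread = cohort_spread(),
                            filters = filter_spec(),
                            first_turn = 3L, last_turn = 16L,
                            min_turn_duration = 0.6,
                            enter_p = 0.05, remove_p = 0.10,
                            seed = 1L,
                            out_dir = NULL,
                            athlete_args = list()) {
  structure(list(n_athletes = n_athletes, course = course, spread = spread,
                 filters = filters, first_turn = as.integer(first_turn),
                 last_turn = as.integer(last_turn),
                 min_turn_duration = min_turn_duration,
                 enter_p = enter_p, remove_p = remove_p,
                 seed = as.integer(seed), out_dir = out_dir,
                 athlete_args = athlete_args),
            class = "pipeline_config")
}

#' Condition, segment and summarize one raw run
#'
#' The per-run processing chain: [synchronize()], [detect_turn_switches()],
#' [select_analysis_turns()], [summarize_run()]. Course time `T` is the
#' duration from the first to the last detected switch (the turned course).
#'
#' @param run A `raw_run`.
#' @param config A [pipeline_config()] (filter/segmentation settings are
#'   taken from it).
#' @return A list: `synced`, `switches`, `boundaries`, `summary`.
#' @export
process_run <- function(run, config = pipeline_config()) {
  synced <- synchronize(run, spec = config$filters)
  switches <- detect_turn_switches(
    synced, min_turn_duration = config$min_turn_duration)
  boundaries <- select_analysis_turns(
    switches, first_turn = config$first_turn, last_turn = config$last_turn,
    section_map = run$meta$section_map)
  course_time <- switches[length(switches)] - switches[1]
  summary <- summarize_run(synced, boundaries, course_time = course_time)
  list(synced = synced, switches = switches, boundaries = boundaries,
       summary = summary)
}

#' Run the full simulate-to-report pipeline
#'
#' Simulates a cohort, conditions and segments every run, computes per-turn
#' metrics and run summaries, compares the key variables between sections
#' (repeated-measures ANOVA with Holm post-hocs), and fits the four-level
#' stepped model. Re-running with the same configuration reproduces
#' identical results; if `config$out_dir` is set, the full plain-text
#' artifact tree is written there.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `report` (stepped model),
#'   `descriptives` (section descriptive table and ANOVA per variable),
#'   `summaries`, `truths`, `profiles`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- do.call(make_cohort,
                    c(list(n_athletes = config$n_athletes,
                           course = config$course,
                           spread = config$spread,
                           seed = config$seed),
                      config$athlete_args))
  processed <- lapply(cohort, function(a) {
    tryCatch(process_run(a$run, config),
             error = function(e)
               stop("processing failed for athlete ", a$athlete_id, ": ",
                    conditionMessage(e)))
  })
  summaries <- lapply(processed, `[[`, "summary")
  report <- run_stepped_model(summaries, enter_p = config$enter_p,
                              remove_p = config$remove_p)
  descriptives <- section_descriptives(summaries)

  out <- structure(list(report = report,
                        descriptives = descriptives,
                        summaries = summaries,
                        truths = lapply(cohort, `[[`, "truth"),
                        profiles = lapply(cohort, `[[`, "profile"),
                        config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    write_pipeline_artifacts(out, processed, cohort, config$out_dir)
  }
  out
}

#' Section descriptive table with repeated-measures comparisons
#'
#' For each per-turn variable: course and per-section cohort mean and SD,
#' the within-subject ANOVA F and p across the three sections, and the Holm
#' post-hoc pairwise effect sizes.
#'
#' @param summaries List of `run_summary` objects.
#' @param variables Variables to tabulate (default: the full turn-record
#'   set).
#' @return A list: `table` (one row per variable) and `anova` (per-variable
#'   `anova_result`).
#' @export
section_descriptives <- function(summaries,
                                 variables = c("T_turn", "v_in", "L",
                                               "de_per_vin", "dalt", "F_tot",
                                               "F_out", "F_ins", "F_diff",
                                               "F_max", "F_maxout",
                                               "F_maxins", "F_r", "RF")) {
  secs <- c("speed", "overspeed", "flat")
  rows <- list(); anovas <- list()
  for (v in variables) {
    course_vals <- vapply(summaries, function(s) s$course[[v]], numeric(1))
    sec_mat <- vapply(secs, function(sec)
      vapply(summaries, function(s) s$sections[sec, v], numeric(1)),
      numeric(length(summaries)))
    an <- rm_anova_holm(sec_mat)
    anovas[[v]] <- an
    rows[[v]] <- data.frame(
      variable = v,
      course_mean = mean(course_vals), course_sd = sd(course_vals),
      speed_mean = mean(sec_mat[, "speed"]), speed_sd = sd(sec_mat[, "speed"]),
      overspeed_mean = mean(sec_mat[, "overspeed"]),
      overspeed_sd = sd(sec_mat[, "overspeed"]),
      flat_mean = mean(sec_mat[, "flat"]), flat_sd = sd(sec_mat[, "flat"]),
      F = an$F, p = an$p)
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       anova = anovas)
}

write_pipeline_artifacts <- function(result, processed, cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort)) {
    adir <- file.path(out_dir, sprintf("athlete_%02d", i))
    write_raw_run(cohort[[i]]$run, adir, truth = cohort[[i]]$truth)
    write_synced_run(processed[[i]]$synced, file.path(adir, "synced.csv"))
    write_boundaries(processed[[i]]$boundaries,
                     file.path(adir, "boundaries.csv"))
    write_run_summary(processed[[i]]$summary, adir)
  }
  data.table::fwrite(result$descriptives$table,
                     file.path(out_dir, "descriptives.csv"))
  write_stepped_report(result$report, out_dir)
  jsonlite::write_json(
    list(seed = result$config$seed,
         n_athletes = result$config$n_athletes,
         course = unclass(result$config$course),
         spread = result$config$spread,
         first_turn = result$config$first_turn,
         last_turn = result$config$last_turn),
    file.path(out_dir, "pipeline_manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write the stepped-model report as JSON and CSV tables
#'
#' `report.json` holds the full nested report; `level1.csv`, `level3.csv`,
#' `level4.csv` the stepwise tables (one block per dataset, mirroring the
#' regression-table layout: standardized beta, p, R-squared change, model F,
#' df and adjusted R-squared) and `level2.csv` the correlation table.
#'
#' @param report A `stepped_model_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_stepped_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  steptab <- function(level) {
    rows <- lapply(names(report$datasets), function(ds) {
      r <- report$datasets[[ds]][[level]]
      if (r$empty)
        return(data.frame(dataset = ds, predictor = NA, beta = NA, p = NA,
                          R2_change = NA, F = NA, df1 = NA, df2 = NA,
                          model_R2_adj = NA))
      data.frame(dataset = ds, predictor = r$coefficients$predictor,
                 beta = r$coefficients$beta, p = r$coefficients$p,
                 R2_change = r$coefficients$R2_change,
                 F = r$F, df1 = r$df[1], df2 = r$df[2],
                 model_R2_adj = r$adj_r_squared)
    })
    do.call(rbind, rows)
  }
  corrow <- function(ds, nm, cr) {
    if (is.data.frame(cr)) data.frame(dataset = ds, pair = nm, cr)
    else data.frame(dataset = ds, pair = nm, r = NA, ci_low = NA,
                    ci_high = NA, p = NA, n = NA, magnitude = cr)
  }
  cortab <- do.call(rbind, lapply(names(report$datasets), function(ds) {
    l2 <- report$datasets[[ds]]$level2
    rbind(corrow(ds, "T_vs_Fr", l2$T_vs_Fr),
          corrow(ds, "de_vs_Fr", l2$de_vs_Fr))
  }))
  data.table::fwrite(steptab("level1"), file.path(dir, "level1.csv"))
  data.table::fwrite(cortab, file.path(dir, "level2.csv"))
  data.table::fwrite(steptab("level3"), file.path(dir, "level3.csv"))
  data.table::fwrite(steptab("level4"), file.path(dir, "level4.csv"))
  report_json <- lapply(report$datasets, function(ds) {
    lapply(ds, function(lvl) {
      if (inherits(lvl, "stepwise_result")) unclass(lvl) else lvl
    })
  })
  jsonlite::write_json(list(datasets = report_json,
                            n_athletes = report$n_athletes,
                            notes = report$notes),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> cohort of ", length(x$summaries), " athletes\n",
      sep = "")
  print(x$report)
  invisible(x)
}
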