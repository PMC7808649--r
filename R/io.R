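# Plain-text artifact readers/writers: CSV streams, JSON manifests.

#' Write a raw run (and optionally its truth record) to a directory
#'
#' Writes `force.csv` (`t_s, plate, Fx_raw, Fy_raw, Fz_raw, accel_mag`),
#' `trajectory.csv` (`t_s, x_m, y_m, z_m, vx_ms, vy_ms, vz_ms, accel_mag`),
#' `manifest.json` (masses, calibration matrices, rates, baseline window,
#' seed) and, when given, `truth.json`.
#'
#' @param run A `raw_run`.
#' @param dir Output directory (created if missing).
#' @param truth Optional `truth_record`.
#' @return `dir`, invisibly.
#' @export
write_raw_run <- function(run, dir, truth = NULL) {
  stopifnot(inherits(run, "raw_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(run$force, file.path(dir, "force.csv"))
  data.table::fwrite(run$traj, file.path(dir, "trajectory.csv"))
  manifest <- c(run$meta,
                list(calibration = lapply(run$calibration, function(m)
                  unclass(as.data.frame(m)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(truth)) {
    jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a raw run (and truth record, if present) from a directory
#'
#' Counterpart of [write_raw_run()].
#'
#' @param dir Directory containing `force.csv`, `trajectory.csv`,
#'   `manifest.json` and optionally `truth.json`.
#' @return A list with `run` (`raw_run`) and `truth` (`truth_record` or
#'   `NULL`).
#' @export
read_raw_run <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  calibration <- lapply(manifest$calibration, function(d)
    as.matrix(as.data.frame(d)))
  calibration <- lapply(calibration, function(m) {
    dimnames(m) <- NULL
    m
  })
  meta <- manifest[setdiff(names(manifest), "calibration")]
  meta$baseline_window <- as.numeric(meta$baseline_window)
  meta$section_map <- lapply(meta$section_map, as.integer)
  run <- structure(list(
    force = data.table::fread(file.path(dir, "force.csv")),
    traj = data.table::fread(file.path(dir, "trajectory.csv")),
    calibration = calibration,
    meta = meta), class = "raw_run")
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    tr <- jsonlite::read_json(tj, simplifyVector = TRUE)
    tr$turns <- as.data.frame(tr$turns)
    truth <- structure(tr, class = "truth_record")
  }
  list(run = run, truth = truth)
}

#' Write a conditioned run to CSV
#'
#' Columns: `t_s, Fout_BW, Fins_BW, F_BW, diff, x_m, y_m, z_m, v_ms,
#' beta_rad`, plus the auxiliary channels (`z_raw_m`, velocity components,
#' per-plate resultants, curvature sense).
#'
#' @param synced A `synced_run`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_synced_run <- function(synced, path) {
  out <- data.table::data.table(
    t_s = synced$t, Fout_BW = synced$F_out, Fins_BW = synced$F_ins,
    F_BW = synced$F, diff = synced$diff,
    x_m = synced$x, y_m = synced$y, z_m = synced$z, v_ms = synced$v,
    beta_rad = synced$beta, z_raw_m = synced$z_raw,
    vx_ms = synced$vx, vy_ms = synced$vy, vz_ms = synced$vz,
    Fleft_BW = synced$F_left, Fright_BW = synced$F_right,
    curv_sign = synced$curv_sign)
  data.table::fwrite(out, path)
  invisible(path)
}

#' Write turn boundaries to CSV
#'
#' Columns: `turn_index, start_s, end_s, section`.
#'
#' @param boundaries Data.frame from [select_analysis_turns()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(boundaries, path) {
  out <- data.frame(turn_index = boundaries$turn_index,
                    start_s = boundaries$start_t,
                    end_s = boundaries$end_t,
                    section = as.character(boundaries$section))
  data.table::fwrite(out, path)
  invisible(path)
}

#' Write per-turn metric records and the run summary
#'
#' `turns.csv` holds one row per turn record; `summary.json` the course and
#' section means plus course time.
#'
#' @param summary A `run_summary`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run_summary <- function(summary, dir) {
  stopifnot(inherits(summary, "run_summary"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(summary$turns, file.path(dir, "turns.csv"))
  jsonlite::write_json(
    list(T = summary$T,
         course = as.list(summary$course),
         sections = cbind(section = rownames(summary$sections),
                          summary$sections)),
    file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(dir)
}
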