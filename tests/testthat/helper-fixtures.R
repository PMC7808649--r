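# Shared fixtures, built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

no_noise_args <- function() {
  list(noise_sd_force = 0, vibration_sd = 0, noise_sd_position = 0,
       noise_sd_velocity = 0, noise_sd_accel = 0)
}

quiet_profile <- function(...) {
  do.call(athlete_profile, modifyList(no_noise_args(), list(...)))
}

# default-noise run with a nontrivial clock offset
demo_sim <- function() {
  cache_fixture("demo_sim",
    simulate_run(course_config(), athlete_profile(seed = 11, clock_offset = 3.21)))
}

# noise-free dissipative run
quiet_sim <- function() {
  cache_fixture("quiet_sim",
    simulate_run(course_config(), quiet_profile(seed = 2, clock_offset = -1.25)))
}

quiet_processed <- function() {
  cache_fixture("quiet_processed", process_run(quiet_sim()$run, pipeline_config()))
}

demo_processed <- function() {
  cache_fixture("demo_processed", process_run(demo_sim()$run, pipeline_config()))
}

# gentle course on which a frictionless run keeps physically sane speeds
gentle_course <- function() {
  course_config(slope_relief_alpha = 3, gate_spacing = 30, gate_offset = 2.5)
}

frictionless_processed <- function() {
  cache_fixture("frictionless_processed", {
    prof <- quiet_profile(seed = 5, dissipation_coeff = 0, drag_k = 0,
                          v_entry = 10, clock_offset = -1.7)
    sim <- simulate_run(gentle_course(), prof)
    list(sim = sim, pr = process_run(sim$run, pipeline_config()))
  })
}

# default-conditions cohort, processed end to end
default_pipeline <- function() {
  cache_fixture("default_pipeline", run_pipeline(pipeline_config(seed = 42)))
}

# noise-free cohort with dissipation as the only trajectory-relevant spread
isolated_dissipation_pipeline <- function() {
  cache_fixture("isolated_dissipation_pipeline", {
    sp <- cohort_spread()
    sp$line <- c(1, 1)
    run_pipeline(pipeline_config(seed = 42, spread = sp,
                                 athlete_args = no_noise_args()))
  })
}

# calibrated, baseline-zeroed per-plate force magnitudes of a raw run (BW)
plate_magnitudes <- function(sim) {
  run <- sim$run
  f <- as.data.frame(run$force)
  out <- lapply(c("left", "right"), function(p) {
    d <- f[f$plate == p, ]
    cal <- apply_calibration(as.matrix(d[, c("Fx_raw", "Fy_raw", "Fz_raw")]),
                             run$calibration[[p]])
    bl <- d$t_s >= run$meta$baseline_window[1] &
          d$t_s <= run$meta$baseline_window[2]
    bw <- zero_and_normalize(cal, bl, run$meta$BW_newtons)
    list(t = d$t_s, mag = resultant_force(bw[, 1], bw[, 2], bw[, 3]),
         vec = bw)
  })
  names(out) <- c("left", "right")
  out
}

# independent circumcircle oracle: radius from the linear-system solution of
# the circle through three points (plane embedding via cross products)
circumradius_oracle <- function(p1, p2, p3) {
  a <- p1 - p2; b <- p3 - p2
  cr <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  den <- 2 * sqrt(sum(cr^2))
  if (den < 1e-14) return(Inf)
  sqrt(sum(a^2)) * sqrt(sum(b^2)) * sqrt(sum((p1 - p3)^2)) / den
}

# exhaustive-subset stability oracle for stepwise selection: a subset is
# stable when every member keeps p <= remove_p given the others and no
# outside candidate would enter at p < enter_p
stable_subsets <- function(y, X, enter_p = 0.05, remove_p = 0.10) {
  X <- as.data.frame(X)
  zs <- function(v) (v - mean(v)) / sd(v)
  yz <- zs(y); Xz <- as.data.frame(lapply(X, zs))
  nm <- names(Xz)
  subsets <- unlist(lapply(0:length(nm), function(k)
    utils::combn(nm, k, simplify = FALSE)), recursive = FALSE)
  keep <- Filter(function(S) {
    if (length(S)) {
      cf <- summary(lm(yz ~ ., data = Xz[, S, drop = FALSE]))$coefficients
      if (!all(S %in% rownames(cf))) return(FALSE)
      if (any(cf[S, 4] > remove_p)) return(FALSE)
    }
    outside <- setdiff(nm, S)
    for (cand in outside) {
      cf <- summary(lm(yz ~ ., data = Xz[, c(S, cand), drop = FALSE]))$coefficients
      if (cand %in% rownames(cf) && cf[cand, 4] < enter_p) return(FALSE)
    }
    TRUE
  }, subsets)
  lapply(keep, sort)
}
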