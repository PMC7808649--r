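# Per-turn kinetic and kinematic metrics.

#' Resultant force magnitude per plate
#'
#' Euclidean norm of the three calibrated axis components,
#' `sqrt(Fx^2 + Fy^2 + Fz^2)`, computed samplewise.
#'
#' @param Fx,Fy,Fz Axis components (any consistent unit).
#' @return Resultant magnitudes.
#' @export
#' @examples
#' resultant_force(3, 4, 0)
resultant_force <- function(Fx, Fy, Fz) {
  sqrt(Fx^2 + Fy^2 + Fz^2)
}

#' Samplewise between-limb force difference ratio
#'
#' `|F_out - F_ins| / (F_out + F_ins)`, the absolute limb difference as a
#' fraction of total force, in `[0, 1]`. Samples where the total force is
#' (numerically) zero are returned as `NA` and excluded from turn means.
#'
#' @param F_out,F_ins Outside- and inside-limb resultant forces, BW.
#' @param eps Total-force floor below which the ratio is undefined.
#' @return Samplewise ratio, `NA` where total force is zero.
#' @export
#' @examples
#' limb_difference(1.06, 0.54)
limb_difference <- function(F_out, F_ins, eps = 1e-6) {
  tot <- F_out + F_ins
  ifelse(tot > eps, abs(F_out - F_ins) / tot, NA_real_)
}

#' Samplewise turn radius by three-point arc fit
#'
#' Radius of the circle through three consecutive trajectory points spaced
#' `spacing` frames apart (60 frames at 200 Hz corresponds to the 10 Hz
#' native trajectory rate). Near-collinear triples are capped at `r_max`
#' (straight-gliding samples); the number of capped samples is attached as
#' attribute `"n_capped"`.
#'
#' @param x,y,z Trajectory coordinates, m (equal length).
#' @param spacing Triple half-spacing, frames.
#' @param r_max Radius cap for near-collinear triples, m.
#' @return Numeric vector of radii (m), `NA` within `spacing` frames of the
#'   stream edges; attribute `n_capped` counts capped samples.
#' @export
turn_radius <- function(x, y, z = NULL, spacing = 60, r_max = 1000) {
  n <- length(x)
  if (is.null(z)) z <- numeric(n)
  if (n < 2 * spacing + 1)
    stop("need at least 2 * spacing + 1 = ", 2 * spacing + 1, " points")
  i <- (spacing + 1):(n - spacing)
  ax <- x[i - spacing] - x[i]; ay <- y[i - spacing] - y[i]; az <- z[i - spacing] - z[i]
  bx <- x[i + spacing] - x[i]; by <- y[i + spacing] - y[i]; bz <- z[i + spacing] - z[i]
  a2 <- ax^2 + ay^2 + az^2
  b2 <- bx^2 + by^2 + bz^2
  c2 <- (bx - ax)^2 + (by - ay)^2 + (bz - az)^2
  cxx <- ay * bz - az * by
  cxy <- az * bx - ax * bz
  cxz <- ax * by - ay * bx
  cr2 <- cxx^2 + cxy^2 + cxz^2           # |a x b|^2 = (2 * area)^2
  r <- sqrt(a2 * b2 * c2) / (2 * sqrt(pmax(cr2, 0)))
  r[!is.finite(r)] <- Inf
  capped <- r > r_max
  r[capped] <- r_max
  out <- rep(NA_real_, n)
  out[i] <- r
  attr(out, "n_capped") <- sum(capped)
  out
}

#' Specific radial force in bodyweight units
#'
#' Sum of the centripetal term and the radial component of gravity on the
#' inclined slope: `F_r = (v^2 / r + grav_sign * g * sin(alpha) * cos(beta)) / g`
#' in BW, where `alpha` is the slope relief, `beta` the angle between the
#' velocity and the contour (across-slope horizontal) direction, and
#' `grav_sign` is +1 when the in-plane gravity component points away from
#' the instantaneous turn centre (the snow must then supply the additional
#' radial force) and -1 when it points toward it.
#'
#' @param v Speed, m/s.
#' @param r Turn radius, m (> 0).
#' @param alpha Slope relief, degrees.
#' @param beta Heading angle to the contour direction, radians.
#' @param grav_sign +1 or -1, see above (may be a vector).
#' @param g Gravitational acceleration, m/s^2.
#' @return Specific radial force, BW.
#' @export
#' @examples
#' radial_force(14, 20, alpha = 0, beta = 0)          # 0.999 BW
#' radial_force(0, Inf, alpha = 25, beta = 0)         # pure gravity: 0.423 BW
radial_force <- function(v, r, alpha, beta = 0, grav_sign = 1, g = 9.81) {
  if (any(r <= 0, na.rm = TRUE)) stop("turn radius must be positive")
  (v^2 / r + grav_sign * g * sin(alpha * pi / 180) * cos(beta)) / g
}

#' Ratio of force application
#'
#' Turn-level ratio of turn-averaged radial force to turn-averaged total
#' force, `RF = F_r / F_tot`. Course- and section-level RF is the mean of
#' per-turn ratios (not the ratio of averaged forces).
#'
#' @param F_r Turn-averaged radial force, BW.
#' @param F_tot Turn-averaged total force, BW (> 0).
#' @return RF, dimensionless.
#' @export
ratio_of_forces <- function(F_r, F_tot) {
  if (any(F_tot <= 0)) stop("F_tot must be positive")
  F_r / F_tot
}

#' Velocity-normalized change in specific mechanical energy over a turn
#'
#' `((v_out^2 - v_in^2) / 2 + g * (z_out - z_in)) / v_in` in J s/kg/m:
#' the change in specific mechanical energy between the two turn switches,
#' normalized to entry speed. Negative when energy is dissipated; zero under
#' conservation.
#'
#' @param v_in,v_out Speed at turn entry and exit, m/s (`v_in > 0`).
#' @param z_in,z_out Altitude at turn entry and exit, m.
#' @param g Gravitational acceleration, m/s^2.
#' @return Normalized energy change, J s/kg/m.
#' @export
#' @examples
#' delta_emech_per_vin(15, 14, 0, -9)   # -6.853
delta_emech_per_vin <- function(v_in, v_out, z_in, z_out, g = 9.81) {
  if (any(v_in <= 0)) stop("entry speed must be positive")
  ((v_out^2 - v_in^2) / 2 + g * (z_out - z_in)) / v_in
}

# Samplewise kinetic series over a whole synced run: arc-fit radius, heading
# and curvature-resolved gravity sign, and the Eq-style radial force. The
# gravity term enters with + when the in-plane gravity component points away
# from the turn centre: the centre is on the +x side when curv_sign < 0, and
# the in-plane gravity projection has a lateral component along sign(vx) of
# the travel; resolved compactly via the slope-frame normal (see vignette).
kinetic_series <- function(synced, spacing = 60, r_max = 1000) {
  meta <- attr(synced, "meta")
  g <- meta$gravity_g
  alpha <- meta$alpha_deg * pi / 180
  r <- turn_radius(synced$x, synced$y, synced$z, spacing = spacing,
                   r_max = r_max)
  v <- synced$v
  # unit tangent from the velocity channel; radial direction toward the
  # centre is curv_sign x (slope-normal x tangent); its altitude component
  # gives the gravity term directly: F_r = v^2/(r g) - (g_vec . N_c)/g
  # with g_vec = (0,0,-g) and N_c the in-plane radial unit toward the
  # centre, (N_c)_z = -curv_sign * sin(alpha) * Tx, and
  # F_r = v^2/(r g) - (g_vec . N_c)/g = v^2/(r g) + (N_c)_z
  Tx <- ifelse(v > 1e-6, synced$vx / v, 0)
  Ncz <- -synced$curv_sign * sin(alpha) * Tx
  F_r <- (v^2 / pmax(r, 1e-6)) / g + Ncz
  list(r = r, F_r = F_r, n_capped = attr(r, "n_capped"))
}

#' Summarize one turn into its metric record
#'
#' Computes the per-turn variable set: turn time, entry and average speed,
#' cumulated path length, altitude drop, turn-averaged radius and radial
#' force, turn-averaged and peak limb/total forces, limb difference, ratio
#' of force application, and normalized mechanical-energy change.
#'
#' Outside/inside limb attribution is made once per turn from the dominant
#' horizontal curvature sense within the turn. Energy point values (entry
#' and exit speed and altitude) are taken from the trajectory-unit velocity
#' channel and the unfiltered resampled altitude so that they stay unbiased
#' by smoothing.
#'
#' @param synced A `synced_run`.
#' @param boundary One row of the data.frame from [select_analysis_turns()]
#'   (fields `turn_index, start_t, end_t, section`).
#' @param series Optional precomputed [radius/radial-force series]; computed
#'   from `synced` when missing (pass one shared series when summarizing
#'   many turns).
#' @return A one-row data.frame (`turn_record`).
#' @export
summarize_turn <- function(synced, boundary, series = NULL) {
  if (is.null(series)) series <- kinetic_series(synced)
  t <- synced$t
  i <- which(t >= boundary$start_t & t < boundary$end_t)
  if (!length(i)) stop("turn boundary outside the synced run")
  # turn-level outside/inside attribution: dominant curvature sense
  dom <- sign(sum(synced$curv_sign[i]))
  if (dom == 0) dom <- 1
  out_is_left <- dom < 0
  F_out_t <- if (out_is_left) synced$F_left[i] else synced$F_right[i]
  F_ins_t <- if (out_is_left) synced$F_right[i] else synced$F_left[i]
  F_t <- synced$F[i]
  dff <- limb_difference(F_out_t, F_ins_t)
  n_zero <- sum(is.na(dff))

  v_in  <- interp1(t, synced$v, boundary$start_t)
  v_out <- interp1(t, synced$v, boundary$end_t)
  z_in  <- interp1(t, synced$z_raw, boundary$start_t)
  z_out <- interp1(t, synced$z_raw, boundary$end_t)

  # cumulated displacement, with the fractional boundary segments included
  cumarc <- c(0, cumsum(sqrt(diff(synced$x)^2 + diff(synced$y)^2 +
                             diff(synced$z)^2)))
  L <- interp1(t, cumarc, boundary$end_t) - interp1(t, cumarc, boundary$start_t)
  F_r_mean <- mean(series$F_r[i], na.rm = TRUE)
  F_tot <- mean(F_t)

  data.frame(
    turn_index = boundary$turn_index,
    section = as.character(boundary$section),
    T_turn = boundary$end_t - boundary$start_t,
    v_in = v_in,
    v_avg = mean(synced$v[i]),
    L = L,
    dalt = z_in - z_out,
    r = mean(series$r[i], na.rm = TRUE),
    F_tot = F_tot,
    F_out = mean(F_out_t),
    F_ins = mean(F_ins_t),
    F_diff = mean(dff, na.rm = TRUE),
    F_max = max(F_t),
    F_maxout = max(F_out_t),
    F_maxins = max(F_ins_t),
    F_r = F_r_mean,
    RF = ratio_of_forces(F_r_mean, F_tot),
    de_per_vin = delta_emech_per_vin(v_in, v_out, z_in, z_out,
                                     g = attr(synced, "meta")$gravity_g),
    n_zero_force = n_zero)
}

#' Summarize all analysis turns of a run
#'
#' Applies [summarize_turn()] to every retained turn and aggregates course-
#' and section-level means (unweighted means over turns; RF and all other
#' variables averaged per turn first).
#'
#' @param synced A `synced_run`.
#' @param boundaries Data.frame from [select_analysis_turns()].
#' @param course_time Total course time `T`, s (e.g. last minus first
#'   detected switch); stored in the summary.
#' @return A list of class `run_summary`: `turns` (per-turn records),
#'   `course` (named course means), `sections` (per-section means),
#'   `T` (course time).
#' @export
summarize_run <- function(synced, boundaries, course_time = NA_real_) {
  series <- kinetic_series(synced)
  recs <- do.call(rbind, lapply(seq_len(nrow(boundaries)), function(j)
    summarize_turn(synced, boundaries[j, ], series = series)))
  metric_cols <- setdiff(names(recs), c("turn_index", "section", "n_zero_force"))
  course <- colMeans(recs[, metric_cols])
  secs <- lapply(split(recs, recs$section, drop = TRUE), function(d)
    colMeans(d[, metric_cols]))
  sections <- do.call(rbind, secs)
  structure(list(turns = recs,
                 course = course,
                 sections = as.data.frame(sections),
                 T = course_time),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("<run_summary> %d turns, T = %.2f s, F_tot %.2f BW, F_r %.2f BW, RF %.2f, de/v_in %.2f\n",
              nrow(x$turns), x$T, x$course[["F_tot"]], x$course[["F_r"]],
              x$course[["RF"]], x$course[["de_per_vin"]]))
  invisible(x)
}
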