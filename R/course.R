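# Course and athlete configuration objects for the synthetic generator.

#' Course configuration for a simulated giant-slalom run
#'
#' Describes the gate geometry and relief of a giant-slalom course. The
#' defaults emulate a short race-pace GS setting: 18 gates on a ~25 deg
#' constant-relief slope, with a turn-to-turn rhythm that yields turn times
#' around 1.7-1.8 s and entry speeds around 15-16 m/s.
#'
#' The local frame is slope-fixed Cartesian: `y` is the horizontal projection
#' of the fall line (positive downhill), `x` is lateral (along the contour
#' line), `z` is altitude. Gate spacing is measured along the slope surface in
#' the fall-line direction; `gate_offset` is the lateral half-amplitude of the
#' centre-of-mass path.
#'
#' @param n_gates Number of gates (turns); at least 4.
#' @param slope_relief_alpha Slope inclination, degrees, in `[0, 90)`.
#' @param gate_spacing Along-slope distance between successive gates, m.
#' @param gate_offset Lateral half-amplitude of the skier path, m.
#' @param section_map Named list mapping section labels (`"speed"`,
#'   `"overspeed"`, `"flat"`) to integer turn indices. The default reproduces
#'   the analysis sections of an 18-gate course: speed = turns 3-5 and 15-16,
#'   overspeed = 6-10, flat = 11-14; all other turns are excluded.
#' @param gravity_g Gravitational acceleration, m/s^2.
#'
#' @return An object of class `course_config`.
#' @export
#' @examples
#' course_config()
course_config <- function(n_gates = 18L,
                          slope_relief_alpha = 25,
                          gate_spacing = 26,
                          gate_offset = 4.6,
                          section_map = default_section_map(),
                          gravity_g = 9.81) {
  n_gates <- as.integer(n_gates)
  stopifnot(n_gates >= 4L)
  if (slope_relief_alpha < 0 || slope_relief_alpha >= 90)
    stop("slope_relief_alpha must be in [0, 90) degrees")
  stopifnot(gate_spacing > 0, gate_offset >= 0, gravity_g > 0)
  section_map <- validate_section_map(section_map, n_gates)
  structure(
    list(n_gates = n_gates,
         slope_relief_alpha = slope_relief_alpha,
         gate_spacing = gate_spacing,
         gate_offset = gate_offset,
         section_map = section_map,
         gravity_g = gravity_g),
    class = "course_config")
}

#' Default course section map (18-gate course)
#'
#' Speed section: turns 3-5 and 15-16; overspeed: turns 6-10; flat: turns
#' 11-14. Turns outside the map are excluded from sectional analysis.
#'
#' @return Named list of integer turn-index vectors.
#' @export
default_section_map <- function() {
  list(speed = c(3L, 4L, 5L, 15L, 16L),
       overspeed = 6:10,
       flat = 11:14)
}

validate_section_map <- function(map, n_gates) {
  stopifnot(is.list(map))
  allowed <- c("speed", "overspeed", "flat")
  if (!all(names(map) %in% allowed))
    stop("section_map names must be among: ", paste(allowed, collapse = ", "))
  idx <- unlist(map, use.names = FALSE)
  if (anyDuplicated(idx))
    stop("section_map assigns some turn to more than one section")
  if (length(idx) && (min(idx) < 1L || max(idx) > n_gates))
    stop("section_map indices must lie in 1..n_gates")
  # the canonical 18-gate analysis window covers exactly turns 3-16
  if (n_gates == 18L && !setequal(idx, 3:16))
    stop("with 18 gates the section map must cover exactly turns 3-16")
  lapply(map, function(v) sort(as.integer(v)))
}

#' Athlete profile for the synthetic generator
#'
#' Parameters of one simulated skier. `system_mass_BM` is total system mass
#' (athlete plus equipment) so that bodyweight BW = mass x g, the unit all
#' forces are normalized to. `dissipation_coeff` is an effective friction
#' coefficient: specific mechanical energy lost to ski-snow interaction per
#' metre of path equals `dissipation_coeff * g` (J/kg/m). `drag_k` adds a
#' speed-dependent loss `drag_k * v^2` per metre (aerodynamic and
#' speed-dependent snow losses) which gives the skier a stable equilibrium
#' speed on constant relief. `limb_split` is the mean outside:inside limb
#' load ratio; `rf_capability` the target mean ratio of force application
#' (radial force over total force, in (0, 1]).
#'
#' @param system_mass_BM Total system mass, kg.
#' @param dissipation_coeff Effective friction coefficient (dimensionless,
#'   >= 0). Zero together with `drag_k = 0` gives a frictionless run.
#' @param drag_k Speed-dependent loss coefficient, 1/m (>= 0).
#' @param limb_split Mean outside:inside load ratio (> 0).
#' @param rf_capability Target mean ratio of force application, in (0, 1].
#' @param v_entry Speed at the start of the turned course section, m/s.
#' @param noise_sd_force Additive Gaussian noise SD on each force channel,
#'   BW units (0 disables).
#' @param vibration_sd Band-limited (10-25 Hz) vibration SD added to force
#'   channels, BW units (0 disables).
#' @param noise_sd_position Additive Gaussian noise SD on trajectory
#'   coordinates, m.
#' @param noise_sd_velocity Additive Gaussian noise SD on the GNSS velocity
#'   channels, m/s.
#' @param noise_sd_accel Additive Gaussian noise SD on the accelerometer
#'   magnitude channels, m/s^2.
#' @param clock_offset Offset of the trajectory-stream clock relative to the
#'   force-plate clock, s (the trajectory clock reads
#'   `t_force - clock_offset`).
#' @param seed Integer seed for this run's random draws.
#'
#' @return An object of class `athlete_profile`.
#' @export
#' @examples
#' athlete_profile(seed = 1)
athlete_profile <- function(system_mass_BM = 84,
                            dissipation_coeff = 0.30,
                            drag_k = 0.004,
                            limb_split = 2.0,
                            rf_capability = 0.68,
                            v_entry = 15.2,
                            noise_sd_force = 0.04,
                            vibration_sd = 0.05,
                            noise_sd_position = 0.05,
                            noise_sd_velocity = 0.05,
                            noise_sd_accel = 0.3,
                            clock_offset = 0,
                            seed = 1L) {
  stopifnot(system_mass_BM > 0, dissipation_coeff >= 0, drag_k >= 0,
            limb_split > 0, v_entry > 0,
            noise_sd_force >= 0, vibration_sd >= 0, noise_sd_position >= 0,
            noise_sd_velocity >= 0, noise_sd_accel >= 0)
  if (rf_capability <= 0 || rf_capability > 1)
    stop("rf_capability must be in (0, 1]")
  structure(
    list(system_mass_BM = system_mass_BM,
         dissipation_coeff = dissipation_coeff,
         drag_k = drag_k,
         limb_split = limb_split,
         rf_capability = rf_capability,
         v_entry = v_entry,
         noise_sd_force = noise_sd_force,
         vibration_sd = vibration_sd,
         noise_sd_position = noise_sd_position,
         noise_sd_velocity = noise_sd_velocity,
         noise_sd_accel = noise_sd_accel,
         clock_offset = clock_offset,
         seed = as.integer(seed)),
    class = "athlete_profile")
}

#' @export
print.course_config <- function(x, ...) {
  cat("<course_config> ", x$n_gates, " gates, relief ",
      x$slope_relief_alpha, " deg, gate spacing ", x$gate_spacing,
      " m, lateral offset ", x$gate_offset, " m\n", sep = "")
  invisible(x)
}

#' @export
print.athlete_profile <- function(x, ...) {
  cat(sprintf(
    "<athlete_profile> mass %.1f kg, dissipation %.3f (+%.4f v^2/m), limb split %.2f, RF target %.2f, clock offset %+.3f s, seed %d\n",
    x$system_mass_BM, x$dissipation_coeff, x$drag_k, x$limb_split,
    x$rf_capability, x$clock_offset, x$seed))
  invisible(x)
}
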