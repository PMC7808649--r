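# Synthetic giant-slalom run generator with ground truth.
#
# The skier path lives on an inclined plane (relief alpha). In-plane
# coordinates: xi = distance along the fall line measured on the slope
# surface, w = lateral coordinate. World frame: x lateral, y horizontal
# projection of the fall line (positive downhill), z altitude, so that
#   x = w,  y = xi * cos(alpha),  z = z0 - xi * sin(alpha).
# The lateral path is w(xi) = A * cos(k * xi) with half-period equal to the
# gate spacing: the run starts at an apex, gates sit at successive apexes and
# turn switches are the trajectory inflections between them.
#
# Speed follows the specific-energy balance along the path arc length sigma:
#   d(v^2/2)/dsigma = g sin(alpha) dxi/dsigma - mu g - k_drag v^2
# where mu (dissipation_coeff) is an effective friction coefficient and
# k_drag a speed-dependent loss. The emitted snow-reaction force is
# F = m (a - g_vec), split between the outside and inside plates so that the
# vector sum preserves the dynamics exactly while the sum of the two limb
# magnitudes realizes the target total force F_r / rf_capability at the
# prescribed outside:inside ratio.

SIM_FS_FORCE <- 200
SIM_FS_TRAJ  <- 10

# timeline constants (s, force-plate clock)
SIM_T_UNLOADED <- 2.0   # plates unloaded (baseline for zeroing)
SIM_T_JUMP1    <- 5.0   # centre of pre-run sync jump
SIM_T_RUN0     <- 8.0   # motion onset
SIM_JUMP_SIGMA <- 0.12  # sync jump impulse width, s
SIM_JUMP_AMP   <- 3.5   # jump accel peak, multiples of g
SIM_POST_PAD   <- 5.0   # settle + post-run jump window, s
SIM_APPROACH   <- 45    # straight approach before the first turn, m

# piecewise lateral path: straight approach (w = A) for xi < 0, cosine
# oscillation from the start-gate apex for xi >= 0
path_eval <- function(xi, A, kw) {
  m <- xi >= 0
  list(w   = ifelse(m,  A * cos(kw * xi), A),
       wp  = ifelse(m, -A * kw * sin(kw * xi), 0),
       wpp = ifelse(m, -A * kw^2 * cos(kw * xi), 0))
}

#' Simulate one giant-slalom run with ground truth
#'
#' Generates the two raw sensor streams of a run — per-limb force-plate
#' channels in raw units at 200 Hz plus an accelerometer-magnitude channel,
#' and a centre-of-mass trajectory (position, velocity, accelerometer
#' magnitude) at 10 Hz on an independent clock — together with a
#' [truth record][simulate_run] holding per-turn true radii, radial force,
#' energy dissipation and the injected clock offset.
#'
#' The emitted streams contain an initial unloaded segment (for force
#' zeroing), a loaded static phase, a strong jump impulse before and after
#' the run (for clock synchronization), and the run itself. Gaussian noise
#' and band-limited vibration are added per the athlete profile; the
#' trajectory stream timestamps are shifted by the athlete's clock offset.
#'
#' @param course A [course_config()].
#' @param athlete An [athlete_profile()].
#' @return A list with elements `run` (class `raw_run`: `force` and `traj`
#'   data.tables, `calibration` matrices, `meta`) and `truth` (class
#'   `truth_record`: per-turn truth table, switch times, clock offset,
#'   course time).
#' @export
#' @examples
#' sim <- simulate_run(course_config(), athlete_profile(seed = 7))
#' head(sim$truth$turns)
simulate_run <- function(course = course_config(),
                         athlete = athlete_profile()) {
  stopifnot(inherits(course, "course_config"),
            inherits(athlete, "athlete_profile"))
  set.seed(athlete$seed)

  g <- course$gravity_g
  alpha <- course$slope_relief_alpha * pi / 180
  A <- course$gate_offset
  lambda <- 2 * course$gate_spacing
  kw <- 2 * pi / lambda
  n_turn <- course$n_gates
  mu <- athlete$dissipation_coeff
  kdrag <- athlete$drag_k
  mass <- athlete$system_mass_BM
  BW <- mass * g

  # ---- path geometry on a fine grid ----
  xi_f <- lambda / 4 + n_turn * lambda / 2 + 0.15 * lambda
  dxi <- 0.02
  xi <- seq(-SIM_APPROACH, xi_f, by = dxi)
  pe <- path_eval(xi, A, kw)
  w <- pe$w; wp <- pe$wp; wpp <- pe$wpp
  sp  <- sqrt(1 + wp^2)              # dsigma/dxi
  sigma <- cumtrapz(xi, sp)

  # ---- energy balance: u = v^2 along the path ----
  u <- energy_profile(xi, sigma, sp, athlete$v_entry^2, g, alpha, mu, kdrag)
  if (any(u <= 1)) {
    stop("dissipation too large: squared speed reaches ",
         sprintf("%.2f", min(u)), " m^2/s^2 at xi = ",
         sprintf("%.1f", xi[which.min(u)]), " m; reduce dissipation_coeff")
  }
  v <- sqrt(u)
  xidot <- v / sp
  t_run <- cumtrapz(xi, 1 / xidot)   # time since motion onset

  # ---- true turn boundaries: inflections of lateral coordinate in time ----
  xidd <- xidot * finite_gradient(xidot, xi)
  alat <- wpp * xidot^2 + wp * xidd  # d^2 x / dt^2 along the run
  sw_t <- zero_crossings(t_run, alat, min_gap = 0.3 * lambda / (2 * max(v)))
  if (length(sw_t) < n_turn + 1)
    stop("internal: expected ", n_turn + 1, " trajectory inflections, found ",
         length(sw_t))
  sw_t <- sw_t[seq_len(n_turn + 1)]

  # ---- per-turn ground truth ----
  kap  <- abs(wpp) / sp^3
  r_cap <- pmin(1 / pmax(kap, 1e-12), 1000)
  # specific radial force (m/s^2): centripetal + in-plane gravity component
  f_r <- u * kap + g * sin(alpha) * sign(wpp) * wp / sp
  e_mech <- u / 2 + g * (-xi * sin(alpha))     # specific energy, datum z0 = 0
  dt_w <- 1 / xidot                            # time weight per unit xi
  turn_sign <- numeric(n_turn)
  truth_rows <- vector("list", n_turn)
  for (j in seq_len(n_turn)) {
    in_turn <- t_run >= sw_t[j] & t_run < sw_t[j + 1]
    wgt <- dt_w[in_turn]
    e_in  <- interp1(t_run, e_mech, sw_t[j])
    e_out <- interp1(t_run, e_mech, sw_t[j + 1])
    v_in  <- interp1(t_run, v, sw_t[j])
    turn_sign[j] <- sign(wpp[in_turn][which.max(abs(wpp[in_turn]))])
    truth_rows[[j]] <- data.frame(
      turn_index = j,
      start_t = SIM_T_RUN0 + sw_t[j],
      end_t   = SIM_T_RUN0 + sw_t[j + 1],
      r_true = weighted.mean(r_cap[in_turn], wgt),
      r_apex_true = min(r_cap[in_turn]),
      F_r_true = weighted.mean(f_r[in_turn], wgt) / g,
      v_in_true = v_in,
      de_mech_true = e_out - e_in,
      de_per_vin_true = (e_out - e_in) / v_in,
      L_true = interp1(t_run, sigma, sw_t[j + 1]) -
               interp1(t_run, sigma, sw_t[j]),
      dalt_true = -sin(alpha) * (interp1(t_run, xi, sw_t[j + 1]) -
                                 interp1(t_run, xi, sw_t[j])),
      turn_direction = turn_sign[j])
  }
  truth_turns <- do.call(rbind, truth_rows)
  course_time <- sw_t[n_turn + 1] - sw_t[1]   # turned-course duration

  # ---- force stream (200 Hz, force-plate clock) ----
  t_end_run <- t_run[length(t_run)]
  t_total <- SIM_T_RUN0 + t_end_run + SIM_POST_PAD
  t_jump2 <- SIM_T_RUN0 + t_end_run + 2.5
  tf <- seq(0, t_total, by = 1 / SIM_FS_FORCE)
  nf <- length(tf)

  in_run <- tf >= SIM_T_RUN0 & tf <= SIM_T_RUN0 + t_end_run
  loaded <- tf >= SIM_T_UNLOADED

  # run-phase kinematics at force sample times
  xi_of_t <- splinefun(t_run, xi, method = "hyman")
  xr <- xi_of_t(pmin(pmax(tf - SIM_T_RUN0, 0), t_end_run))
  per <- path_eval(xr, A, kw)
  wr <- per$w; wpr <- per$wp; wppr <- per$wpp
  spr  <- sqrt(1 + wpr^2)
  ur   <- splinefun(xi, u, method = "natural")(xr)
  vr   <- sqrt(ur)
  dudxi <- 2 * g * sin(alpha) - 2 * (mu * g + kdrag * ur) * spr
  dvdt <- dudxi * (vr / spr) / (2 * vr)
  kapr <- abs(wppr) / spr^3

  # world-frame unit vectors: T tangent, Nl left in-plane normal
  Tx <- wpr / spr; Ty <- cos(alpha) / spr; Tz <- -sin(alpha) / spr
  Nlx <- 1 / spr; Nly <- -wpr * cos(alpha) / spr; Nlz <- wpr * sin(alpha) / spr
  sgn <- sign(wppr)
  ax <- dvdt * Tx + ur * kapr * sgn * Nlx
  ay <- dvdt * Ty + ur * kapr * sgn * Nly
  az <- dvdt * Tz + ur * kapr * sgn * Nlz

  # net snow-reaction force F = m (a - g_vec); static phases support weight
  Fx <- ifelse(in_run, mass * ax, 0)
  Fy <- ifelse(in_run, mass * ay, 0)
  Fz <- ifelse(in_run, mass * (az + g), mass * g)
  Fz[!loaded] <- 0
  # sync jumps modulate the vertical channel
  jump <- SIM_JUMP_AMP * (exp(-0.5 * ((tf - SIM_T_JUMP1) / SIM_JUMP_SIGMA)^2) +
                          exp(-0.5 * ((tf - t_jump2) / SIM_JUMP_SIGMA)^2))
  Fz <- Fz + mass * g * jump * loaded * !in_run
  Fmag <- sqrt(Fx^2 + Fy^2 + Fz^2)

  # specific radial force at force samples, for the total-magnitude target
  f_r_s <- ifelse(in_run, ur * kapr + g * sin(alpha) * sgn * wpr / spr, 0)
  S_target <- pmax(mass * f_r_s / athlete$rf_capability, Fmag)

  # outside/inside split: outside share per turn at limb_split : 1
  ls <- athlete$limb_split
  out_share <- rep(0.5, nf)
  turn_of <- findInterval(tf - SIM_T_RUN0, sw_t)
  run_idx <- which(in_run)
  # sample-level turn direction: per-turn dominant sign inside boundaries,
  # local curvature sign in the lead-in/out, even split on straight segments
  dir_s <- sgn
  inside <- turn_of >= 1 & turn_of <= n_turn
  dir_s[inside] <- turn_sign[turn_of[inside]]
  # outside ski is on the opposite side of the turn centre; facing downhill
  # (+y) with z up, +x is the skier's right, so when the centre lies on the
  # +x side (wpp > 0) the outside (more loaded) plate is the left one
  is_right_outside <- dir_s < 0
  out_share[run_idx] <- ifelse(dir_s[run_idx] == 0, 0.5, ls / (1 + ls))

  split <- split_limb_forces(Fx, Fy, Fz, S_target, out_share, Tx, Ty, Tz)
  # route outside/inside magnitudes to physical left/right plates
  FL <- split$out; FR <- split$ins
  swap <- is_right_outside & in_run
  FL[swap, ] <- split$ins[swap, , drop = FALSE]
  FR[swap, ] <- split$out[swap, , drop = FALSE]

  accel_card <- Fmag / mass
  accel_card[!loaded] <- g   # card still senses gravity when plates unloaded

  # ---- noise, vibration, calibration to raw units ----
  calib <- list(left = random_calibration(), right = random_calibration())
  nsd <- athlete$noise_sd_force * BW
  if (nsd > 0) {
    FL <- FL + matrix(rnorm(3 * nf, sd = nsd), ncol = 3)
    FR <- FR + matrix(rnorm(3 * nf, sd = nsd), ncol = 3)
  }
  if (athlete$vibration_sd > 0) {
    vib_sd <- athlete$vibration_sd * BW
    vib <- replicate(6, band_limited_noise(nf, SIM_FS_FORCE, 10, 25, vib_sd))
    vib <- vib * as.numeric(in_run)
    FL <- FL + vib[, 1:3]
    FR <- FR + vib[, 4:6]
  }
  rawL <- t(solve(calib$left) %*% t(FL))
  rawR <- t(solve(calib$right) %*% t(FR))
  off <- runif(6, -0.05, 0.05)   # per-channel raw baseline offsets
  rawL <- sweep(rawL, 2, off[1:3], "+")
  rawR <- sweep(rawR, 2, off[4:6], "+")
  if (athlete$noise_sd_accel > 0)
    accel_card <- accel_card + rnorm(nf, sd = athlete$noise_sd_accel)

  force_dt <- data.table::data.table(
    t_s = rep(tf, 2),
    plate = rep(c("left", "right"), each = nf),
    Fx_raw = c(rawL[, 1], rawR[, 1]),
    Fy_raw = c(rawL[, 2], rawR[, 2]),
    Fz_raw = c(rawL[, 3], rawR[, 3]),
    accel_mag = rep(accel_card, 2))

  # ---- trajectory stream (10 Hz, offset clock) ----
  o <- athlete$clock_offset
  kk <- seq(ceiling((-1 - o) * SIM_FS_TRAJ), floor((t_total + 1 - o) * SIM_FS_TRAJ))
  tg <- kk / SIM_FS_TRAJ            # GNSS clock
  tr <- tg + o                      # force clock ("real" time)
  ng <- length(tg)
  in_run_g <- tr >= SIM_T_RUN0 & tr <= SIM_T_RUN0 + t_end_run
  xg <- xi_of_t(pmin(pmax(tr - SIM_T_RUN0, 0), t_end_run))
  peg <- path_eval(xg, A, kw)
  wg <- peg$w; wpg <- peg$wp; wppg <- peg$wpp
  spg  <- sqrt(1 + wpg^2)
  ug   <- splinefun(xi, u, method = "natural")(xg)
  vg   <- sqrt(ug)
  pos_x <- wg
  pos_y <- xg * cos(alpha)
  pos_z <- -xg * sin(alpha)
  vx <- ifelse(in_run_g, vg * wpg / spg, 0)
  vy <- ifelse(in_run_g, vg * cos(alpha) / spg, 0)
  vz <- ifelse(in_run_g, -vg * sin(alpha) / spg, 0)
  jump_g <- exp(-0.5 * ((tr - SIM_T_JUMP1) / SIM_JUMP_SIGMA)^2) +
            exp(-0.5 * ((tr - t_jump2) / SIM_JUMP_SIGMA)^2)
  pos_z <- pos_z + 0.25 * jump_g
  # GNSS accelerometer senses the same specific force as the card
  kapg <- abs(wppg) / spg^3
  dudxig <- 2 * g * sin(alpha) - 2 * (mu * g + kdrag * ug) * spg
  dvdtg <- dudxig / (2 * spg)
  f_spec <- sqrt(dvdtg^2 + (ug * kapg + g * sin(alpha) * sign(wppg) * wpg / spg)^2 +
                 (g * cos(alpha))^2)
  accel_g <- ifelse(in_run_g, f_spec, g * (1 + SIM_JUMP_AMP * jump_g))
  if (athlete$noise_sd_position > 0) {
    pos_x <- pos_x + rnorm(ng, sd = athlete$noise_sd_position)
    pos_y <- pos_y + rnorm(ng, sd = athlete$noise_sd_position)
    pos_z <- pos_z + rnorm(ng, sd = athlete$noise_sd_position)
  }
  if (athlete$noise_sd_velocity > 0) {
    vx <- vx + rnorm(ng, sd = athlete$noise_sd_velocity)
    vy <- vy + rnorm(ng, sd = athlete$noise_sd_velocity)
    vz <- vz + rnorm(ng, sd = athlete$noise_sd_velocity)
  }
  if (athlete$noise_sd_accel > 0)
    accel_g <- accel_g + rnorm(ng, sd = athlete$noise_sd_accel)

  traj_dt <- data.table::data.table(
    t_s = tg, x_m = pos_x, y_m = pos_y, z_m = pos_z,
    vx_ms = vx, vy_ms = vy, vz_ms = vz, accel_mag = accel_g)

  run <- structure(list(
    force = force_dt,
    traj = traj_dt,
    calibration = calib,
    meta = list(
      BW_newtons = BW,
      system_mass_BM = mass,
      fs_force = SIM_FS_FORCE,
      fs_traj = SIM_FS_TRAJ,
      alpha_deg = course$slope_relief_alpha,
      gravity_g = g,
      n_gates = n_turn,
      section_map = course$section_map,
      baseline_window = c(0.1, SIM_T_UNLOADED - 0.2),
      seed = athlete$seed)),
    class = "raw_run")

  truth <- structure(list(
    turns = truth_turns,
    switch_times = SIM_T_RUN0 + sw_t,
    run_start = SIM_T_RUN0,
    run_end = SIM_T_RUN0 + t_end_run,
    course_time = course_time,
    clock_offset = o,
    limb_split = ls,
    dissipation_coeff = mu,
    drag_k = kdrag,
    rf_capability = athlete$rf_capability),
    class = "truth_record")

  list(run = run, truth = truth)
}

# Split a net force vector into outside/inside limb vectors whose vector sum
# is exactly the net force, whose magnitudes sum to S_target (>= |F|), and
# whose magnitude ratio is out_share : (1 - out_share). Classic two-link
# construction: both limb vectors lie in the plane spanned by F and the
# tangent T, at angles given by the law of cosines.
split_limb_forces <- function(Fx, Fy, Fz, S_target, out_share, Tx, Ty, Tz) {
  Fmag <- sqrt(Fx^2 + Fy^2 + Fz^2)
  S <- pmax(S_target, Fmag)
  Mo <- S * out_share
  Mi <- S - Mo
  ok <- Fmag > 1e-9
  ex <- ifelse(ok, Fx / Fmag, 0)
  ey <- ifelse(ok, Fy / Fmag, 0)
  ez <- ifelse(ok, Fz / Fmag, 1)
  # in-plane perpendicular from the tangent direction
  dot <- Tx * ex + Ty * ey + Tz * ez
  px <- Tx - dot * ex; py <- Ty - dot * ey; pz <- Tz - dot * ez
  pn <- sqrt(px^2 + py^2 + pz^2)
  deg <- pn < 1e-9
  px <- ifelse(deg, 1 - ex^2, px)   # fall back to x-axis component
  py <- ifelse(deg, -ex * ey, py)
  pz <- ifelse(deg, -ex * ez, pz)
  pn <- sqrt(px^2 + py^2 + pz^2)
  pn[pn < 1e-12] <- 1
  px <- px / pn; py <- py / pn; pz <- pz / pn
  cth <- (Fmag^2 + Mo^2 - Mi^2) / (2 * pmax(Fmag * Mo, 1e-12))
  cth <- pmin(pmax(cth, -1), 1)
  sth <- sqrt(1 - cth^2)
  ox <- Mo * (cth * ex + sth * px)
  oy <- Mo * (cth * ey + sth * py)
  oz <- Mo * (cth * ez + sth * pz)
  out <- cbind(ox, oy, oz)
  out[!ok, ] <- 0
  ins <- cbind(Fx, Fy, Fz) - out
  list(out = out, ins = ins)
}

random_calibration <- function() {
  # scaled random rotation: raw-to-Newton map, well conditioned by design
  th <- runif(3, -pi, pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0), c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  s <- runif(1, 1500, 2500)   # N per raw unit
  s * (Rz %*% Ry %*% Rx)
}

band_limited_noise <- function(n, fs, f_lo, f_hi, sd_target) {
  x <- rnorm(n)
  bf <- signal::butter(2, c(f_lo, f_hi) / (fs / 2), type = "pass")
  y <- signal::filter(bf, x)
  y <- as.numeric(y)
  s <- sd(y)
  if (s < 1e-12) return(numeric(n))
  y / s * sd_target
}

#' Simulate a cohort of athletes on a shared course
#'
#' Draws `n_athletes` athlete profiles with heterogeneous dissipation, ratio
#' of force application capability, limb split, mass, line amplitude and
#' clock offset, and simulates one run per athlete on the shared course
#' setting. Deterministic under `seed`.
#'
#' @param n_athletes Number of athletes (>= 3).
#' @param course Base [course_config()]; each athlete's lateral amplitude is
#'   scaled by their drawn line factor.
#' @param spread Named list of parameter ranges:
#'   `dissipation = c(lo, hi)`, `rf = c(lo, hi)`, `limb_split = c(lo, hi)`,
#'   `mass = c(mean, sd)`, `line = c(lo, hi)`, `clock = c(lo, hi)`.
#'   Ranges of zero width are allowed but flagged with a warning because
#'   between-athlete correlations downstream are then undefined.
#' @param seed Integer master seed.
#' @param ... Further arguments passed to [athlete_profile()] (e.g. noise
#'   levels; `noise_sd_force = 0` etc. gives noise-free runs).
#' @return A list of length `n_athletes`; each element has `run`, `truth`
#'   and `profile`.
#' @export
#' @examples
#' cohort <- make_cohort(3, seed = 1, noise_sd_position = 0)
#' length(cohort)
make_cohort <- function(n_athletes = 15,
                        course = course_config(),
                        spread = cohort_spread(),
                        seed = 1L,
                        ...) {
  if (n_athletes < 3)
    stop("n_athletes must be >= 3 (cohort correlations need at least 3 athletes)")
  sp <- utils::modifyList(cohort_spread(), spread)
  widths <- c(diff(sp$dissipation), diff(sp$rf), diff(sp$limb_split),
              sp$mass[2], diff(sp$line))
  if (all(widths == 0))
    warning("degenerate spread: all athletes identical; downstream correlations are undefined")
  set.seed(as.integer(seed))
  prof_seeds <- sample.int(.Machine$integer.max - 1L, n_athletes)
  draws <- data.frame(
    dissipation = runif(n_athletes, sp$dissipation[1], sp$dissipation[2]),
    rf = runif(n_athletes, sp$rf[1], sp$rf[2]),
    limb_split = runif(n_athletes, sp$limb_split[1], sp$limb_split[2]),
    mass = pmax(rnorm(n_athletes, sp$mass[1], sp$mass[2]), 45),
    line = runif(n_athletes, sp$line[1], sp$line[2]),
    clock = runif(n_athletes, sp$clock[1], sp$clock[2]))
  lapply(seq_len(n_athletes), function(i) {
    crs <- course
    crs$gate_offset <- course$gate_offset * draws$line[i]
    prof <- athlete_profile(
      system_mass_BM = draws$mass[i],
      dissipation_coeff = draws$dissipation[i],
      limb_split = draws$limb_split[i],
      rf_capability = draws$rf[i],
      clock_offset = draws$clock[i],
      seed = prof_seeds[i],
      ...)
    sim <- simulate_run(crs, prof)
    list(run = sim$run, truth = sim$truth, profile = prof, athlete_id = i)
  })
}

#' Default cohort parameter spread
#'
#' Ranges for [make_cohort()] draws. The dissipation range brackets the
#' course's equilibrium coefficient so the cohort's speeds stay realistic;
#' the ratio-of-force-application and limb-split ranges bracket typical
#' giant-slalom values (~0.68 and ~2:1).
#'
#' @return Named list of ranges.
#' @export
cohort_spread <- function() {
  list(dissipation = c(0.285, 0.315),
       rf = c(0.62, 0.74),
       limb_split = c(1.75, 2.35),
       mass = c(84, 8),
       line = c(0.96, 1.04),
       clock = c(-5, 5))
}

#' @export
print.raw_run <- function(x, ...) {
  cat(sprintf("<raw_run> %d force samples x 2 plates @ %g Hz, %d trajectory samples @ %g Hz, BW %.0f N\n",
              nrow(x$force) / 2, x$meta$fs_force, nrow(x$traj),
              x$meta$fs_traj, x$meta$BW_newtons))
  invisible(x)
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf("<truth_record> %d turns, course time %.2f s, clock offset %+.3f s, dissipation %.3f, limb split %.2f\n",
              nrow(x$turns), x$course_time, x$clock_offset,
              x$dissipation_coeff, x$limb_split))
  invisible(x)
}
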