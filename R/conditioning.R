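# Conditioning: raw multi-rate streams -> one clean synchronized 200 Hz run.

#' Filtering specification for stream conditioning
#'
#' Smoothing and low-pass parameters applied to the conditioned streams:
#' the resampled trajectory is smoothed with a 2nd-order Savitzky-Golay
#' filter (201-frame window at 200 Hz) and then low-passed with a 2nd-order
#' Butterworth at 1.5 Hz; per-limb resultant forces are low-passed with a
#' 2nd-order Butterworth at 8 Hz. Filters are applied zero-phase
#' (forward-backward) by default so that force and trajectory stay aligned;
#' set `zero_phase = FALSE` for a single causal pass.
#'
#' @param savgol_order Savitzky-Golay polynomial order.
#' @param savgol_window Savitzky-Golay window length, frames (odd, > order).
#' @param butter_order Butterworth order.
#' @param butter_cutoff_force Force low-pass cutoff, Hz.
#' @param butter_cutoff_position Position low-pass cutoff, Hz.
#' @param zero_phase Apply filters forward-backward.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(savgol_order = 2,
                        savgol_window = 201,
                        butter_order = 2,
                        butter_cutoff_force = 8,
                        butter_cutoff_position = 1.5,
                        zero_phase = TRUE) {
  if (savgol_window %% 2 != 1 || savgol_window <= savgol_order)
    stop("savgol_window must be odd and greater than savgol_order")
  stopifnot(butter_order >= 1, butter_cutoff_force > 0,
            butter_cutoff_position > 0)
  structure(list(savgol_order = savgol_order,
                 savgol_window = as.integer(savgol_window),
                 butter_order = butter_order,
                 butter_cutoff_force = butter_cutoff_force,
                 butter_cutoff_position = butter_cutoff_position,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Apply a boot calibration matrix to raw force channels
#'
#' Converts raw sensor output to force units (N) by the linear map
#' `F = C %*% raw` applied samplewise.
#'
#' @param raw Numeric matrix, samples x channels.
#' @param matrix Square calibration matrix, channels x channels; must be
#'   invertible and match `ncol(raw)`.
#' @return Matrix of calibrated forces, same shape as `raw`.
#' @export
#' @examples
#' apply_calibration(cbind(1, 1, 1), diag(2, 3))
apply_calibration <- function(raw, matrix) {
  raw <- as.matrix(raw)
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("calibration matrix must be square")
  if (ncol(raw) != ncol(matrix))
    stop("channel count (", ncol(raw), ") does not match calibration matrix dimension (",
         ncol(matrix), ")")
  d <- det(matrix)
  if (!is.finite(d) || abs(d) < 1e-12) stop("calibration matrix is singular")
  t(matrix %*% t(raw))
}

#' Zero force channels against an unloaded baseline and normalize to bodyweight
#'
#' Subtracts the mean of the unloaded baseline window from each channel and
#' divides by bodyweight in newtons, so the output is in BW units.
#'
#' @param forces Numeric vector or matrix (samples x channels), in N.
#' @param baseline Logical or integer index of the unloaded baseline samples.
#' @param BW_newtons Bodyweight (total system mass x g), N.
#' @param movement_tol Warn if the baseline channel SD exceeds this fraction
#'   of BW (baseline likely overlaps movement).
#' @return Zeroed forces in BW units, same shape as `forces`.
#' @export
#' @examples
#' zero_and_normalize(c(50, 50, 850), baseline = 1:2, BW_newtons = 800)
zero_and_normalize <- function(forces, baseline, BW_newtons,
                               movement_tol = 0.05) {
  stopifnot(BW_newtons > 0)
  vec <- is.null(dim(forces))
  m <- as.matrix(forces)
  bl <- m[baseline, , drop = FALSE]
  if (nrow(bl) < 2) stop("baseline window too short")
  if (any(apply(bl, 2, sd) > movement_tol * BW_newtons))
    warning("baseline window is not quiet (SD > ", movement_tol,
            " BW): zero offset may be biased by movement")
  out <- sweep(m, 2, colMeans(bl)) / BW_newtons
  if (vec) drop(out) else out
}

#' Resample a series with cubic-spline interpolation
#'
#' Natural cubic interpolation through the original samples (exact at the
#' knots, exact for cubic polynomials), used to bring the 10 Hz trajectory
#' onto the 200 Hz force clock.
#'
#' @param t Sample times of `y`, strictly increasing.
#' @param y Numeric vector or matrix (samples x channels).
#' @param t_out Output sample times.
#' @return Interpolated values at `t_out` (vector or matrix).
#' @export
resample_cubic <- function(t, y, t_out) {
  if (length(t) < 4) stop("need at least 4 samples for cubic resampling")
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  vec <- is.null(dim(y))
  m <- as.matrix(y)
  out <- apply(m, 2, function(col) splinefun(t, col, method = "fmm")(t_out))
  out <- matrix(out, nrow = length(t_out), ncol = ncol(m),
                dimnames = list(NULL, colnames(m)))
  if (vec) drop(out) else out
}

#' Smooth and low-pass filter a conditioned series
#'
#' For `which = "position"`: Savitzky-Golay smoothing followed by the
#' position-stream Butterworth low-pass. For `which = "force"`: the
#' force-stream Butterworth low-pass only. Zero-phase application uses
#' forward-backward filtering over reflected padding; Savitzky-Golay edges
#' use the filter's polynomial edge fits.
#'
#' @param x Numeric vector or matrix (samples x channels).
#' @param fs Sampling rate of `x`, Hz.
#' @param spec A [filter_spec()].
#' @param which `"force"` or `"position"`.
#' @return Filtered series, same shape as `x`.
#' @export
smooth_and_filter <- function(x, fs, spec = filter_spec(),
                              which = c("force", "position")) {
  which <- match.arg(which)
  stopifnot(inherits(spec, "filter_spec"))
  cutoff <- if (which == "force") spec$butter_cutoff_force else
    spec$butter_cutoff_position
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  vec <- is.null(dim(x))
  m <- as.matrix(x)
  need <- max(3 * spec$savgol_window %/% 2, ceiling(3 * fs / cutoff))
  if (nrow(m) < need)
    stop("series too short (", nrow(m), " samples) for the requested filters")
  if (which == "position") {
    m <- apply(m, 2, function(col)
      signal::sgolayfilt(col, p = spec$savgol_order, n = spec$savgol_window))
  }
  bf <- signal::butter(spec$butter_order, cutoff / (fs / 2), type = "low")
  m <- apply(as.matrix(m), 2, function(col)
    butter_apply(col, bf, zero_phase = spec$zero_phase,
                 pad = ceiling(3 * fs / cutoff)))
  out <- matrix(m, ncol = ncol(as.matrix(x)),
                dimnames = list(NULL, colnames(as.matrix(x))))
  if (vec) drop(out) else out
}

# Butterworth application with reflected-edge padding; forward-backward when
# zero_phase so the pass band keeps zero group delay. Each pass is anchored
# at its first sample (the filter sees a signal starting at zero) so the
# zero-state startup transient vanishes for constant segments and decays
# within the padding otherwise.
butter_apply <- function(x, bf, zero_phase = TRUE, pad = 600) {
  n <- length(x)
  pad <- min(pad, n - 1)
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(head_pad, x, tail_pad)
  run <- function(v) as.numeric(signal::filter(bf, v - v[1])) + v[1]
  y <- run(xp)
  if (zero_phase) y <- rev(run(rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Detect the pre- and post-run synchronization jump impulses
#'
#' Finds the two strong isolated peaks that the athlete's double-limbed
#' jumps leave on an accelerometer (or force) magnitude series, one before
#' and one after the run. Peaks are clustered by a minimum separation; the
#' first and last cluster are returned, so unequal impulse heights are
#' handled (isolation, not global maxima).
#'
#' @param t Sample times, s.
#' @param a Accelerometer or force magnitude series.
#' @param threshold Detection threshold on `a`; default
#'   `baseline + 0.4 * (max - baseline)` with `baseline = median(a)`, so
#'   impulses of unequal height are both retained while ordinary run-phase
#'   loading stays below threshold.
#' @param min_separation Minimum time between distinct impulses, s.
#' @return Numeric length-2 vector: times of the pre- and post-run impulse
#'   peaks.
#' @export
detect_jump_impulses <- function(t, a, threshold = NULL, min_separation = 2) {
  stopifnot(length(t) == length(a))
  base <- median(a)
  if (is.null(threshold)) threshold <- base + 0.4 * (max(a) - base)
  hot <- which(a > threshold)
  if (length(hot) < 2)
    stop("fewer than two impulse peaks above threshold: trial unusable for synchronization")
  gaps <- which(diff(t[hot]) > min_separation)
  bounds <- c(0, gaps, length(hot))
  clusters <- lapply(seq_len(length(bounds) - 1), function(i)
    hot[(bounds[i] + 1):bounds[i + 1]])
  if (length(clusters) < 2)
    stop("only one impulse found: need a pre-run and a post-run jump")
  peak_time <- function(idx) t[idx[which.max(a[idx])]]
  c(peak_time(clusters[[1]]), peak_time(clusters[[length(clusters)]]))
}

#' Estimate the clock offset between force and trajectory streams
#'
#' Coarse-then-fine estimate of the trajectory-stream clock offset: the
#' impulse peak-time difference gives a coarse alignment, then the lag
#' maximizing the cross-correlation of the two accelerometer signals within
#' +/- `window` frames of each impulse pair (averaged over the two events,
#' with parabolic sub-frame refinement) gives the final offset.
#'
#' @param t_force,accel_force Force-card accelerometer series (force clock).
#' @param t_traj,accel_traj Trajectory-unit accelerometer series (its own
#'   clock, any rate; resampled internally).
#' @param fs Force-stream sampling rate, Hz.
#' @param window Fine-search half-width, frames at `fs`.
#' @return List: `offset` (s; trajectory clock + offset = force clock),
#'   `coarse`, `lags` (per-event fine lags, s), `ambiguous` (TRUE if a
#'   secondary correlation peak came within 5% of the maximum).
#' @export
estimate_clock_offset <- function(t_force, accel_force, t_traj, accel_traj,
                                  fs = 200, window = 100) {
  pk_f <- detect_jump_impulses(t_force, accel_force)
  pk_g <- detect_jump_impulses(t_traj, accel_traj)
  coarse <- mean(pk_f - pk_g)
  tg <- t_traj + coarse
  lags <- numeric(2)
  ambiguous <- FALSE
  for (e in 1:2) {
    centre <- pk_f[e]
    span <- (window + 2 * fs) / fs    # frames of search + 2 s of support
    seg_t <- t_force[t_force >= centre - span & t_force <= centre + span]
    f_seg <- approx(t_force, accel_force, seg_t)$y
    keep <- seg_t >= min(tg) & seg_t <= max(tg)
    seg_t <- seg_t[keep]; f_seg <- f_seg[keep]
    g_seg <- splinefun(tg, accel_traj, method = "fmm")(seg_t)
    f_seg <- f_seg - mean(f_seg); g_seg <- g_seg - mean(g_seg)
    n <- length(f_seg)
    lag_idx <- -window:window
    cc <- vapply(lag_idx, function(l) {
      if (l >= 0) sum(f_seg[(1 + l):n] * g_seg[1:(n - l)])
      else        sum(f_seg[1:(n + l)] * g_seg[(1 - l):n])
    }, numeric(1))
    i0 <- which.max(cc)
    # secondary-peak ambiguity check away from the main lobe
    far <- abs(lag_idx - lag_idx[i0]) > 10
    if (any(far) && max(cc[far]) > 0.95 * cc[i0]) ambiguous <- TRUE
    frac <- 0
    if (i0 > 1 && i0 < length(cc)) {
      denom <- cc[i0 - 1] - 2 * cc[i0] + cc[i0 + 1]
      if (abs(denom) > 0) frac <- 0.5 * (cc[i0 - 1] - cc[i0 + 1]) / denom
      frac <- max(min(frac, 0.5), -0.5)
    }
    # positive lag means the trajectory signal arrives early: offset grows
    lags[e] <- (lag_idx[i0] + frac) / fs
  }
  if (ambiguous)
    warning("cross-correlation peak ambiguous (secondary peak within 5% of maximum)")
  list(offset = coarse + mean(lags), coarse = coarse, lags = lags,
       ambiguous = ambiguous)
}

#' Condition and synchronize a raw run into a single-clock 200 Hz run
#'
#' Full conditioning chain: per-boot calibration, baseline zeroing and
#' bodyweight normalization, per-limb resultant forces (Butterworth 8 Hz),
#' jump-impulse clock synchronization, cubic-spline resampling of the
#' trajectory onto the force clock, Savitzky-Golay plus Butterworth (1.5 Hz)
#' position smoothing, and outside/inside limb attribution from the signed
#' horizontal path curvature.
#'
#' The returned table carries both the filtered positions (used for
#' curvature, heading and path length) and the unfiltered resampled altitude
#' `z_raw` plus the trajectory-unit velocity channels (used for the energy
#' metrics, where point values must stay unbiased).
#'
#' @param run A `raw_run` (from [simulate_run()] or [read_raw_run()]).
#' @param spec A [filter_spec()].
#' @param velocity_source `"doppler"` uses the trajectory unit's velocity
#'   channels; `"position"` differentiates the filtered positions.
#' @return A `synced_run`: data.table with columns `t, F_out, F_ins, F,
#'   diff, F_left, F_right, x, y, z, z_raw, vx, vy, vz, v, beta, curv_sign`
#'   and metadata in `attr(, "meta")` (including the recovered clock
#'   offset).
#' @export
synchronize <- function(run, spec = filter_spec(),
                        velocity_source = c("doppler", "position")) {
  stopifnot(inherits(run, "raw_run"))
  velocity_source <- match.arg(velocity_source)
  meta <- run$meta
  fs <- meta$fs_force
  g <- meta$gravity_g

  force <- data.table::as.data.table(run$force)
  traj <- data.table::as.data.table(run$traj)
  plates <- list(left = force[force$plate == "left", ],
                 right = force[force$plate == "right", ])
  tf <- plates$left$t_s
  if (!isTRUE(all.equal(tf, plates$right$t_s)))
    stop("left and right plate streams are not on a common clock")

  baseline <- tf >= meta$baseline_window[1] & tf <= meta$baseline_window[2]
  res <- lapply(c("left", "right"), function(p) {
    raw <- as.matrix(plates[[p]][, c("Fx_raw", "Fy_raw", "Fz_raw")])
    cal <- apply_calibration(raw, run$calibration[[p]])
    bw <- zero_and_normalize(cal, baseline, meta$BW_newtons)
    resultant_force(bw[, 1], bw[, 2], bw[, 3])
  })
  names(res) <- c("left", "right")
  # resultants are magnitudes: clip the filter's negative undershoots
  F_left <- pmax(smooth_and_filter(res$left, fs, spec, "force"), 0)
  F_right <- pmax(smooth_and_filter(res$right, fs, spec, "force"), 0)

  sync <- estimate_clock_offset(tf, plates$left$accel_mag,
                                traj$t_s, traj$accel_mag, fs = fs)
  tg <- traj$t_s + sync$offset

  keep <- tf >= tg[1] & tf <= tg[length(tg)]
  t_out <- tf[keep]
  F_left <- F_left[keep]; F_right <- F_right[keep]
  pos <- resample_cubic(tg, as.matrix(traj[, c("x_m", "y_m", "z_m")]), t_out)
  vel <- resample_cubic(tg, as.matrix(traj[, c("vx_ms", "vy_ms", "vz_ms")]), t_out)
  z_raw <- pos[, 3]
  pos_f <- smooth_and_filter(pos, fs, spec, "position")

  if (velocity_source == "position") {
    vel <- cbind(finite_gradient(pos_f[, 1], t_out),
                 finite_gradient(pos_f[, 2], t_out),
                 finite_gradient(pos_f[, 3], t_out))
  }
  v <- sqrt(rowSums(vel^2))
  # heading relative to the contour (across-slope horizontal) direction
  vh <- sqrt(vel[, 1]^2 + vel[, 2]^2)
  cosb <- ifelse(v > 0.5, pmin(abs(vel[, 1]) / pmax(v, 1e-9), 1), 0)
  beta <- acos(cosb)

  # signed horizontal curvature sense from the filtered positions:
  # curv_sign > 0 means the turn centre lies left of travel (counterclockwise
  # seen from above)
  dx <- finite_gradient(pos_f[, 1], t_out)
  dy <- finite_gradient(pos_f[, 2], t_out)
  ddx <- finite_gradient(dx, t_out)
  ddy <- finite_gradient(dy, t_out)
  cross_z <- dx * ddy - dy * ddx
  curv_sign <- sign(cross_z)
  # outside ski is opposite the turn centre; +x is the skier's right when
  # facing downhill (+y), so centre right (cross_z < 0) -> outside = left
  out_is_left <- cross_z < 0
  F_out <- ifelse(out_is_left, F_left, F_right)
  F_ins <- ifelse(out_is_left, F_right, F_left)
  Ftot <- F_left + F_right
  dff <- limb_difference(F_out, F_ins)

  dt <- data.table::data.table(
    t = t_out, F_out = F_out, F_ins = F_ins, F = Ftot, diff = dff,
    F_left = F_left, F_right = F_right,
    x = pos_f[, 1], y = pos_f[, 2], z = pos_f[, 3], z_raw = z_raw,
    vx = vel[, 1], vy = vel[, 2], vz = vel[, 3], v = v,
    beta = beta, curv_sign = curv_sign)
  structure(dt, class = c("synced_run", class(dt)),
            meta = c(meta, list(
              clock_offset_applied = sync$offset,
              sync_lags = sync$lags,
              sync_ambiguous = sync$ambiguous,
              filter_spec = spec,
              velocity_source = velocity_source)))
}
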