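test_that("calibration applies the linear map samplewise", {
  raw <- matrix(c(1, 1, 1, 2, 0.5, -1), ncol = 3, byrow = TRUE)
  expect_equal(apply_calibration(raw, diag(3)), raw)
  expect_equal(apply_calibration(matrix(c(1, 1, 1), ncol = 3), diag(2, 3)),
               matrix(c(2, 2, 2), ncol = 3))
  set.seed(1)
  C <- matrix(rnorm(9), 3)
  X <- matrix(rnorm(30), ncol = 3)
  # brute-force oracle: row-by-row matrix-vector products
  oracle <- t(vapply(seq_len(nrow(X)), function(i) as.numeric(C %*% X[i, ]),
                     numeric(3)))
  expect_equal(apply_calibration(X, C), oracle, tolerance = 1e-12)
  expect_error(apply_calibration(X[, 1:2], C), "channel count")
  expect_error(apply_calibration(X, matrix(0, 3, 3)), "singular")
})

test_that("zeroing and bodyweight normalization", {
  x <- c(50, 50, 50, 850)
  expect_equal(zero_and_normalize(x, 1:3, 800)[4], 1.0)
  expect_equal(zero_and_normalize(rep(50, 10), 1:10, 800), rep(0, 10))
  loaded <- c(rnorm(50, 0, 1), rnorm(50, 400, 200))
  expect_warning(zero_and_normalize(loaded, 1:100, 800), "not quiet")
})

test_that("cubic resampling is exact at knots and for cubic signals", {
  t10 <- seq(0, 5, by = 0.1)
  t200 <- seq(0, 5, by = 1 / 200)
  ramp <- 2 * t10 - 1
  expect_equal(resample_cubic(t10, ramp, t10), ramp, tolerance = 1e-12)
  expect_equal(resample_cubic(t10, ramp, t200), 2 * t200 - 1,
               tolerance = 1e-10)
  cub <- t10^3 - 2 * t10^2 + 0.5
  expect_equal(resample_cubic(t10, cub, t200), t200^3 - 2 * t200^2 + 0.5,
               tolerance = 1e-9)
  sine <- sin(2 * pi * 0.5 * t10)
  err <- resample_cubic(t10, sine, t200) - sin(2 * pi * 0.5 * t200)
  expect_lt(max(abs(err)), 1e-3)
  expect_error(resample_cubic(c(0, 0.1, 0.1, 0.3), 1:4, t200),
               "strictly increasing")
  expect_error(resample_cubic(c(0, 1, 2), 1:3, t200), "at least 4")
})

test_that("smoothing preserves constants and quadratic trends in the interior", {
  fs <- 200
  t <- seq(0, 10, by = 1 / fs)
  const <- rep(3.7, length(t))
  expect_equal(smooth_and_filter(const, fs, which = "force"), const,
               tolerance = 1e-9)
  quad <- 0.2 * t^2 - t + 4
  out <- smooth_and_filter(quad, fs, which = "position")
  interior <- t > 2 & t < 8
  expect_equal(out[interior], quad[interior], tolerance = 1e-6)
})

test_that("single-pass Butterworth matches the analytic magnitude response", {
  fs <- 200
  t <- seq(0, 6, by = 1 / fs)
  f <- 20
  x <- sin(2 * pi * f * t)
  spec <- filter_spec(zero_phase = FALSE)
  y <- smooth_and_filter(x, fs, spec, which = "force")
  interior <- t > 2 & t < 4
  # least-squares amplitude of the 20 Hz component in the settled interior
  basis <- cbind(sin(2 * pi * f * t[interior]), cos(2 * pi * f * t[interior]))
  gain <- sqrt(sum(coef(lm(y[interior] ~ basis - 1))^2))
  # closed-form 2nd-order Butterworth magnitude; the digital design is
  # frequency-prewarped, so evaluate at the warped frequency ratio
  warp <- tan(pi * f / fs) / tan(pi * spec$butter_cutoff_force / fs)
  H <- 1 / sqrt(1 + warp^4)
  expect_equal(gain, H, tolerance = 0.02)
  # and the analog response is approached at low frequency ratios
  H_analog <- 1 / sqrt(1 + (f / spec$butter_cutoff_force)^4)
  expect_equal(gain, H_analog, tolerance = 0.1)
})

test_that("filtering an already band-limited signal is near idempotent", {
  fs <- 200
  t <- seq(0, 20, by = 1 / fs)
  x <- sin(2 * pi * 0.4 * t) + 0.5 * sin(2 * pi * 1.1 * t)
  once <- smooth_and_filter(x, fs, which = "force")
  twice <- smooth_and_filter(once, fs, which = "force")
  interior <- t > 2 & t < 18
  rel_rms <- sqrt(mean((twice - once)[interior]^2)) /
    sqrt(mean(once[interior]^2))
  expect_lt(rel_rms, 0.01)
})

test_that("resultant magnitude is invariant to joint channel rotation", {
  set.seed(7)
  X <- matrix(rnorm(60), ncol = 3)
  th <- runif(1, 0, 2 * pi)
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Xr <- apply_calibration(X, R)
  expect_equal(resultant_force(X[, 1], X[, 2], X[, 3]),
               resultant_force(Xr[, 1], Xr[, 2], Xr[, 3]), tolerance = 1e-12)
})

test_that("jump impulse detection finds isolated pre/post peaks", {
  t <- seq(0, 50, by = 1 / 200)
  a <- 9.81 + 0.1 * sin(2 * pi * 0.5 * t)
  a <- a + 40 * exp(-0.5 * ((t - 2) / 0.1)^2) + 30 * exp(-0.5 * ((t - 40) / 0.1)^2)
  pk <- detect_jump_impulses(t, a)
  expect_equal(pk, c(2, 40), tolerance = 1 / 200)
  expect_error(detect_jump_impulses(t, rep(9.81, length(t))), "impulse")
  # unequal heights, and a taller event between the jumps, must not
  # displace the detected pre/post impulses (isolation, not global max)
  a2 <- a + 60 * exp(-0.5 * ((t - 20) / 0.1)^2)
  pk2 <- detect_jump_impulses(t, a2)
  expect_equal(pk2, c(2, 40), tolerance = 1 / 200)
})

test_that("clock offset is recovered within one frame", {
  sim <- demo_sim()
  synced <- quiet_processed()  # warms cache for later tests
  m <- attr(demo_processed()$synced, "meta")
  expect_lt(abs(m$clock_offset_applied - sim$truth$clock_offset), 0.005)
  # zero-offset run
  sim0 <- simulate_run(course_config(), athlete_profile(seed = 21, clock_offset = 0))
  est <- estimate_clock_offset(
    sim0$run$force$t_s[sim0$run$force$plate == "left"],
    sim0$run$force$accel_mag[sim0$run$force$plate == "left"],
    sim0$run$traj$t_s, sim0$run$traj$accel_mag)
  expect_lt(abs(est$offset), 0.005)
})

test_that("offsets beyond the fine window are recovered via coarse alignment", {
  sim <- simulate_run(course_config(),
                      athlete_profile(seed = 22, clock_offset = 4.8))
  # 4.8 s >> the +/-0.5 s fine cross-correlation window
  pr <- attr(synchronize(sim$run), "meta")
  expect_lt(abs(pr$clock_offset_applied - 4.8), 0.005)
})

test_that("synchronized run satisfies the total-force identity", {
  synced <- quiet_processed()$synced
  expect_equal(synced$F, synced$F_out + synced$F_ins, tolerance = 1e-12)
  expect_true(all(synced$F_out >= 0 & synced$F_ins >= 0))
  expect_true(all(abs(synced$beta) <= pi))
})

test_that("conditioned limb attribution recovers the simulated outside:inside split", {
  pr <- quiet_processed()
  sim <- quiet_sim()
  recs <- pr$summary$turns
  ratio <- recs$F_out / recs$F_ins
  expect_true(all(ratio > 1.5))  # true split is 2:1
  expect_equal(mean(ratio), sim$truth$limb_split, tolerance = 0.1)
})
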