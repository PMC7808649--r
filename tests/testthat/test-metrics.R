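# helper: synthetic synced_run with the column set and metadata the metric
# layer expects
make_synced <- function(df, alpha_deg = 0, g = 9.81) {
  structure(data.table::as.data.table(df),
            class = c("synced_run", "data.table", "data.frame"),
            meta = list(alpha_deg = alpha_deg, gravity_g = g,
                        fs_force = 200))
}

# circle trajectory at constant speed on a flat slope
circle_synced <- function(R = 30, v = 15, fs = 200, dur = 20,
                          noise = 0, seed = 1) {
  set.seed(seed)
  t <- seq(0, dur, by = 1 / fs)
  om <- v / R
  x <- R * cos(om * t) + rnorm(length(t), sd = noise)
  y <- R * sin(om * t) + rnorm(length(t), sd = noise)
  vx <- -R * om * sin(om * t)
  vy <- R * om * cos(om * t)
  make_synced(data.frame(
    t = t, x = x, y = y, z = 0, z_raw = 0,
    vx = vx, vy = vy, vz = 0, v = sqrt(vx^2 + vy^2),
    beta = 0, curv_sign = 1,
    F_left = 1, F_right = 0.5, F_out = 1, F_ins = 0.5, F = 1.5,
    diff = limb_difference(1, 0.5)))
}

test_that("resultant force is the Euclidean norm", {
  expect_equal(resultant_force(0, 0, 0), 0)
  expect_equal(resultant_force(3, 4, 0), 5)
  set.seed(3)
  X <- matrix(rnorm(30), ncol = 3)
  oracle <- apply(X, 1, function(r) sqrt(sum(r^2)))
  expect_equal(resultant_force(X[, 1], X[, 2], X[, 3]), oracle,
               tolerance = 1e-12)
})

test_that("limb difference ratio behaves at the boundaries and matches printed values", {
  expect_equal(limb_difference(1, 1), 0)
  expect_equal(limb_difference(1, 0), 1)
  # printed course means: 1.06 and 0.54 BW give 0.52/1.60 = 0.325 ~ 0.32
  expect_equal(limb_difference(1.06, 0.54), 0.325, tolerance = 1e-12)
  expect_equal(round(limb_difference(1.06, 0.54), 2), 0.32)
  expect_true(is.na(limb_difference(0, 0)))
})

test_that("three-point arc radius is exact on circles and capped when collinear", {
  th <- c(0.1, 0.7, 1.9)
  x <- cos(th); y <- sin(th); z <- rep(0, 3)
  r3 <- turn_radius(x, y, z, spacing = 1)
  expect_equal(r3[2], 1, tolerance = 1e-12)
  rc <- turn_radius(c(0, 1, 2), c(0, 1, 2), c(0, 0, 0), spacing = 1)
  expect_equal(rc[2], 1000)
  expect_equal(attr(rc, "n_capped"), 1L)
})

test_that("arc radius agrees with an independent circumcircle oracle on random triples", {
  set.seed(42)
  for (i in 1:25) {
    P <- matrix(rnorm(9, sd = 5), ncol = 3)
    r <- turn_radius(P[, 1], P[, 2], P[, 3], spacing = 1, r_max = Inf)[2]
    expect_equal(r, circumradius_oracle(P[1, ], P[2, ], P[3, ]),
                 tolerance = 1e-9)
  }
})

test_that("radius recovery on a 30 m circle: 0.1% noise-free, 3% at configured noise", {
  clean <- circle_synced(R = 30, v = 15, noise = 0)
  r <- turn_radius(clean$x, clean$y, clean$z, spacing = 60)
  expect_equal(mean(r, na.rm = TRUE), 30, tolerance = 0.001)

  # configured position noise, conditioned as in the pipeline: 10 Hz native
  # samples, cubic resampling to 200 Hz, position smoothing, then the fit
  set.seed(8)
  t10 <- seq(0, 40, by = 0.1)
  om <- 15 / 30
  x10 <- 30 * cos(om * t10) + rnorm(length(t10), sd = 0.05)
  y10 <- 30 * sin(om * t10) + rnorm(length(t10), sd = 0.05)
  t200 <- seq(0, 40, by = 1 / 200)
  pos <- smooth_and_filter(resample_cubic(t10, cbind(x10, y10), t200),
                           200, filter_spec(), "position")
  rn <- turn_radius(pos[, 1], pos[, 2], spacing = 60)
  interior <- seq_along(rn) > 1000 & seq_along(rn) < length(rn) - 1000
  expect_equal(mean(rn[interior], na.rm = TRUE), 30, tolerance = 0.03)
})

test_that("radial force matches hand-computed values", {
  expect_equal(radial_force(0, 10, alpha = 0), 0)
  expect_equal(radial_force(14, 20, alpha = 0), (196 / 20) / 9.81,
               tolerance = 1e-12)
  expect_equal(radial_force(14, 20, alpha = 0), 0.999, tolerance = 1e-3)
  # straight glide on a 25 degree slope: gravity term alone
  expect_equal(radial_force(15, Inf, alpha = 25, beta = 0), sin(25 * pi / 180),
               tolerance = 1e-12)
  expect_equal(radial_force(15, Inf, alpha = 25, beta = 0), 0.423,
               tolerance = 1e-3)
  expect_error(radial_force(10, 0, alpha = 0), "positive")
})

test_that("radial force equals the closed form on a circular turn", {
  syn <- circle_synced(R = 30, v = 15)
  ks <- gsforce:::kinetic_series(syn)
  interior <- !is.na(ks$r)
  expect_equal(mean(ks$r[interior]), 30, tolerance = 0.001)
  expect_equal(mean(ks$F_r[interior]), 15^2 / (30 * 9.81), tolerance = 0.005)
})

test_that("ratio of forces and its edge cases", {
  expect_equal(ratio_of_forces(1.2, 1.2), 1)
  expect_equal(ratio_of_forces(1.06, 1.60), 0.6625)
  expect_error(ratio_of_forces(1, 0), "positive")
})

test_that("energy metric matches hand computation and printed magnitudes", {
  expect_equal(delta_emech_per_vin(15, 14, 0, -9),
               ((196 - 225) / 2 + 9.81 * (-9)) / 15, tolerance = 1e-12)
  expect_equal(delta_emech_per_vin(15, 14, 0, -9), -6.853, tolerance = 1e-3)
  # constant speed, 9.33 m drop per turn at 15.6 m/s: within the printed
  # course spread -5.59 +/- 0.52
  val <- delta_emech_per_vin(15.6, 15.6, 0, -9.33)
  expect_equal(val, -5.87, tolerance = 1e-2)
  expect_gt(val, -5.59 - 2 * 0.52)
  expect_lt(val, -5.59 + 2 * 0.52)
  expect_error(delta_emech_per_vin(0, 1, 0, 0), "positive")
})

test_that("turn summary on a constant-force straight segment", {
  t <- seq(0, 5, by = 1 / 200)
  v <- 12
  syn <- make_synced(data.frame(
    t = t, x = 0 * t, y = v * t, z = 0, z_raw = 0,
    vx = 0, vy = v, vz = 0, v = v, beta = 0, curv_sign = 0,
    F_left = 1.0, F_right = 0.5, F_out = 1.0, F_ins = 0.5, F = 1.5,
    diff = limb_difference(1.0, 0.5)))
  b <- data.frame(turn_index = 1, start_t = 1, end_t = 4, section = "speed")
  rec <- summarize_turn(syn, b)
  expect_equal(rec$F_tot, 1.5, tolerance = 1e-12)
  expect_equal(rec$F_max, 1.5, tolerance = 1e-12)
  expect_equal(rec$T_turn, 3)
  expect_equal(rec$L, v * 3, tolerance = 1e-6)
  expect_equal(rec$de_per_vin, 0, tolerance = 1e-12)
})

test_that("course means equal the mean of per-turn records by definition", {
  s <- quiet_processed()$summary
  expect_equal(s$course[["F_tot"]], mean(s$turns$F_tot), tolerance = 1e-12)
  expect_equal(s$course[["F_tot"]], s$course[["F_out"]] + s$course[["F_ins"]],
               tolerance = 1e-12)
  sec_n <- table(s$turns$section)
  expect_equal(unname(sec_n[c("speed", "overspeed", "flat")]),
               c(5L, 5L, 4L), ignore_attr = TRUE)
})

test_that("per-turn radial force and energy metrics track simulator truth", {
  pr <- quiet_processed()
  tr <- quiet_sim()$truth$turns
  est <- pr$summary$turns
  sel <- est$turn_index %in% 4:15
  tru <- tr[match(est$turn_index[sel], tr$turn_index), ]
  expect_equal(est$F_r[sel], tru$F_r_true, tolerance = 0.02)
  expect_equal(est$de_per_vin[sel], tru$de_per_vin_true, tolerance = 0.01)
  expect_equal(est$v_in[sel], tru$v_in_true, tolerance = 0.01)
  expect_equal(est$L[sel], tru$L_true, tolerance = 0.01)
})

test_that("per-turn radial force is the product of total force and RF (quasi-identity)", {
  turns <- do.call(rbind, lapply(default_pipeline()$summaries,
                                 function(s) s$turns))
  fit <- lm(F_r ~ F_tot + RF, data = turns)
  expect_gt(summary(fit)$r.squared, 0.99)
})
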