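test_that("static gravity estimation is accurate and guarded", {
  fs <- 250
  n <- 5 * fs
  still <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  rec <- triaxial_recording(still, fs)
  expect_equal(estimate_static_gravity(rec), c(0, 0, 1))

  # isotropic 0.01 g noise: direction within 0.2 degrees over seeds
  errs <- vapply(1:10, function(s) {
    set.seed(s)
    noisy <- triaxial_recording(still + matrix(rnorm(3 * n, 0, 0.01), n, 3), fs)
    g <- estimate_static_gravity(noisy)
    acos(min(1, sum(g * c(0, 0, 1)))) * 180 / pi
  }, numeric(1))
  expect_lt(max(errs), 0.2)

  half <- triaxial_recording(still * 0.5, fs)
  expect_error(estimate_static_gravity(half), "outside")
  set.seed(1)
  shaky <- triaxial_recording(still + matrix(rnorm(3 * n, 0, 0.2), n, 3), fs)
  expect_error(estimate_static_gravity(shaky), "still")
})

test_that("Rodrigues rotation maps from onto to and is proper", {
  v <- c(0.3, -0.5, 0.81)
  expect_equal(rodrigues_rotation(v, v)$R, diag(3), tolerance = 1e-12)

  r <- rodrigues_rotation(c(0, 0, 1), c(-1, 0, 0))
  expect_equal(as.vector(r$R %*% c(0, 0, 1)), c(-1, 0, 0), tolerance = 1e-9)
  # rotation angle 90 degrees: trace = 1 + 2 cos(angle)
  expect_equal(sum(diag(r$R)), 1, tolerance = 1e-9)

  # antiparallel case: some 180-degree rotation with R v = -v
  u <- c(0.6, 0.8, 0) / 1
  ra <- rodrigues_rotation(u, -u)
  expect_equal(as.vector(ra$R %*% u), -u, tolerance = 1e-9)

  # orthogonality and unit determinant for random pairs
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3)
    R <- rodrigues_rotation(a, b)$R
    expect_lt(max(abs(R %*% t(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
    expect_lt(max(abs(as.vector(R %*% (a / sqrt(sum(a^2)))) -
                        b / sqrt(sum(b^2)))), 1e-9)
  }
})

test_that("alignment is an isometry and identity rotation is a no-op", {
  set.seed(3)
  vals <- matrix(rnorm(300), 100, 3)
  rec <- triaxial_recording(vals, 250)
  rid <- rodrigues_rotation(c(1, 0, 0), c(1, 0, 0))
  expect_equal(align_recording(rec, rid)$values[, 1], vals[, 1])

  rot <- rodrigues_rotation(c(0.2, 0.5, -0.8), anatomical_gravity_reference())
  out <- align_recording(rec, rot)
  expect_lt(max(abs(sqrt(rowSums(out$values^2)) - sqrt(rowSums(vals^2)))),
            1e-9)
})

test_that("pitch angle follows the atan2 convention", {
  mk <- function(ax, az) {
    triaxial_recording(matrix(c(ax, 0, az), 1, 3)[rep(1, 10), ], 250)
  }
  expect_equal(as.vector(pitch_angle(mk(-1, 0))$values)[1], 0)
  expect_equal(as.vector(pitch_angle(mk(0, 1))$values)[1], pi / 2)
  expect_equal(as.vector(pitch_angle(mk(-cos(pi / 6), sin(pi / 6)))$values)[1],
               pi / 6, tolerance = 1e-12)
})

test_that("numerical differentiation is second-order accurate", {
  fs <- 250
  t <- seq(0, 2, by = 1 / fs)
  ramp <- uniform_signal(2.5 * t, fs)
  expect_lt(max(abs(differentiate(ramp)$values - 2.5)), 1e-9)

  s <- uniform_signal(sin(2 * pi * t), fs)
  err <- abs(differentiate(s)$values - 2 * pi * cos(2 * pi * t))
  n <- length(err)
  expect_lt(max(err[2:(n - 1)]), 1e-3)       # central: h^2 |f'''| / 6
  expect_lt(max(err[c(1, n)]), 2e-3)         # one-sided: h^2 |f'''| / 3

  cst <- uniform_signal(rep(1, 100), fs)
  expect_equal(max(abs(differentiate(cst)$values)), 0)
})

test_that("rotational power matches the raised-cosine closed form", {
  fs <- 250
  # theta: pi/2 -> 0 over 1 s; peak RP = pi^5/32 at t = T/4 of the descent
  th <- rc_pitch_signal(pi / 2, 1, fs)
  rp <- rotational_power(th, bypass_filter = TRUE)
  expect_equal(max(rp$values), pi^5 / 32, tolerance = 0.005)
  expect_equal(max(rp$values), rc_peak_oracle(pi / 2, 1), tolerance = 0.005)

  # 1/T^3 law: doubling T divides the peak by 8
  th2 <- rc_pitch_signal(pi / 2, 2, fs)
  rp2 <- rotational_power(th2, bypass_filter = TRUE)
  expect_equal(max(rp2$values) / max(rp$values), 1 / 8, tolerance = 0.005)

  # invariance to a constant pitch offset
  th_off <- uniform_signal(th$values + 0.7, fs)
  rp_off <- rotational_power(th_off, bypass_filter = TRUE)
  expect_equal(rp_off$values, rp$values, tolerance = 1e-9)

  # constant pitch has zero rotational power
  expect_equal(max(abs(rotational_power(uniform_signal(rep(1, 1000), fs),
                                        bypass_filter = TRUE)$values)), 0)
})

test_that("vertical power matches the closed form and its symmetries", {
  fs <- 100
  z <- rc_height_signal(0.3, 1, fs)
  p <- vertical_power_from_height(z, bypass_filter = TRUE)
  expect_equal(max(p$values), 0.3^2 * pi^3 / 8, tolerance = 0.005)

  # mirrored descent gives the identical positive peak
  zd <- uniform_signal(rev(z$values), fs)
  pd <- vertical_power_from_height(zd, bypass_filter = TRUE)
  expect_equal(max(pd$values), max(p$values), tolerance = 1e-6)

  # invariance to a height offset; flat height gives zero power
  z_off <- uniform_signal(z$values + 10, fs)
  expect_equal(vertical_power_from_height(z_off, bypass_filter = TRUE)$values,
               p$values, tolerance = 1e-9)
  expect_equal(max(abs(vertical_power_from_height(
    uniform_signal(rep(0.5, 500), fs), bypass_filter = TRUE)$values)), 0)
})

test_that("full-pipeline filtering keeps the closed-form peaks within 5%", {
  fs <- 250
  th <- rc_pitch_signal(pi / 2, 1, fs, hold_s = 3)
  acc <- quasi_static_accel(th)
  accf <- bessel_lowpass(acc, filter_spec(4L, 2))
  class(accf) <- class(acc)
  rp <- rotational_power(pitch_angle(accf))  # includes the 2.5 Hz stage
  expect_equal(max(rp$values), pi^5 / 32, tolerance = 0.05)

  z <- rc_height_signal(0.3, 1, 100, hold_s = 3)
  p <- vertical_power_from_height(z)  # includes the 2 Hz stage
  expect_equal(max(p$values), 0.3^2 * pi^3 / 8, tolerance = 0.05)
})

test_that("known misalignment is recovered end to end in the quasi-static case", {
  cfg <- sim_config(seed = 4, accel_noise_sd = 0, marker_noise_sd = 0,
                    misalignment_angle = 0.35, fatigue_decay = 0)
  ses <- simulate_session(cfg, 1, capacity = 1)
  rot <- rodrigues_rotation(estimate_static_gravity(ses$calib),
                            anatomical_gravity_reference())
  aligned <- align_recording(ses$accel, rot)
  alf <- bessel_lowpass(aligned, filter_spec(4L, 2))
  class(alf) <- class(aligned)
  theta_est <- pitch_angle(alf)
  t_a <- signal_time(ses$accel)
  # true pitch on the accelerometer clock
  tr <- ses$truth$transitions
  phi <- rotpower:::eval_phi(t_a - cfg$true_lag, tr)
  theta_true <- cfg$pitch_amplitude * (1 - phi)
  interior <- t_a > 3 & t_a < max(t_a) - 3
  err_deg <- max(abs(theta_est$values[interior] - theta_true[interior])) *
    180 / pi
  expect_lt(err_deg, 1)
})

test_that("simulated static calibration recovers the misaligned gravity direction", {
  cfg <- sim_config(seed = 6)
  ses <- simulate_session(cfg, 1, capacity = 1)
  g <- estimate_static_gravity(ses$calib)
  ang <- acos(min(1, sum(g * ses$truth$gravity_device))) * 180 / pi
  expect_lt(ang, 0.5)
})
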