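test_that("raised-cosine profiles have the stated endpoints and product peak", {
  p <- raised_cosine_profile(0.2, 1.2, T_s = 1, fs = 250)
  v <- as.vector(p$values)
  expect_equal(v[1], 0.2)
  expect_equal(v[length(v)], 1.2)
  expect_equal(v[round(length(v) / 2)], 0.7, tolerance = 1e-3)

  d1 <- differentiate(p); d2 <- differentiate(d1)
  prod_peak <- max(d1$values * d2$values)
  expect_equal(prod_peak, rc_peak_oracle(1.0, 1), tolerance = 0.005)
  # peak sits at t = T/4
  expect_equal(signal_time(p)[which.max(d1$values * d2$values)], 0.25,
               tolerance = 0.02)
})

test_that("session simulation is deterministic and honors its invariants", {
  cfg <- sim_config(seed = 12)
  s1 <- simulate_session(cfg, 3)
  s2 <- simulate_session(cfg, 3)
  expect_identical(s1$accel$values, s2$accel$values)
  expect_identical(s1$markers$left$values, s2$markers$left$values)
  expect_identical(s1$calib$values, s2$calib$values)

  # different subjects get different streams
  s3 <- simulate_session(cfg, 4)
  expect_false(identical(s1$accel$values, s3$accel$values))

  # static segments of the accelerometer have norm ~ 1 g
  norms <- sqrt(rowSums(s1$calib$values^2))
  expect_lt(abs(mean(norms) - 1), 0.01)

  expect_error(sim_config(transition_duration = 2, rep_period = 2.5),
               "rep_period")
  expect_error(sim_config(fatigue_decay = 0.7), "fatigue_decay")
  expect_error(sim_config(pitch_amplitude = 2), "pitch_amplitude")
})

test_that("fatigue decay makes ground-truth peak powers strictly decreasing", {
  ses <- simulate_session(sim_config(seed = 2, fatigue_decay = 0.05), 1,
                          capacity = 1)
  tr <- ses$truth$transitions
  rpp_sist <- tr$rp_peak[tr$label == "SI-ST"]
  expect_true(all(diff(rpp_sist) < 0))
})

test_that("a clean default session yields 12 true and 12 detected repetitions", {
  cfg <- sim_config(seed = 1, go_delay = 0, fatigue_decay = 0,
                    accel_noise_sd = 0, marker_noise_sd = 0,
                    misalignment_angle = 0)
  ses <- simulate_session(cfg, 1, capacity = 1)
  expect_equal(ses$truth$n_reps, 12L)
  res <- suppressWarnings(process_session(ses$accel, ses$markers, ses$calib))
  expect_equal(res$n_reps, 12L)
})

test_that("pipeline RPP and VPP close the loop on the simulator ground truth", {
  cfg <- sim_config(seed = 3, accel_noise_sd = 0, marker_noise_sd = 0,
                    fatigue_decay = 0.04)
  ses <- simulate_session(cfg, 1, capacity = 1)
  res <- suppressWarnings(process_session(ses$accel, ses$markers, ses$calib))
  m <- merge(res$transitions, ses$truth$transitions, by = "index",
             suffixes = c("", ".true"))
  m <- m[m$t_f <= 29 & m$t_i >= 1, ]  # away from recording edges
  expect_true(all(m$label == m$label.true))
  # full pipeline (filters enabled, in-band kinematics): peaks within 5%
  expect_lt(max(abs(m$rpp / m$rp_peak - 1)), 0.05)
  expect_lt(max(abs(m$vpp / m$vp_peak - 1)), 0.05)
})

test_that("cohort scores couple to capacity with the expected signs", {
  co <- simulate_cohort(sim_config(seed = 7))
  expect_equal(nrow(co$scores), 17)
  expect_gt(cor(co$capacities, co$scores$abc), 0)
  expect_lt(cor(co$capacities, co$scores$mfis_total), 0)
  expect_true(all(co$scores$abc >= 0 & co$scores$abc <= 100))
  expect_equal(co$scores$mfis_total,
               co$scores$mfis_physical + co$scores$mfis_cognitive +
                 co$scores$mfis_psychosocial)

  # determinism of the cohort draw
  co2 <- simulate_cohort(sim_config(seed = 7))
  expect_identical(co$transitions, co2$transitions)
  expect_identical(co$scores, co2$scores)

  # zero coupling centres the correlations near zero over seeds
  rs <- vapply(1:20, function(s) {
    cz <- simulate_cohort(sim_config(seed = s, abc_gain = 0, mfis_gain = 0))
    cor(cz$summaries$rp95c_sist, cz$scores$abc)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.2)
})

test_that("cohort sign pattern matches the clinical validation structure", {
  ok <- vapply(1:20, function(s) {
    co <- simulate_cohort(sim_config(seed = s))
    tab <- clinical_correlations(co$summaries, co$scores)
    pos <- tab$score %in% c("n_reps", "abc")
    all(tab$coefficient[pos] > 0) && all(tab$coefficient[!pos] < 0)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
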