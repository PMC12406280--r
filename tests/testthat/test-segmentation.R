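test_that("degenerate displacement signals yield no transitions", {
  flat <- uniform_signal(rep(0.5, 1000), 100)
  expect_warning(seg <- segment_transitions(flat), "no transitions")
  expect_equal(nrow(seg), 0)
  expect_equal(count_valid_reps(seg), 0L)
})

test_that("a single rise then fall is exactly one SI-ST and one ST-SI", {
  fs <- 100
  t <- seq(0, 6, by = 1 / fs)
  z <- 0.5 + 0.3 * exp(-((t - 3) / 0.8)^2)
  seg <- segment_transitions(uniform_signal(z, fs))
  expect_equal(seg$label, c("SI-ST", "ST-SI"))
})

test_that("simulated sessions are segmented with correct labels and boundaries", {
  cfg <- sim_config(seed = 8, fatigue_decay = 0, accel_noise_sd = 0,
                    marker_noise_sd = 0, session_duration = 29)
  ses <- simulate_session(cfg, 1, capacity = 1)
  zf <- bessel_lowpass(com_height(ses$markers), filter_spec(4L, 2))
  seg <- segment_transitions(zf)
  tr <- ses$truth$transitions
  tr <- tr[tr$t_f <= 29, ]
  expect_equal(nrow(seg), nrow(tr))
  expect_equal(sum(seg$label == "SI-ST"), sum(tr$label == "SI-ST"))
  expect_equal(seg$label, tr$label)
  # boundaries are the z extrema, which land in the postural hold separating
  # consecutive transitions; noise-free they stay within one hold (0.35 s)
  # of the configured transition edges
  hold <- (2.5 - 2 * 0.9) / 2
  expect_lt(max(abs(seg$t_i - tr$t_i)), hold)
  expect_lt(max(abs(seg$t_f - tr$t_f)), hold)
})

test_that("labels alternate and counts differ by at most one in any session", {
  for (s in 1:5) {
    ses <- simulate_session(sim_config(seed = s), 1)
    zf <- bessel_lowpass(com_height(ses$markers), filter_spec(4L, 2))
    seg <- segment_transitions(zf)
    expect_true(all(seg$label[-1] != seg$label[-nrow(seg)]))
    expect_lte(abs(sum(seg$label == "SI-ST") - sum(seg$label == "ST-SI")), 1)
  }
})

test_that("the valid-repetition rule excludes transitions completing late", {
  seg <- data.frame(
    index = 1:24,
    t_i = rep(seq(0, by = 2.5, length.out = 12), each = 2) + c(0, 1.25),
    t_f = rep(seq(0, by = 2.5, length.out = 12), each = 2) + c(1, 2.25),
    label = rep(c("SI-ST", "ST-SI"), 12))
  expect_equal(count_valid_reps(seg, 30), 12L)

  # last ST-SI ending at 30.4 s does not count
  seg_late <- seg
  seg_late$t_f[24] <- 30.4
  expect_equal(count_valid_reps(seg_late, 30), 11L)

  # a trailing SI-ST without its ST-SI does not count
  seg_open <- seg[1:23, ]
  expect_equal(count_valid_reps(seg_open, 30), 11L)
})

test_that("window assignment is half-open on the interior edges", {
  expect_equal(assign_window(c(9.8, 10, 19.999, 20, 30)), c(1L, 2L, 2L, 3L, 3L))
  expect_true(is.na(assign_window(30.4)))
  expect_true(is.na(assign_window(-0.1)))
})

test_that("detected rep counts match ground truth on known-cadence sessions", {
  hits <- vapply(1:20, function(s) {
    ses <- simulate_session(sim_config(seed = s, fatigue_decay = 0), 1,
                            capacity = 1)
    res <- suppressWarnings(process_session(ses$accel, ses$markers, ses$calib))
    res$n_reps == ses$truth$n_reps
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
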