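#' Simulation configuration for synthetic 30-second chair-stand sessions
#'
#' Defines the generative model of a synthetic 30CST session: a subject
#' alternates between sitting (pitch `pitch_amplitude`, height `z_sit`) and
#' standing (pitch 0, height `z_sit + com_rise`) through raised-cosine
#' transitions. The defaults emulate the measurement protocol (250 Hz +/-16 g
#' thigh accelerometer, 100 Hz marker pair on the posterior superior iliac
#' spines, standard 0.432 m chair) and a mildly impaired cohort of 17
#' subjects completing about 12 repetitions in 30 s.
#'
#' @param seed Integer master seed; all draws derive from it.
#' @param n_subjects Cohort size (default 17).
#' @param rep_period Sit-stand-sit cycle duration in s (default 2.5, giving
#'   12 repetitions in 30 s at unit capacity and zero decay).
#' @param transition_duration Duration T of one transition in s (default
#'   0.9; must be below `rep_period / 2`).
#' @param go_delay Reaction time between the "go" signal and the first
#'   sit-to-stand, in s (default 0.5).
#' @param pitch_amplitude Seated pitch amplitude theta0 in rad (default 1.48,
#'   i.e. the thigh close to horizontal on a standard-height chair).
#' @param com_rise Vertical center-of-mass rise h in m (default 0.30,
#'   consistent with standing up from a 0.432 m chair).
#' @param z_sit Seated PSIS height in m (default 0.55).
#' @param fatigue_decay Per-repetition fractional inflation of the transition
#'   duration (default 0.05); peak powers then decay as (1+d)^-3 per rep.
#' @param stsi_multiplier Duration multiplier for stand-to-sit relative to
#'   sit-to-stand (default 1 for symmetric oracles).
#' @param accel_noise_sd Accelerometer noise sd in g (default 0.02).
#' @param marker_noise_sd Marker noise sd in m (default 0.002).
#' @param misalignment_axis Axis of the sensor-to-segment misalignment. The
#'   default lies in the plane orthogonal to the cranial-caudal axis, the
#'   component of mounting error a single static calibration can correct.
#' @param misalignment_angle Misalignment angle in rad (default 0.2).
#' @param true_lag Accelerometer-minus-marker clock offset in s (default 0.8).
#' @param capacity_sigma Between-subject log-normal sd of capacity (default
#'   0.25); transition and cycle durations scale inversely with capacity.
#' @param rpp_noise_cv,vpp_noise_cv Log-normal coefficient of variation of
#'   the observed per-transition peaks around their closed-form values, used
#'   by the transition-level cohort generator (defaults 0.10 and 0.12).
#' @param abc_gain,abc_noise ABC score: mean 80 at unit capacity, slope per
#'   capacity z-score, and noise sd (defaults 10 and 4).
#' @param mfis_gain,mfis_noise MFIS sub-score coupling (negative with
#'   capacity) and noise scale (defaults 5 and 2.5).
#' @param accel_fs,marker_fs Sampling rates in Hz (250 and 100).
#' @param session_duration Recorded duration in s (default 32; recording
#'   overruns the 30 s task so that trailing incomplete transitions exist).
#' @param task_duration Task duration in s (default 30).
#' @param chair_height_m Chair height metadata in m (default 0.432).
#' @param dynamic_accel Add the linear-acceleration term of the sensor point
#'   to the quasi-static gravity projection (default FALSE; the 2 Hz
#'   filtering is designed to suppress it and the closed-form oracles assume
#'   the quasi-static case).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_subjects = 17L,
                       rep_period = 2.5,
                       transition_duration = 0.9,
                       go_delay = 0.5,
                       pitch_amplitude = 1.48,
                       com_rise = 0.30,
                       z_sit = 0.55,
                       fatigue_decay = 0.05,
                       stsi_multiplier = 1,
                       accel_noise_sd = 0.02,
                       marker_noise_sd = 0.002,
                       misalignment_axis = c(0, 0.6, 0.8),
                       misalignment_angle = 0.2,
                       true_lag = 0.8,
                       capacity_sigma = 0.25,
                       rpp_noise_cv = 0.10,
                       vpp_noise_cv = 0.12,
                       abc_gain = 10, abc_noise = 4,
                       mfis_gain = 5, mfis_noise = 2.5,
                       accel_fs = 250, marker_fs = 100,
                       session_duration = 32,
                       task_duration = 30,
                       chair_height_m = 0.432,
                       dynamic_accel = FALSE) {
  cfg <- as.list(environment())
  if (cfg$transition_duration >= cfg$rep_period / 2) {
    stop("transition_duration must be below rep_period / 2")
  }
  if (cfg$pitch_amplitude <= 0 || cfg$pitch_amplitude > pi / 2) {
    stop("pitch_amplitude must lie in (0, pi/2]")
  }
  if (cfg$fatigue_decay < 0 || cfg$fatigue_decay >= 0.5) {
    stop("fatigue_decay must lie in [0, 0.5)")
  }
  if (cfg$rep_period <= 0 || cfg$accel_fs <= 0 || cfg$marker_fs <= 0 ||
      cfg$session_duration <= 0) {
    stop("rates and durations must be positive")
  }
  structure(cfg, class = "sim_config")
}

# deterministic per-subject substream (subject 0 = cohort-level draws)
substream_seed <- function(seed, subject) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(subject) * 7919) %%
               2147483629)
}

#' Raised-cosine transition profile
#'
#' x(t) = x0 + (x1 - x0) / 2 * (1 - cos(pi t / T)) on [0, T]: continuous in
#' value and first derivative at both endpoints. It is the kinematic template
#' of every simulated transition; the product of its first and second
#' derivatives peaks at (x1 - x0)^2 pi^3 / (8 T^3) at t = T/4, which is the
#' closed-form oracle for both peak powers.
#'
#' @param x0,x1 Start and end values.
#' @param T_s Transition duration in s.
#' @param fs Sampling rate in Hz.
#' @return A `uniform_signal` covering [0, T].
#' @export
raised_cosine_profile <- function(x0, x1, T_s, fs) {
  if (T_s <= 0) stop("transition duration must be positive")
  t <- seq(0, T_s, by = 1 / fs)
  uniform_signal(x0 + (x1 - x0) / 2 * (1 - cos(pi * t / T_s)), fs)
}

#' Closed-form peak of the derivative product of a raised cosine
#'
#' For a raised-cosine excursion of amplitude `dx` over duration `T_s`, the
#' product of the first and second time derivatives attains its positive peak
#' dx^2 pi^3 / (8 T^3) at t = T/4. With dx in rad this is the peak rotational
#' power; with dx in m it is the peak vertical power per unit mass.
#'
#' @param dx Excursion amplitude.
#' @param T_s Duration in s.
#' @return Peak value.
#' @export
raised_cosine_power_peak <- function(dx, T_s) {
  dx^2 * pi^3 / (8 * T_s^3)
}

# transition timetable of one subject: alternating SI-ST / ST-SI raised
# cosines with per-rep duration inflation, scaled by subject capacity
make_timeline <- function(cfg, capacity = 1) {
  p <- cfg$rep_period / capacity
  t_sist <- cfg$transition_duration / capacity
  t_stsi <- t_sist * cfg$stsi_multiplier
  hold <- (p - t_sist - t_stsi) / 2
  if (hold <= 0) stop("transition durations exceed the repetition period")
  rows <- list()
  t <- cfg$go_delay; k <- 0L
  repeat {
    infl <- (1 + cfg$fatigue_decay)^k
    d1 <- t_sist * infl
    d2 <- t_stsi * infl
    if (t >= cfg$session_duration) break
    rows[[length(rows) + 1L]] <- data.frame(
      label = "SI-ST", t_i = t, t_f = t + d1, duration = d1)
    rows[[length(rows) + 1L]] <- data.frame(
      label = "ST-SI", t_i = t + d1 + hold, t_f = t + d1 + hold + d2,
      duration = d2)
    t <- t + d1 + hold + d2 + hold
    k <- k + 1L
  }
  tl <- do.call(rbind, rows)
  tl <- tl[tl$t_i < cfg$session_duration, , drop = FALSE]
  tl$index <- seq_len(nrow(tl))
  tl
}

# standing fraction phi(t): 0 seated, 1 standing, raised cosine in between
eval_phi <- function(t, timeline) {
  phi <- numeric(length(t))
  for (r in seq_len(nrow(timeline))) {
    t_i <- timeline$t_i[r]; t_f <- timeline$t_f[r]
    target <- if (timeline$label[r] == "SI-ST") 1 else 0
    from <- 1 - target
    inside <- t >= t_i & t <= t_f
    phi[inside] <- from + (target - from) / 2 *
      (1 - cos(pi * (t[inside] - t_i) / (t_f - t_i)))
    phi[t > t_f] <- target
  }
  phi
}

#' Simulate one ground-truthed 30CST session
#'
#' Generates the accelerometer stream (quasi-static gravity projection of the
#' pitch trajectory, rotated by the configured misalignment, 250 Hz, noisy),
#' the marker pair (center-of-mass height split into two PSIS markers with a
#' lateral offset, 100 Hz, noisy, on a clock offset by `-true_lag` relative
#' to the accelerometer), a static calibration recording, and the ground
#' truth (per-transition boundaries, labels and closed-form peak powers, the
#' valid-repetition count, capacity, lag and misalignment).
#'
#' @param cfg A [sim_config()].
#' @param subject Subject index (selects the deterministic substream and the
#'   subject's capacity).
#' @param capacity Optional capacity override (default: drawn from the
#'   subject's substream as log-normal with sd `capacity_sigma`).
#' @return List of class `sim_session` with elements `accel`, `markers`,
#'   `calib`, `truth`.
#' @export
simulate_session <- function(cfg, subject = 1L, capacity = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  withr_seed <- substream_seed(cfg$seed, subject)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(withr_seed)
  if (is.null(capacity)) {
    capacity <- exp(stats::rnorm(1, 0, cfg$capacity_sigma))
  }
  tl <- make_timeline(cfg, capacity)
  theta0 <- cfg$pitch_amplitude
  h <- cfg$com_rise

  # markers on the session ("go") clock
  t_m <- seq(0, cfg$session_duration, by = 1 / cfg$marker_fs)
  phi_m <- eval_phi(t_m, tl)
  z <- cfg$z_sit + h * phi_m
  nm <- length(t_m)
  lat <- 0.08  # half the inter-PSIS distance, m
  left <- cbind(0, -lat, z) +
    matrix(stats::rnorm(3 * nm, 0, cfg$marker_noise_sd), nm, 3)
  right <- cbind(0, lat, z) +
    matrix(stats::rnorm(3 * nm, 0, cfg$marker_noise_sd), nm, 3)
  markers <- marker_pair(left, right, fs = cfg$marker_fs, t0 = 0,
                         vertical_axis = 3L)

  # accelerometer on its own clock: session event at t appears at t + lag
  m_rot <- rotation_from_axis_angle(cfg$misalignment_axis,
                                    cfg$misalignment_angle)
  t_a <- seq(0, cfg$session_duration, by = 1 / cfg$accel_fs)
  phi_a <- eval_phi(t_a - cfg$true_lag, tl)
  theta <- theta0 * (1 - phi_a)
  a_anat <- cbind(-cos(theta), 0, sin(theta))
  if (cfg$dynamic_accel) {
    # linear acceleration of the sensor point along the thigh, expressed in g
    zs <- uniform_signal(cfg$z_sit + h * phi_a, cfg$accel_fs)
    a_lin <- differentiate(differentiate(zs))$values / 9.80665
    a_anat[, 1] <- a_anat[, 1] - a_lin * cos(theta)
    a_anat[, 3] <- a_anat[, 3] + a_lin * sin(theta)
  }
  na <- length(t_a)
  dev <- a_anat %*% m_rot +
    matrix(stats::rnorm(3 * na, 0, cfg$accel_noise_sd), na, 3)
  colnames(dev) <- c("x", "y", "z")
  accel <- triaxial_recording(dev, fs = cfg$accel_fs, t0 = 0)

  # static calibration: quiet standing, 5 s
  nc <- round(5 * cfg$accel_fs) + 1L
  calib_dev <- matrix(rep(c(-1, 0, 0) %*% m_rot, each = nc), nc, 3) +
    matrix(stats::rnorm(3 * nc, 0, cfg$accel_noise_sd), nc, 3)
  colnames(calib_dev) <- c("x", "y", "z")
  calib <- triaxial_recording(calib_dev, fs = cfg$accel_fs, t0 = 0)

  truth_tr <- tl
  truth_tr$rp_peak <- raised_cosine_power_peak(theta0, tl$duration)
  truth_tr$vp_peak <- raised_cosine_power_peak(h, tl$duration)
  truth_tr$window <- assign_window(tl$t_f, task_end_s = cfg$task_duration)
  truth <- list(transitions = truth_tr,
                n_reps = count_valid_reps(tl, cfg$task_duration),
                lag_s = cfg$true_lag,
                capacity = capacity,
                misalignment = m_rot,
                gravity_device = as.vector(c(-1, 0, 0) %*% m_rot))
  structure(list(accel = accel, markers = markers, calib = calib,
                 truth = truth),
            class = "sim_session")
}

#' Simulate a cohort with clinical scores
#'
#' Draws per-subject capacities (log-normal), generates per-subject
#' transition tables, and couples the clinical scores to capacity so that the
#' expected correlation signs match the clinical validation structure: ABC
#' (balance confidence) increases and MFIS (fatigue impact, total and all
#' three sub-scores) decreases with capacity; #Reps increases mechanically
#' with capacity through the cycle duration.
#'
#' At the default `level = "transitions"` the observed per-transition peaks
#' are the closed-form ground-truth peaks under log-normal measurement noise
#' (`rpp_noise_cv`, `vpp_noise_cv`), which exercises every statistical stage
#' at negligible cost. `level = "signals"` additionally generates the full
#' accelerometer/marker/calibration streams per subject for end-to-end runs.
#'
#' @param cfg A [sim_config()].
#' @param level `"transitions"` (default) or `"signals"`.
#' @return List of class `sim_cohort`: `transitions` (one row per transition:
#'   `subject_id`, `label`, `index`, `t_i`, `t_f`, `rpp`, `vpp`, `window`),
#'   `summaries` (via [summarize_transitions()]), `scores`, `capacities`, and
#'   (at signal level) `sessions`.
#' @export
simulate_cohort <- function(cfg, level = c("transitions", "signals")) {
  level <- match.arg(level)
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_subjects < 2L) stop("need at least 2 subjects")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)

  set.seed(substream_seed(cfg$seed, 0L))
  zlat <- stats::rnorm(cfg$n_subjects)            # latent capacity z-score
  capacities <- exp(cfg$capacity_sigma * zlat)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  abc <- clamp(80 + cfg$abc_gain * zlat + stats::rnorm(cfg$n_subjects, 0, cfg$abc_noise),
               0, 100)
  mfis_phys <- clamp(16 - cfg$mfis_gain * zlat +
                       stats::rnorm(cfg$n_subjects, 0, cfg$mfis_noise), 0, 36)
  mfis_cog <- clamp(15 - cfg$mfis_gain * zlat +
                      stats::rnorm(cfg$n_subjects, 0, 1.2 * cfg$mfis_noise), 0, 40)
  mfis_psy <- clamp(3.5 - 0.25 * cfg$mfis_gain * zlat +
                      stats::rnorm(cfg$n_subjects, 0, 0.3 * cfg$mfis_noise), 0, 8)
  scores <- data.frame(
    subject_id = seq_len(cfg$n_subjects),
    abc = abc,
    mfis_physical = mfis_phys,
    mfis_cognitive = mfis_cog,
    mfis_psychosocial = mfis_psy,
    mfis_total = mfis_phys + mfis_cog + mfis_psy,
    age = round(clamp(stats::rnorm(cfg$n_subjects, 45, 10), 22, 70)),
    gender = sample(c("F", "M"), cfg$n_subjects, replace = TRUE,
                    prob = c(13, 4) / 17))

  tr_rows <- list()
  sessions <- if (level == "signals") vector("list", cfg$n_subjects) else NULL
  for (s in seq_len(cfg$n_subjects)) {
    set.seed(substream_seed(cfg$seed, s))
    tl <- make_timeline(cfg, capacities[s])
    ntr <- nrow(tl)
    rpp <- raised_cosine_power_peak(cfg$pitch_amplitude, tl$duration) *
      exp(stats::rnorm(ntr, 0, cfg$rpp_noise_cv))
    vpp <- raised_cosine_power_peak(cfg$com_rise, tl$duration) *
      exp(stats::rnorm(ntr, 0, cfg$vpp_noise_cv))
    tr_rows[[s]] <- data.frame(subject_id = s, label = tl$label,
                               index = tl$index, t_i = tl$t_i, t_f = tl$t_f,
                               rpp = rpp, vpp = vpp,
                               window = assign_window(tl$t_f,
                                                      task_end_s = cfg$task_duration))
    if (level == "signals") {
      sessions[[s]] <- simulate_session(cfg, s, capacity = capacities[s])
    }
  }
  transitions <- do.call(rbind, tr_rows)
  out <- list(transitions = transitions,
              summaries = summarize_transitions(transitions,
                                                task_end_s = cfg$task_duration),
              scores = scores,
              capacities = capacities,
              sessions = sessions)
  structure(out, class = "sim_cohort")
}

#' Per-subject trial summaries from a transition table
#'
#' Aggregates per-transition peaks into the trial-level capacity measures:
#' the valid-repetition count and the 95th centile of RPP and VPP per
#' transition type, over transitions completing within the task.
#'
#' @param transitions Data frame with `subject_id`, `label`, `t_i`, `t_f`,
#'   `rpp`, `vpp`.
#' @param task_end_s Task duration in s (default 30).
#' @param prob Centile (default 0.95).
#' @return Data frame with one row per subject.
#' @export
summarize_transitions <- function(transitions, task_end_s = 30, prob = 0.95) {
  out <- lapply(split(transitions, transitions$subject_id), function(d) {
    d <- d[order(d$t_i), , drop = FALSE]
    valid <- d[d$t_f <= task_end_s + 1e-9, , drop = FALSE]
    p95 <- function(lab, col) {
      v <- valid[[col]][valid$label == lab]
      if (length(v) == 0L) return(NA_real_)
      percentile95(v, prob)
    }
    data.frame(subject_id = d$subject_id[1],
               n_reps = count_valid_reps(d, task_end_s),
               rp95c_sist = p95("SI-ST", "rpp"),
               rp95c_stsi = p95("ST-SI", "rpp"),
               vp95c_sist = p95("SI-ST", "vpp"),
               vp95c_stsi = p95("ST-SI", "vpp"))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
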