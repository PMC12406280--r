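# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# |H(j 2 pi f / fc)|^2 of the delay-normalized analog 4th-order Bessel
# low-pass, from the reverse Bessel polynomial evaluated directly:
# theta_4(s) = s^4 + 10 s^3 + 45 s^2 + 105 s + 105.
bessel4_analog_gain2 <- function(f, fc) {
  s <- 1i * f / fc
  h <- 105 / (s^4 + 10 * s^3 + 45 * s^2 + 105 * s + 105)
  Mod(h)^2
}

# two-way ANOVA mean squares via aov(), combined per the two-way random
# absolute-agreement convention
icc_aov_oracle <- function(x, form = c("2,1", "2,k")) {
  form <- match.arg(form)
  n <- nrow(x); k <- ncol(x)
  long <- data.frame(y = as.vector(x),
                     target = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ target + rater, data = long))[[1]]
  msr <- tab["target", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  if (form == "2,1") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (msc - mse) / n)
  }
}

# raised-cosine derivative-product peak: dx^2 pi^3 / (8 T^3)
rc_peak_oracle <- function(dx, T_s) dx^2 * pi^3 / (8 * T_s^3)

# embed one raised-cosine descent of the pitch angle (theta0 -> 0 over T_s)
# between constant holds, as a pitch signal at fs
rc_pitch_signal <- function(theta0, T_s, fs, hold_s = 2) {
  t <- seq(0, 2 * hold_s + T_s, by = 1 / fs)
  theta <- ifelse(t < hold_s, theta0,
                  ifelse(t < hold_s + T_s,
                         theta0 / 2 * (1 + cos(pi * (t - hold_s) / T_s)),
                         0))
  uniform_signal(theta, fs)
}

# same for a height rise (0 -> h over T_s)
rc_height_signal <- function(h, T_s, fs, hold_s = 2) {
  t <- seq(0, 2 * hold_s + T_s, by = 1 / fs)
  z <- ifelse(t < hold_s, 0,
              ifelse(t < hold_s + T_s,
                     h / 2 * (1 - cos(pi * (t - hold_s) / T_s)),
                     h))
  uniform_signal(z, fs)
}

# quasi-static accelerometer channels for a pitch trace (anatomical frame)
quasi_static_accel <- function(theta_sig) {
  th <- as.vector(theta_sig$values)
  vals <- cbind(-cos(th), 0, sin(th))
  colnames(vals) <- c("x", "y", "z")
  triaxial_recording(vals, theta_sig$fs, theta_sig$t0)
}
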