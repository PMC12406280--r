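#' Thigh pitch angle from aligned accelerometer axes
#'
#' Under quasi-static conditions the low-passed cranial-caudal (a_X) and
#' anterior-posterior (a_Z) components encode the tilt of the thigh with the
#' vertical: theta = atan2(a_Z, -a_X), 0 when standing and +pi/2 when seated
#' with the thigh horizontal. Samples where both arguments vanish (free-fall
#' artifact) are flagged.
#'
#' @param aligned An aligned `triaxial_recording` whose a_X and a_Z channels
#'   have been low-passed (2 Hz Bessel).
#' @return Scalar `uniform_signal` of pitch in radians, with an attribute
#'   `flagged` listing degenerate sample indices (if any).
#' @export
pitch_angle <- function(aligned) {
  ax <- aligned$values[, 1]
  az <- aligned$values[, 3]
  degenerate <- which(abs(ax) < 1e-12 & abs(az) < 1e-12)
  theta <- atan2(az, -ax)
  out <- uniform_signal(theta, aligned$fs, aligned$t0)
  if (length(degenerate) > 0L) {
    warning(sprintf("%d pitch samples with vanishing acceleration flagged",
                    length(degenerate)))
    attr(out, "flagged") <- degenerate
  }
  out
}

#' Rotational power from the pitch angle
#'
#' The pitch angle is low-pass filtered once more (4th-order Bessel, 2.5 Hz
#' by default), then the angular velocity omega = d(theta)/dt and angular
#' acceleration alpha = d(omega)/dt are computed by numerical
#' differentiation; the rotational power is their product, RP = omega * alpha
#' (rad^2/s^3).
#'
#' @param theta Scalar `uniform_signal` of pitch in radians.
#' @param spec [filter_spec()] for the re-filtering stage (default 4th-order
#'   2.5 Hz).
#' @param bypass_filter Skip the re-filtering stage (used when the input is
#'   already band-limited, e.g. analytic test profiles).
#' @return Scalar `uniform_signal` of RP in rad^2/s^3.
#' @export
rotational_power <- function(theta, spec = filter_spec(4L, 2.5),
                             bypass_filter = FALSE) {
  th <- if (bypass_filter) theta else bessel_lowpass(theta, spec)
  omega <- differentiate(th)
  alpha <- differentiate(omega)
  uniform_signal(omega$values * alpha$values, theta$fs, theta$t0)
}

#' Vertical center-of-mass height from a marker pair
#'
#' The average vertical coordinate of the left and right PSIS markers,
#' used as an approximation of the vertical center-of-mass displacement.
#'
#' @param mp A `marker_pair`.
#' @return Scalar `uniform_signal` of height in meters.
#' @export
com_height <- function(mp) {
  k <- mp$vertical_axis
  z <- (mp$left$values[, k] + mp$right$values[, k]) / 2
  uniform_signal(z, mp$left$fs, mp$left$t0)
}

#' Body-mass-normalized vertical power from a marker pair
#'
#' The averaged PSIS vertical displacement z is low-pass filtered (4th-order
#' Bessel, 2 Hz by default) and differentiated twice to give vertical
#' velocity v and acceleration a; the body-mass-normalized vertical power is
#' p = a * v (W/kg = m^2/s^3).
#'
#' @param mp A `marker_pair` (positions in meters).
#' @param spec [filter_spec()] for the displacement filter.
#' @param bypass_filter Skip filtering (for analytic test profiles).
#' @return Scalar `uniform_signal` of vertical power in W/kg.
#' @export
vertical_power <- function(mp, spec = filter_spec(4L, 2),
                           bypass_filter = FALSE) {
  z <- com_height(mp)
  vertical_power_from_height(z, spec, bypass_filter)
}

#' Vertical power from a height signal
#'
#' Same computation as [vertical_power()] starting from an already extracted
#' height trace.
#'
#' @param z Scalar `uniform_signal` of vertical displacement in meters.
#' @inheritParams vertical_power
#' @return Scalar `uniform_signal` of vertical power in W/kg.
#' @export
vertical_power_from_height <- function(z, spec = filter_spec(4L, 2),
                                       bypass_filter = FALSE) {
  zf <- if (bypass_filter) z else bessel_lowpass(z, spec)
  v <- differentiate(zf)
  a <- differentiate(v)
  uniform_signal(a$values * v$values, z$fs, z$t0)
}

#' Positive peak of a signal over a transition
#'
#' The per-transition summary of both power branches is the positive peak
#' (RPP for rotational power, VPP for vertical power). A segment in which the
#' signal never becomes positive yields 0 with a QC flag.
#'
#' @param sig Scalar `uniform_signal`.
#' @param t_i,t_f Segment boundaries in seconds (must lie within the signal
#'   span).
#' @return Peak value, with attribute `flagged = TRUE` when the signal is
#'   never positive in the segment.
#' @export
peak_positive <- function(sig, t_i, t_f) {
  seg <- crop_signal(sig, t_i, t_f)
  m <- max(seg$values)
  if (m <= 0) {
    out <- 0
    attr(out, "flagged") <- TRUE
    return(out)
  }
  m
}
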