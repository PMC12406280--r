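#' Gravity direction from an orthostatic calibration trial
#'
#' During quiet standing the accelerometer measures only the gravity reaction,
#' so the mean acceleration over a still window gives the gravity direction in
#' the sensor frame. The window must be still (standard deviation of the
#' sample norm below `stillness_sd`) and the mean norm must be within
#' [0.9, 1.1] g.
#'
#' @param calib A `triaxial_recording` of quiet standing.
#' @param window_s Optional window length in seconds taken from the start of
#'   the recording; the whole recording is used when omitted.
#' @param stillness_sd Maximum admissible standard deviation of the sample
#'   norm, in g (default 0.05).
#' @return Unit 3-vector: gravity direction in the sensor frame.
#' @export
estimate_static_gravity <- function(calib, window_s = NULL,
                                    stillness_sd = 0.05) {
  vals <- calib$values
  if (!is.null(window_s)) {
    n <- min(nrow(vals), max(2L, round(window_s * calib$fs)))
    vals <- vals[seq_len(n), , drop = FALSE]
  }
  norms <- sqrt(rowSums(vals^2))
  if (stats::sd(norms) > stillness_sd) {
    stop(sprintf("calibration not still: norm sd %.3f g exceeds %.3f g",
                 stats::sd(norms), stillness_sd))
  }
  g <- colMeans(vals)
  gn <- sqrt(sum(g^2))
  if (gn < 0.9 || gn > 1.1) {
    stop(sprintf("mean calibration norm %.3f g outside [0.9, 1.1] g", gn))
  }
  g / gn
}

#' Rotation aligning one direction onto another (Rodrigues formula)
#'
#' Builds the proper rotation about the axis `from x to` that maps `from_vec`
#' onto `to_vec`, via the Rodrigues rotation formula
#' R = I + sin(phi) K + (1 - cos(phi)) K^2 with K the skew matrix of the unit
#' axis. Antiparallel inputs (rotation by pi, axis undefined) are handled by
#' picking any axis orthogonal to `from_vec`.
#'
#' @param from_vec,to_vec Nonzero 3-vectors (normalized internally).
#' @return List of class `alignment_rotation` with the 3 x 3 matrix `R` and
#'   `gravity_static = from_vec` (normalized).
#' @export
rodrigues_rotation <- function(from_vec, to_vec) {
  f <- from_vec / sqrt(sum(from_vec^2))
  t_ <- to_vec / sqrt(sum(to_vec^2))
  if (any(!is.finite(f)) || any(!is.finite(t_))) {
    stop("`from_vec` and `to_vec` must be nonzero finite 3-vectors")
  }
  ax <- c(f[2] * t_[3] - f[3] * t_[2],
          f[3] * t_[1] - f[1] * t_[3],
          f[1] * t_[2] - f[2] * t_[1])
  s <- sqrt(sum(ax^2))
  cth <- sum(f * t_)
  if (s < 1e-12) {
    if (cth > 0) {
      R <- diag(3)
    } else {
      # antiparallel: rotate by pi about any axis orthogonal to f
      basis <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u <- basis - sum(basis * f) * f
      u <- u / sqrt(sum(u^2))
      R <- 2 * tcrossprod(u) - diag(3)
    }
  } else {
    u <- ax / s
    K <- matrix(c(0, u[3], -u[2],
                  -u[3], 0, u[1],
                  u[2], -u[1], 0), 3, 3)
    R <- diag(3) + s * K + (1 - cth) * (K %*% K)
  }
  structure(list(R = R, gravity_static = f), class = "alignment_rotation")
}

#' Rotation matrix from an axis-angle pair
#'
#' @param axis Nonzero 3-vector (normalized internally).
#' @param angle Rotation angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_from_axis_angle <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Reference static gravity direction in the anatomical frame
#'
#' After alignment the orthostatic gravity measurement maps to (-1, 0, 0) g
#' on the cranial-caudal axis; with the anterior-posterior axis as the third
#' channel, quasi-static sitting then gives a positive third component, so
#' that the pitch angle atan2(aZ, -aX) is 0 standing and +90 degrees sitting.
#'
#' @return Unit 3-vector.
#' @export
anatomical_gravity_reference <- function() c(-1, 0, 0)

#' Rotate a recording into the anatomical frame
#'
#' Premultiplies every sample by the alignment rotation. After alignment the
#' channel order is cranial-caudal (a_X), medial-lateral (a_Y),
#' anterior-posterior (a_Z).
#'
#' @param rec A `triaxial_recording`.
#' @param rot An `alignment_rotation` from [rodrigues_rotation()].
#' @return The aligned `triaxial_recording`.
#' @export
align_recording <- function(rec, rot) {
  stopifnot(inherits(rot, "alignment_rotation"))
  vals <- rec$values %*% t(rot$R)
  colnames(vals) <- c("x", "y", "z")
  triaxial_recording(vals, rec$fs, rec$t0)
}
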