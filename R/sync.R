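#' Estimate the time lag between two streams by cross-correlation
#'
#' The accelerometer and the motion-capture system run on independent clocks;
#' the lag between them is estimated as the shift maximizing the normalized
#' cross-correlation of two derived signals sampled at the same rate (the
#' marker branch is resampled to the accelerometer rate first).
#'
#' The returned `lag_s` is the accelerometer time minus the marker time: an
#' event seen at marker time t appears in the accelerometer stream at
#' t + `lag_s`, so shifting accelerometer timestamps by `-lag_s` aligns the
#' streams.
#'
#' @param accel_derived,marker_derived Scalar `uniform_signal`s at the same
#'   sampling rate. Both are zero-meaned internally.
#' @param max_lag_s Largest admissible lag magnitude in seconds (default 5).
#' @param warn_below Warn when the correlation peak falls below this value
#'   (default 0.5), indicating that the streams may not share content.
#' @param edge_trim_s Seconds discarded from both ends of both signals before
#'   correlating (default 0). Zero-phase filtering distorts the first and
#'   last seconds of a recording; trimming keeps those samples out of the
#'   correlation, which matters when a recording boundary cuts through a
#'   transition.
#' @return A list of class `sync_result` with `lag_s`, `peak_xcorr` and
#'   `lag_samples`.
#' @export
estimate_lag <- function(accel_derived, marker_derived, max_lag_s = 5,
                         warn_below = 0.5, edge_trim_s = 0) {
  if (abs(accel_derived$fs - marker_derived$fs) > 1e-9) {
    stop("both signals must be at the same sampling rate (resample first)")
  }
  fs <- accel_derived$fs
  a <- as.vector(accel_derived$values)
  b <- as.vector(marker_derived$values)
  nt <- as.integer(round(edge_trim_s * fs))
  if (nt > 0) {
    if (min(length(a), length(b)) <= 2L * nt + 2L) {
      stop("signals too short for the requested edge trim")
    }
    a <- a[(nt + 1):(length(a) - nt)]
    b <- b[(nt + 1):(length(b) - nt)]
  }
  a <- a - mean(a)
  b <- b - mean(b)
  L <- as.integer(round(max_lag_s * fs))
  nmin <- min(length(a), length(b))
  if (nmin < 2L * L + 8L) {
    stop(sprintf("signals too short (%d, %d samples) for max lag %g s",
                 length(a), length(b), max_lag_s))
  }
  # fixed central window of `a` against sliding windows of `b`, so that every
  # lag uses the same number of products and the same `a` energy; per-lag
  # normalization by the energy of the `b` window it actually overlaps
  # (a pure shift of identical content then peaks at exactly 1)
  ia <- (L + 1):(nmin - L)          # a[i] pairs with b[i - l], all in range
  aw <- a[ia]
  ea <- sum(aw^2)
  cb2 <- c(0, cumsum(b^2))
  lags <- (-L):L
  r <- vapply(lags, function(l) {
    jb <- ia - l
    eb <- cb2[jb[length(jb)] + 1L] - cb2[jb[1]]
    if (ea == 0 || eb == 0) return(0)
    sum(aw * b[jb]) / sqrt(ea * eb)
  }, numeric(1))
  if (all(r == 0)) stop("zero-variance input to estimate_lag")
  k <- which.max(r)
  if (r[k] < warn_below) {
    warning(sprintf("weak synchronization peak (%.2f): streams may be unrelated",
                    r[k]))
  }
  structure(list(lag_s = lags[k] / fs, peak_xcorr = r[k],
                 lag_samples = lags[k]),
            class = "sync_result")
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("<sync_result> lag = %.4f s (%d samples), peak xcorr = %.3f\n",
              x$lag_s, x$lag_samples, x$peak_xcorr))
  invisible(x)
}
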