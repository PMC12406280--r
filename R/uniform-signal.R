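#' Uniformly sampled signal
#'
#' The backbone container of the package: a scalar or fixed-width vector time
#' series sampled at a constant rate. Scalar signals are stored as numeric
#' vectors, multichannel signals as numeric matrices (samples in rows,
#' channels in columns).
#'
#' @param values Numeric vector (scalar signal) or matrix (one column per
#'   channel, one row per sample).
#' @param fs Sampling frequency in Hz; must be positive.
#' @param t0 Time of the first sample in seconds (default 0). All times in the
#'   package are seconds from the "go" signal of the task.
#' @return An object of class `uniform_signal`.
#' @examples
#' s <- uniform_signal(sin(2 * pi * seq(0, 1, by = 0.01)), fs = 100)
#' signal_time(s)[1:3]
#' @export
uniform_signal <- function(values, fs, t0 = 0) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)")
  }
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be numeric")
  structure(list(values = values, fs = fs, t0 = t0),
            class = "uniform_signal")
}

#' @export
print.uniform_signal <- function(x, ...) {
  nc <- n_channels(x)
  cat(sprintf("<uniform_signal> %d samples x %d channel%s @ %g Hz, t0 = %g s\n",
              n_samples(x), nc, if (nc > 1) "s" else "", x$fs, x$t0))
  invisible(x)
}

#' Number of samples in a signal
#' @param sig A `uniform_signal`.
#' @return Integer sample count.
#' @export
n_samples <- function(sig) {
  if (is.matrix(sig$values)) nrow(sig$values) else length(sig$values)
}

#' Number of channels in a signal
#' @param sig A `uniform_signal`.
#' @return Integer channel count (1 for scalar signals).
#' @export
n_channels <- function(sig) {
  if (is.matrix(sig$values)) ncol(sig$values) else 1L
}

#' Sample times of a signal
#' @param sig A `uniform_signal`.
#' @return Numeric vector of sample times in seconds.
#' @export
signal_time <- function(sig) {
  sig$t0 + (seq_len(n_samples(sig)) - 1L) / sig$fs
}

#' Crop a signal to a time window
#'
#' Keeps samples with time in `[t_from, t_to]` (inclusive at both ends; the
#' window is closed because segment boundaries are themselves samples).
#'
#' @param sig A `uniform_signal`.
#' @param t_from,t_to Window boundaries in seconds.
#' @return A `uniform_signal` covering the window.
#' @export
crop_signal <- function(sig, t_from, t_to) {
  tt <- signal_time(sig)
  keep <- which(tt >= t_from - 1e-9 & tt <= t_to + 1e-9)
  if (length(keep) == 0L) {
    stop(sprintf("window [%g, %g] s lies outside the signal span [%g, %g] s",
                 t_from, t_to, tt[1], tt[length(tt)]))
  }
  vals <- if (is.matrix(sig$values)) sig$values[keep, , drop = FALSE] else sig$values[keep]
  uniform_signal(vals, sig$fs, t0 = tt[keep[1]])
}

#' Numerical differentiation of a uniform signal
#'
#' Second-order central differences in the interior and second-order one-sided
#' differences at the endpoints, so the output has the same length and sample
#' grid as the input.
#'
#' @param sig A `uniform_signal` with at least 3 samples.
#' @return A `uniform_signal` holding the derivative (per second).
#' @export
differentiate <- function(sig) {
  n <- n_samples(sig)
  if (n < 3L) stop("differentiation requires at least 3 samples")
  d1 <- function(x) {
    fs <- sig$fs
    c((-3 * x[1] + 4 * x[2] - x[3]) * fs / 2,
      (x[3:n] - x[1:(n - 2)]) * fs / 2,
      (3 * x[n] - 4 * x[n - 1] + x[n - 2]) * fs / 2)
  }
  vals <- if (is.matrix(sig$values)) apply(sig$values, 2L, d1) else d1(sig$values)
  uniform_signal(vals, sig$fs, sig$t0)
}

#' Fraction of signal energy retained after filtering
#'
#' The design rule for the low-pass cut-offs is that filtering must retain at
#' least 95 percent of the signal's energy. Energy is the mean-removed sum of
#' squares; a zero-variance input is a degenerate case that returns 1 with a
#' warning.
#'
#' @param raw,filtered `uniform_signal`s of equal length (scalar channels).
#' @param warn_below Emit a warning when retention falls below this fraction
#'   (default 0.95); set to 0 to silence.
#' @return Retention fraction (filtered energy over raw energy).
#' @export
energy_retention <- function(raw, filtered, warn_below = 0.95) {
  x <- as.vector(raw$values)
  y <- as.vector(filtered$values)
  if (length(x) != length(y)) stop("`raw` and `filtered` must have equal length")
  ex <- sum((x - mean(x))^2)
  if (ex == 0) {
    warning("zero-variance raw signal: energy retention undefined, returning 1")
    return(1)
  }
  r <- sum((y - mean(y))^2) / ex
  if (r < warn_below) {
    warning(sprintf("energy retention %.3f below %.2f: cut-off may be too aggressive",
                    r, warn_below))
  }
  r
}

#' Resample a signal to a new rate
#'
#' Polyphase FIR resampling (via the `signal` package) at the rational rate
#' ratio, with reflective padding so that edge transients of the
#' anti-aliasing filter do not contaminate the output. Linear interpolation is
#' available as a fallback method.
#'
#' @param sig A `uniform_signal`.
#' @param fs_target Target rate in Hz.
#' @param method `"fir"` (polyphase, default) or `"linear"`.
#' @return A `uniform_signal` at `fs_target` starting at the same `t0`.
#' @export
resample_signal <- function(sig, fs_target, method = c("fir", "linear")) {
  method <- match.arg(method)
  if (!is.numeric(fs_target) || length(fs_target) != 1L || fs_target <= 0) {
    stop("`fs_target` must be a single positive rate in Hz")
  }
  if (abs(fs_target - sig$fs) < 1e-12) return(sig)
  n <- n_samples(sig)
  t_new <- seq(sig$t0, by = 1 / fs_target,
               length.out = floor((n - 1) * fs_target / sig$fs) + 1L)
  res1 <- function(x) {
    if (method == "linear") {
      return(stats::approx(signal_time(sig), x, xout = t_new)$y)
    }
    pq <- rational_ratio(fs_target, sig$fs)
    p <- pq[1]; q <- pq[2]
    # reflective padding, a whole multiple of q so the output offset is exact
    np <- q * ceiling(min(n - 1L, max(50L, round(0.5 * sig$fs))) / q)
    xp <- c(2 * x[1] - rev(x[2:(np + 1)]), x,
            2 * x[n] - rev(x[(n - np):(n - 1)]))
    y <- signal::resample(xp, p, q)
    off <- np * p / q
    y[(off + 1):(off + length(t_new))]
  }
  vals <- if (is.matrix(sig$values)) apply(sig$values, 2L, res1) else res1(sig$values)
  uniform_signal(vals, fs_target, sig$t0)
}

# smallest p/q with p/q = a/b exactly (rates are stored as doubles; work on a
# common fine grid of 1e-6 Hz to absorb representation error)
rational_ratio <- function(a, b) {
  ia <- round(a * 1e6); ib <- round(b * 1e6)
  g <- gcd_int(ia, ib)
  c(ia / g, ib / g)
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}
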