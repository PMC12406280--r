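#' Segment postural transitions from the vertical displacement
#'
#' Alternating local maxima (standing) and minima (sitting) of the filtered
#' vertical displacement define the transition boundaries: each segment runs
#' from one extremum to the next, labeled SI-ST when the height rises and
#' ST-SI when it falls. Small oscillations are suppressed by a minimum
#' prominence (fraction of the trial's height range) and a minimum temporal
#' separation between retained extrema.
#'
#' @param z Scalar `uniform_signal` of vertical displacement, already
#'   low-passed at 2 Hz.
#' @param min_prominence Minimum extremum-to-extremum amplitude as a fraction
#'   of the overall z range (default 0.25).
#' @param min_separation_s Minimum time between retained extrema in seconds
#'   (default 0.5; maximum plausible cadence is about one transition per
#'   second).
#' @return Data frame with one row per transition: `index`, `t_i`, `t_f`,
#'   `label` (`"SI-ST"` or `"ST-SI"`). Zero rows (with a warning) when fewer
#'   than two qualifying extrema exist.
#' @export
segment_transitions <- function(z, min_prominence = 0.25,
                                min_separation_s = 0.5) {
  x <- as.vector(z$values)
  tt <- signal_time(z)
  empty <- data.frame(index = integer(), t_i = numeric(), t_f = numeric(),
                      label = character(), stringsAsFactors = FALSE)
  rng <- diff(range(x))
  if (rng <= 0) {
    warning("flat displacement signal: no transitions found")
    return(empty)
  }
  ext <- local_extrema(x)
  ext <- enforce_alternation(ext, x)
  ext <- prune_extrema(ext, x, thresh = min_prominence * rng,
                       min_sep = round(min_separation_s * z$fs))
  ext <- add_endpoint_extrema(ext, x, thresh = min_prominence * rng)
  if (length(ext$idx) < 2L) {
    warning("fewer than two qualifying extrema: no transitions found")
    return(empty)
  }
  n <- length(ext$idx) - 1L
  lab <- ifelse(ext$is_max[-1], "SI-ST", "ST-SI")  # rising ends at a maximum
  data.frame(index = seq_len(n),
             t_i = tt[ext$idx[-length(ext$idx)]],
             t_f = tt[ext$idx[-1]],
             label = lab,
             stringsAsFactors = FALSE)
}

# indices and type of all strict local extrema (plateaus take the midpoint)
local_extrema <- function(x) {
  n <- length(x)
  idx <- integer(); is_max <- logical()
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) {
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1L
      if (j == n || x[j + 1] < x[i]) {
        idx <- c(idx, (i + j) %/% 2L); is_max <- c(is_max, TRUE)
      }
      i <- j + 1L
    } else if (x[i] < x[i - 1] && x[i] <= x[i + 1]) {
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1L
      if (j == n || x[j + 1] > x[i]) {
        idx <- c(idx, (i + j) %/% 2L); is_max <- c(is_max, FALSE)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  list(idx = idx, is_max = is_max)
}

# collapse runs of same-type extrema to the most extreme one
enforce_alternation <- function(ext, x) {
  if (length(ext$idx) <= 1L) return(ext)
  keep_idx <- integer(); keep_max <- logical()
  cur <- ext$idx[1]; cur_max <- ext$is_max[1]
  for (k in seq_along(ext$idx)[-1]) {
    if (ext$is_max[k] == cur_max) {
      better <- if (cur_max) x[ext$idx[k]] > x[cur] else x[ext$idx[k]] < x[cur]
      if (better) cur <- ext$idx[k]
    } else {
      keep_idx <- c(keep_idx, cur); keep_max <- c(keep_max, cur_max)
      cur <- ext$idx[k]; cur_max <- ext$is_max[k]
    }
  }
  keep_idx <- c(keep_idx, cur); keep_max <- c(keep_max, cur_max)
  list(idx = keep_idx, is_max = keep_max)
}

# a trial that starts seated (or ends mid-posture) has its first/last
# boundary at a signal endpoint rather than at an interior extremum; add the
# endpoint as a pseudo-extremum when the excursion to its neighbor qualifies
add_endpoint_extrema <- function(ext, x, thresh) {
  n <- length(x)
  if (length(ext$idx) == 0L) return(ext)
  if (ext$idx[1] > 1L && abs(x[ext$idx[1]] - x[1]) >= thresh) {
    ext$idx <- c(1L, ext$idx)
    ext$is_max <- c(!ext$is_max[1], ext$is_max)
  }
  last <- length(ext$idx)
  if (ext$idx[last] < n && abs(x[n] - x[ext$idx[last]]) >= thresh) {
    ext$idx <- c(ext$idx, n)
    ext$is_max <- c(ext$is_max, !ext$is_max[last])
  }
  ext
}

# iteratively remove the weakest adjacent pair violating amplitude or
# separation, re-enforcing alternation after each removal
prune_extrema <- function(ext, x, thresh, min_sep) {
  repeat {
    if (length(ext$idx) < 2L) return(ext)
    amp <- abs(diff(x[ext$idx]))
    sep <- diff(ext$idx)
    bad <- which(amp < thresh | sep < min_sep)
    if (length(bad) == 0L) return(ext)
    # drop the pair with the smallest amplitude among violators
    k <- bad[which.min(amp[bad])]
    drop <- c(k, k + 1L)
    ext <- list(idx = ext$idx[-drop], is_max = ext$is_max[-drop])
    ext <- enforce_alternation(ext, x)
  }
}

#' Count valid 30CST repetitions
#'
#' A valid repetition is a sit-to-stand (SI-ST) immediately followed by a
#' completed stand-to-sit (ST-SI) that ends no later than the end of the
#' task; transitions still in progress at the end of the 30-second period do
#' not count.
#'
#' @param segments Data frame from [segment_transitions()] (time-ordered).
#' @param task_end_s End of the task in seconds (default 30).
#' @return Integer repetition count.
#' @export
count_valid_reps <- function(segments, task_end_s = 30) {
  if (nrow(segments) == 0L) return(0L)
  n <- 0L
  for (k in seq_len(nrow(segments) - 1L)) {
    if (segments$label[k] == "SI-ST" &&
        segments$t_i[k] >= 0 &&
        segments$label[k + 1L] == "ST-SI" &&
        segments$t_f[k + 1L] <= task_end_s + 1e-9) {
      n <- n + 1L
    }
  }
  n
}

#' Assign transitions to 10-second task windows
#'
#' Windows are half-open: [0, 10), [10, 20), [20, 30]; assignment uses the
#' transition end time. Transitions ending outside the task get `NA`.
#'
#' @param t_f Transition end times in seconds.
#' @param edges Interior window edges (default `c(10, 20)`).
#' @param task_end_s End of the task (default 30).
#' @return Integer window index (1-3) or `NA`.
#' @export
assign_window <- function(t_f, edges = c(10, 20), task_end_s = 30) {
  w <- findInterval(t_f, edges) + 1L
  w[t_f < 0 | t_f > task_end_s + 1e-9] <- NA_integer_
  w
}
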