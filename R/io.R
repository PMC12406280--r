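#' Read a triaxial accelerometer recording
#'
#' Parses a delimited text file with one timestamp column and three axis
#' columns into a `triaxial_recording` (a 3-channel [uniform_signal()] in
#' units of g). Timestamps must be strictly increasing and uniform; jitter
#' above 0.5 percent of the nominal sample period is rejected.
#'
#' @param path Path to a CSV/TSV file.
#' @param column_map Named list: `time` (timestamp column name), `axes`
#'   (character vector of the three axis column names, device order), and
#'   `units` (`"g"`, `"mg"`, or `"mm_s2"`). See [read_column_map()].
#' @param fs Optional nominal sampling rate in Hz; derived from timestamps
#'   when omitted.
#' @param sep Field separator (default `","`).
#' @return A `triaxial_recording`: a `uniform_signal` with 3 channels, values
#'   in g, plus sampling metadata.
#' @export
read_accel <- function(path, column_map = default_accel_map(), fs = NULL,
                       sep = ",") {
  df <- read_delim_checked(path, sep)
  need <- c(column_map$time, column_map$axes)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("missing columns in %s: %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  tt <- df[[column_map$time]]
  check_timestamps(tt, path)
  fs_est <- 1 / stats::median(diff(tt))
  if (is.null(fs)) fs <- round(fs_est, 6)
  jitter <- max(abs(diff(tt) - 1 / fs)) * fs
  if (jitter > 0.005) {
    stop(sprintf("timestamp jitter %.2f%% exceeds 0.5%% of the sample period in %s",
                 100 * jitter, path))
  }
  vals <- as.matrix(df[, column_map$axes, drop = FALSE])
  units <- if (is.null(column_map$units)) "g" else column_map$units
  vals <- switch(units,
    g = vals,
    mg = vals / 1000,
    mm_s2 = vals / (9.80665 * 1000),
    m_s2 = vals / 9.80665,
    stop(sprintf("unknown accelerometer units '%s'", units)))
  colnames(vals) <- c("x", "y", "z")
  triaxial_recording(vals, fs = fs, t0 = tt[1])
}

#' Construct a triaxial recording
#'
#' @param values n x 3 numeric matrix in g (device axes).
#' @param fs Sampling rate in Hz (nominally 250).
#' @param t0 Start time in seconds.
#' @return Object of classes `triaxial_recording` and `uniform_signal`.
#' @export
triaxial_recording <- function(values, fs, t0 = 0) {
  if (!is.matrix(values) || ncol(values) != 3L) {
    stop("a triaxial recording needs an n x 3 value matrix")
  }
  out <- uniform_signal(values, fs, t0)
  class(out) <- c("triaxial_recording", class(out))
  out
}

#' Read a PSIS marker pair
#'
#' Parses six 3-D position columns (left and right posterior superior iliac
#' spine markers) into a `marker_pair`, converting to meters. Dropout runs
#' (NaN) up to `max_gap` samples are linearly interpolated; longer gaps are an
#' error.
#'
#' @param path Path to a CSV/TSV file.
#' @param column_map Named list with `time`, `left` and `right` (each a
#'   3-vector of column names, component order x/y/z), `units` (`"m"` or
#'   `"mm"`), and `vertical_axis` (1, 2 or 3; which component is vertical).
#' @param fs Optional nominal sampling rate (derived when omitted).
#' @param max_gap Longest interpolatable dropout, in samples (default 10,
#'   i.e. 0.1 s at 100 Hz).
#' @param sep Field separator.
#' @return A `marker_pair`: list with `left` and `right` 3-channel
#'   [uniform_signal()]s in meters and the vertical axis index.
#' @export
read_markers <- function(path, column_map = default_marker_map(), fs = NULL,
                         max_gap = 10L, sep = ",") {
  df <- read_delim_checked(path, sep)
  need <- c(column_map$time, column_map$left, column_map$right)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("missing columns in %s: %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  tt <- df[[column_map$time]]
  check_timestamps(tt, path)
  if (is.null(fs)) fs <- round(1 / stats::median(diff(tt)), 6)
  units <- if (is.null(column_map$units)) "m" else column_map$units
  scale <- switch(units, m = 1, mm = 1 / 1000,
                  stop(sprintf("unknown marker units '%s'", units)))
  get_mat <- function(cols) {
    m <- as.matrix(df[, cols, drop = FALSE]) * scale
    apply(m, 2L, fill_gaps, max_gap = max_gap, path = path)
  }
  marker_pair(left = get_mat(column_map$left),
              right = get_mat(column_map$right),
              fs = fs, t0 = tt[1],
              vertical_axis = column_map$vertical_axis %||% 3L)
}

#' Construct a marker pair
#'
#' @param left,right n x 3 position matrices in meters.
#' @param fs Sampling rate in Hz (nominally 100).
#' @param t0 Start time in seconds.
#' @param vertical_axis Index (1-3) of the vertical component.
#' @return Object of class `marker_pair`.
#' @export
marker_pair <- function(left, right, fs, t0 = 0, vertical_axis = 3L) {
  if (!identical(dim(left), dim(right))) {
    stop("left and right markers must have equal dimensions")
  }
  structure(list(left = uniform_signal(left, fs, t0),
                 right = uniform_signal(right, fs, t0),
                 vertical_axis = as.integer(vertical_axis)),
            class = "marker_pair")
}

#' @export
print.marker_pair <- function(x, ...) {
  cat(sprintf("<marker_pair> %d samples @ %g Hz, vertical axis %d\n",
              n_samples(x$left), x$left$fs, x$vertical_axis))
  invisible(x)
}

#' Write a triaxial recording to CSV
#'
#' Inverse of [read_accel()] for the default column map; full double
#' precision so that a write/read round trip reproduces values to 1e-9.
#'
#' @param rec A `triaxial_recording`.
#' @param path Output path.
#' @export
write_accel <- function(rec, path) {
  df <- data.frame(time = signal_time(rec),
                   ax = rec$values[, 1], ay = rec$values[, 2],
                   az = rec$values[, 3])
  write_full_precision(df, path)
}

#' Write a marker pair to CSV
#'
#' Inverse of [read_markers()] for the default column map.
#'
#' @param mp A `marker_pair`.
#' @param path Output path.
#' @export
write_markers <- function(mp, path) {
  df <- data.frame(time = signal_time(mp$left),
                   lx = mp$left$values[, 1], ly = mp$left$values[, 2],
                   lz = mp$left$values[, 3],
                   rx = mp$right$values[, 1], ry = mp$right$values[, 2],
                   rz = mp$right$values[, 3])
  write_full_precision(df, path)
}

#' Default accelerometer column map
#' @return Named list usable as `column_map` in [read_accel()].
#' @export
default_accel_map <- function() {
  list(time = "time", axes = c("ax", "ay", "az"), units = "g")
}

#' Default marker column map
#' @return Named list usable as `column_map` in [read_markers()].
#' @export
default_marker_map <- function() {
  list(time = "time", left = c("lx", "ly", "lz"),
       right = c("rx", "ry", "rz"), units = "m", vertical_axis = 3L)
}

#' Read a column map from YAML
#'
#' @param path YAML file naming the timestamp/axis columns, units, and (for
#'   markers) the vertical axis.
#' @return Named list.
#' @export
read_column_map <- function(path) {
  yaml::read_yaml(path)
}

# ---- internal helpers -------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

read_delim_checked <- function(path, sep) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop(sprintf("empty file: %s", path))
  df
}

check_timestamps <- function(tt, path) {
  bad <- which(diff(tt) <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("non-monotone or duplicated timestamp at row %d of %s",
                 bad[1] + 1L, path))
  }
}

fill_gaps <- function(x, max_gap, path) {
  isna <- !is.finite(x)
  if (!any(isna)) return(x)
  r <- rle(isna)
  runs <- r$lengths[r$values]
  if (any(runs > max_gap)) {
    stop(sprintf("marker dropout of %d samples exceeds max gap %d in %s",
                 max(runs), max_gap, path))
  }
  if (isna[1] || isna[length(x)]) {
    stop(sprintf("marker dropout at the recording boundary in %s", path))
  }
  idx <- seq_along(x)
  stats::approx(idx[!isna], x[!isna], xout = idx)$y
}

write_full_precision <- function(df, path) {
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
}
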