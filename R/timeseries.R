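#' Uniformly sampled scalar time series
#'
#' Lightweight container used throughout the package for per-frame signal
#' traces: colour-channel means, nostril temperatures, recovered pulse
#' waveforms. Values are stored with their sampling rate and start time so
#' peak indices convert to absolute seconds.
#'
#' @param values numeric vector, finite except for `NA` gap markers.
#' @param fs sampling rate in Hz, > 0.
#' @param t0 time of the first sample in seconds (default 0).
#' @param label channel name, e.g. `"green"` or `"nostril"`.
#' @return An object of class `vital_ts` with fields `values`, `fs`, `t0`,
#'   `label`.
#' @examples
#' x <- time_series(sin(2 * pi * 1.2 * seq(0, 15, by = 1 / 25)), fs = 25)
#' ts_times(x)[1:3]
#' @export
time_series <- function(values, fs, t0 = 0, label = "") {
  stopifnot(is.numeric(values), length(values) >= 1)
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (any(!is.finite(values) & !is.na(values)))
    stop("`values` must be finite or NA", call. = FALSE)
  structure(list(values = as.numeric(values), fs = fs, t0 = t0,
                 label = label),
            class = "vital_ts")
}

#' @export
print.vital_ts <- function(x, ...) {
  cat(sprintf("<vital_ts '%s': %d samples @ %g Hz, t0 = %g s>\n",
              x$label, length(x$values), x$fs, x$t0))
  invisible(x)
}

#' @export
length.vital_ts <- function(x) length(x$values)

#' Sample times of a time series
#' @param x a `vital_ts`.
#' @return numeric vector of times in seconds.
#' @export
ts_times <- function(x) x$t0 + (seq_along(x$values) - 1) / x$fs

#' Extract a time slice of a series
#' @param x a `vital_ts`.
#' @param start,end window bounds in seconds (half-open `[start, end)`).
#' @return a `vital_ts` covering the requested span.
#' @export
ts_slice <- function(x, start, end) {
  tt <- ts_times(x)
  keep <- tt >= start - 1e-9 & tt < end - 1e-9
  if (!any(keep)) stop("empty slice", call. = FALSE)
  time_series(x$values[keep], x$fs, t0 = tt[which(keep)[1]], label = x$label)
}

as_ts <- function(x, fs, label = "") {
  if (inherits(x, "vital_ts")) x else time_series(x, fs = fs, label = label)
}

#' Zero-mean, unit-variance normalization
#'
#' Standardizes a channel trace to zero mean and unit variance before blind
#' source separation, so that channel gains do not dominate the mixing
#' estimate. Uses the sample standard deviation.
#'
#' @param x a `vital_ts` with non-constant, gap-free values.
#' @return a `vital_ts` with mean 0 and variance 1.
#' @export
ts_normalize <- function(x) {
  v <- x$values
  if (anyNA(v)) stop("cannot normalize a series with gaps", call. = FALSE)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop("constant series: standard deviation is zero", call. = FALSE)
  time_series((v - mean(v)) / s, x$fs, x$t0, x$label)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Third-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), so filtering does not shift peak times. The input
#' must be long enough for the filter transient to die out: at least
#' `guard_periods` periods of the lower band edge.
#'
#' @param x a `vital_ts`.
#' @param low_hz,high_hz band edges in Hz; `fs > 2 * high_hz` required.
#' @param order filter order (default 3).
#' @param guard_periods minimum input length expressed in periods of
#'   `low_hz` (default `3 * order`). The respiratory chain relaxes this to 2
#'   so that 15-s windows remain admissible at a 0.15 Hz edge.
#' @return filtered `vital_ts`, same length and sampling rate.
#' @export
bandpass <- function(x, low_hz, high_hz, order = 3,
                     guard_periods = 3 * order) {
  stopifnot(low_hz > 0, high_hz > low_hz)
  if (x$fs <= 2 * high_hz)
    stop("sampling rate must exceed twice the upper band edge", call. = FALSE)
  if (anyNA(x$values)) stop("cannot filter a series with gaps", call. = FALSE)
  min_n <- ceiling(guard_periods * x$fs / low_hz)
  if (length(x$values) < min_n)
    stop(sprintf("input too short for band edge %g Hz: need >= %d samples, got %d",
                 low_hz, min_n, length(x$values)), call. = FALSE)
  bf <- signal::butter(order, c(low_hz, high_hz) / (x$fs / 2), type = "pass")
  # remove the DC level first: the band-pass kills it anyway, and a large
  # offset otherwise leaks a step transient into the filter edges
  time_series(signal::filtfilt(bf, x$values - mean(x$values)),
              x$fs, x$t0, x$label)
}

#' Peak detection with prominence and refractory constraints
#'
#' Finds local maxima whose topographic prominence is at least
#' `min_prominence_sd` signal standard deviations, then enforces a minimum
#' separation by keeping the higher peak of any conflicting pair. Defaults
#' suit band-limited cardiac (0.5 s floor, 120 bpm ceiling) and respiratory
#' (2 s floor, 30 brpm ceiling) waveforms.
#'
#' @param x a `vital_ts`.
#' @param min_separation_s refractory period between accepted peaks, seconds.
#' @param min_prominence_sd prominence threshold in units of `sd(x)`.
#' @return numeric vector of peak times (seconds). If fewer than two peaks
#'   survive, the vector carries `attr(, "insufficient") = TRUE`.
#' @export
detect_peaks <- function(x, min_separation_s, min_prominence_sd = 0.3) {
  v <- x$values
  n <- length(v)
  idx <- which(diff(sign(diff(v))) < 0) + 1L  # strict rise, fall or plateau end
  if (length(idx) > 0) {
    prom <- vapply(idx, function(i) peak_prominence(v, i), numeric(1))
    idx <- idx[prom >= min_prominence_sd * stats::sd(v)]
  }
  # greedy refractory pruning: highest peaks win
  if (length(idx) > 1) {
    ord <- idx[order(v[idx], decreasing = TRUE)]
    min_gap <- min_separation_s * x$fs
    kept <- integer(0)
    for (i in ord) {
      if (all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
    }
    idx <- sort(kept)
  }
  times <- x$t0 + (idx - 1) / x$fs
  if (length(times) < 2) attr(times, "insufficient") <- TRUE
  times
}

# Topographic prominence of a local maximum: height above the higher of the
# two lowest saddles separating it from taller terrain (or the record edge).
peak_prominence <- function(v, i) {
  h <- v[i]
  left <- if (i > 1) v[seq_len(i - 1)] else numeric(0)
  right <- if (i < length(v)) v[seq.int(i + 1, length(v))] else numeric(0)
  base_left <- if (length(left) == 0) min(v) else {
    taller <- which(left >= h)
    if (length(taller) == 0) min(left)
    else min(left[seq.int(max(taller), length(left))])
  }
  base_right <- if (length(right) == 0) min(v) else {
    taller <- which(right >= h)
    if (length(taller) == 0) min(right)
    else min(right[seq_len(min(taller))])
  }
  h - max(base_left, base_right)
}

#' Rate from peak times
#'
#' Converts successive peak intervals to a per-minute rate:
#' `60 / mean(diff(peak_times))`. This is the conversion used for both
#' heart rate (beats/min) and respiration rate (breaths/min).
#'
#' @param peak_times strictly increasing numeric vector of peak times (s).
#' @return rate per minute.
#' @export
rate_from_peaks <- function(peak_times) {
  if (length(peak_times) < 2)
    stop("need at least two peaks to form an interval", call. = FALSE)
  if (any(diff(peak_times) <= 0))
    stop("peak times must be strictly increasing", call. = FALSE)
  60 / mean(diff(peak_times))
}

#' Fraction of spectral power inside a band
#'
#' Periodogram power in `[low_hz, high_hz]` divided by total non-DC power.
#' Used by the rBVP component-selection fallback to decide whether a source
#' is pulse-like.
#'
#' @param x a `vital_ts`.
#' @param low_hz,high_hz band edges in Hz.
#' @return fraction in `[0, 1]`.
#' @export
band_power_fraction <- function(x, low_hz, high_hz) {
  v <- x$values - mean(x$values)
  n <- length(v)
  p <- Mod(stats::fft(v))^2
  freqs <- (seq_len(n) - 1) * x$fs / n
  half <- freqs <= x$fs / 2 & freqs > 0
  tot <- sum(p[half])
  if (tot == 0) return(0)
  sum(p[half & freqs >= low_hz & freqs <= high_hz]) / tot
}

#' Fill short gaps in a series, splitting at long ones
#'
#' `NA` runs lasting at most `max_gap_s` are filled by linear interpolation;
#' longer runs split the series, and each contiguous piece is returned for
#' separate quality assessment. Leading/trailing `NA`s are trimmed.
#'
#' @param x a `vital_ts` possibly containing `NA` gap markers.
#' @param max_gap_s longest gap bridged by interpolation (default 0.5 s).
#' @return list of gap-free `vital_ts` segments (possibly empty).
#' @export
fill_gaps <- function(x, max_gap_s = 0.5) {
  v <- x$values
  if (all(is.na(v))) return(list())
  max_run <- floor(max_gap_s * x$fs + 1e-9)
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # interpolate interior NA runs short enough to bridge
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    if (starts[k] == 1L || ends[k] == length(v)) next
    if (r$lengths[k] <= max_run) {
      i0 <- starts[k] - 1L; i1 <- ends[k] + 1L
      v[starts[k]:ends[k]] <-
        stats::approx(c(i0, i1), v[c(i0, i1)], xout = starts[k]:ends[k])$y
    }
  }
  # split at the remaining NA runs
  ok <- !is.na(v)
  r2 <- rle(ok)
  e2 <- cumsum(r2$lengths)
  s2 <- e2 - r2$lengths + 1L
  segs <- list()
  for (k in seq_along(r2$lengths)) {
    if (!r2$values[k]) next
    segs[[length(segs) + 1L]] <-
      time_series(v[s2[k]:e2[k]], x$fs,
                  t0 = x$t0 + (s2[k] - 1L) / x$fs, label = x$label)
  }
  segs
}
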