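#' Template-correlation signal quality index
#'
#' Ensemble-averaging quality measure for quasi-periodic waveforms. The
#' template window length is the median interval between successive peaks,
#' rounded to the nearest odd number of samples so each pulse can be
#' centred exactly on its peak. Every complete pulse (windows truncated by
#' the segment edge are dropped) is extracted, the sample-wise mean of the
#' pulses forms the template, and the SQI is the mean Pearson correlation
#' between the individual pulses and that template. Identical periodic
#' pulses give exactly 1; incoherent noise gives values near 0.
#'
#' Zero-variance pulses, for which Pearson correlation is undefined, are
#' excluded; if fewer than two informative pulses remain the SQI is 0.
#'
#' @param x a `vital_ts` waveform.
#' @param peak_times peak times in seconds, e.g. from [detect_peaks()];
#'   at least 3 peaks required.
#' @return scalar SQI in `[-1, 1]`.
#' @export
sqi <- function(x, peak_times) {
  if (length(peak_times) < 3)
    stop("need at least 3 peaks to form a template", call. = FALSE)
  idx <- round((peak_times - x$t0) * x$fs) + 1
  L <- stats::median(diff(idx))
  L <- round(L)
  if (L %% 2 == 0) L <- L + 1L  # odd length: peak sits exactly in the middle
  half <- (L - 1) / 2
  n <- length(x$values)
  complete <- idx[idx - half >= 1 & idx + half <= n]
  if (length(complete) < 2)
    stop("fewer than 2 complete pulses inside the segment", call. = FALSE)
  pulses <- vapply(complete, function(i)
    x$values[(i - half):(i + half)], numeric(L))
  informative <- apply(pulses, 2, stats::sd) > 0
  pulses <- pulses[, informative, drop = FALSE]
  if (ncol(pulses) < 2) return(0)
  template <- rowMeans(pulses)
  if (stats::sd(template) == 0) return(0)
  mean(apply(pulses, 2, stats::cor, y = template))
}

#' Quality gate for a signal segment
#'
#' A segment is used for rate estimation only when its SQI strictly exceeds
#' the modality threshold: 0.8 for the cardiac (rBVP) waveform and 0.7 for
#' the respiratory waveform.
#'
#' @param sqi_value scalar SQI in `[-1, 1]`.
#' @param kind `"cardiac"` or `"respiratory"`.
#' @param thresholds named numeric thresholds (defaults
#'   `c(cardiac = 0.8, respiratory = 0.7)`).
#' @return logical.
#' @export
sqi_passes <- function(sqi_value,
                       kind = c("cardiac", "respiratory"),
                       thresholds = c(cardiac = 0.8, respiratory = 0.7)) {
  kind <- match.arg(kind)
  sqi_value > thresholds[[kind]]
}
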