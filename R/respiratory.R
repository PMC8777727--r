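#' Respiration rate from the nostril temperature trace
#'
#' Exhaled air warms and inhaled air cools the nostril region, so the mean
#' nostril temperature oscillates at the breathing frequency. The trace is
#' band-passed to 0.15-0.5 Hz (9-30 breaths/min) with a zero-phase
#' 3rd-order Butterworth filter, breath peaks are detected with a 2-s
#' refractory period, and `RR = 60 / mean(interval)`. Note on polarity:
#' nostril temperature falls during inhalation (the opposite of a
#' force-based chest belt), but the rate is polarity-invariant, so no
#' inversion is applied.
#'
#' @param x a `vital_ts` nostril trace covering at least 15 s.
#' @param band respiratory passband in Hz (default `c(0.15, 0.5)`).
#' @param order Butterworth order (default 3).
#' @param sqi_threshold validity threshold on the SQI (default 0.7, strict).
#' @param min_separation_s breath-peak refractory period (default 2 s, a
#'   30 breaths/min ceiling).
#' @return an object of class `resp_result`: `waveform`, `peak_times`,
#'   `rr_brpm`, `sqi`, `valid`, `reason` (when invalid).
#' @export
estimate_rr <- function(x, band = c(0.15, 0.5), order = 3,
                        sqi_threshold = 0.7, min_separation_s = 2) {
  if (length(x$values) / x$fs < 15 - 1e-9)
    return(invalid_resp("window shorter than 15 s"))
  wave <- try(bandpass(x, band[1], band[2], order = order,
                       guard_periods = 2),
              silent = TRUE)
  if (inherits(wave, "try-error"))
    return(invalid_resp(conditionMessage(attr(wave, "condition"))))
  peaks <- detect_peaks(wave, min_separation_s = min_separation_s)
  if (isTRUE(attr(peaks, "insufficient")))
    return(invalid_resp("insufficient peaks"))
  rr <- rate_from_peaks(peaks)
  q <- tryCatch(sqi(wave, peaks), error = function(e) 0)
  valid <- q > sqi_threshold && rr >= band[1] * 60 && rr <= band[2] * 60
  structure(list(waveform = wave, peak_times = as.numeric(peaks),
                 rr_brpm = rr, sqi = q, valid = valid,
                 reason = if (valid) NA_character_
                          else if (q <= sqi_threshold) "SQI below threshold"
                          else "rate outside passband"),
            class = "resp_result")
}

invalid_resp <- function(reason) {
  structure(list(waveform = NULL, peak_times = numeric(0),
                 rr_brpm = NA_real_, sqi = NA_real_, valid = FALSE,
                 reason = reason),
            class = "resp_result")
}

#' @export
print.resp_result <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<resp_result: RR %.1f brpm, SQI %.3f, %d peaks>\n",
                x$rr_brpm, x$sqi, length(x$peak_times)))
  else
    cat(sprintf("<resp_result: invalid (%s)>\n", x$reason))
  invisible(x)
}
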