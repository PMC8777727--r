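#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by the standard
#' sifting procedure: at each step the mean of the upper and lower cubic
#' spline envelopes (through the local maxima and minima, with mirrored
#' boundary extrema) is subtracted until the Cauchy-type stopping criterion
#' `sum((h_prev - h)^2) / sum(h_prev^2) < sd_thresh` is met or `max_sift`
#' iterations elapse. Decomposition stops when the residue has fewer than
#' three extrema or `max_imfs` IMFs have been extracted. By construction,
#' the IMFs plus the residue sum exactly to the input.
#'
#' @param x numeric vector or `vital_ts`, length >= 100.
#' @param max_imfs maximum number of IMFs (default 10).
#' @param max_sift maximum sifting iterations per IMF (default 10).
#' @param sd_thresh sifting stop threshold (default 0.2).
#' @return list with `imfs` (list of numeric vectors) and `residue`.
#' @export
emd <- function(x, max_imfs = 10, max_sift = 10, sd_thresh = 0.2) {
  v <- if (inherits(x, "vital_ts")) x$values else as.numeric(x)
  if (length(v) < 100)
    stop("need at least 100 samples to sift", call. = FALSE)
  imfs <- list()
  residue <- v
  while (length(imfs) < max_imfs) {
    ext <- local_extrema(residue)
    if (length(ext$max) + length(ext$min) < 3) break
    h <- residue
    for (k in seq_len(max_sift)) {
      ext_h <- local_extrema(h)
      if (length(ext_h$max) < 2 || length(ext_h$min) < 2) break
      env_mean <- (spline_envelope(h, ext_h$max) +
                     spline_envelope(h, ext_h$min)) / 2
      h_new <- h - env_mean
      sd_k <- sum(env_mean^2) / sum(h^2)
      h <- h_new
      if (sd_k < sd_thresh) break
    }
    imfs[[length(imfs) + 1L]] <- h
    residue <- residue - h
  }
  list(imfs = imfs, residue = residue)
}

local_extrema <- function(v) {
  d <- diff(v)
  s <- sign(d)
  # collapse flats so plateau edges count once
  ch <- diff(s)
  list(max = which(ch < 0) + 1L, min = which(ch > 0) + 1L)
}

# Natural cubic spline through the extrema at `idx`, with up to two extrema
# mirrored past each end so the envelope does not sag at the boundaries.
spline_envelope <- function(v, idx) {
  n <- length(v)
  k <- min(2L, length(idx))
  left_t <- 2 * 1 - rev(idx[seq_len(k)])
  left_v <- rev(v[idx[seq_len(k)]])
  right_t <- 2 * n - rev(idx[seq.int(length(idx) - k + 1, length(idx))])
  right_v <- rev(v[idx[seq.int(length(idx) - k + 1, length(idx))]])
  tt <- c(left_t, idx, right_t)
  vv <- c(left_v, v[idx], right_v)
  keep <- !duplicated(tt)
  f <- stats::splinefun(tt[keep], vv[keep], method = "natural")
  f(seq_len(n))
}

#' Select the maximum-power IMF as the recovered pulse
#'
#' Runs [emd()] on the ICA source chosen by [select_rbvp()] and returns the
#' intrinsic mode function with the greatest mean-square power, which
#' carries the plethysmographic oscillation once broadband residue has been
#' stripped into the other modes.
#'
#' @param x a `vital_ts`.
#' @param ... passed to [emd()].
#' @return a `vital_ts` (the selected IMF) with attributes `imf_index` and
#'   `n_imfs`.
#' @export
emd_select <- function(x, ...) {
  dec <- emd(x, ...)
  if (length(dec$imfs) == 0)
    stop("decomposition produced no IMFs", call. = FALSE)
  pow <- vapply(dec$imfs, function(m) mean(m^2), numeric(1))
  i <- which.max(pow)
  out <- time_series(dec$imfs[[i]], x$fs, x$t0, label = "rbvp")
  attr(out, "imf_index") <- i
  attr(out, "n_imfs") <- length(dec$imfs)
  out
}
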