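#' Default pipeline configuration
#'
#' Nested list of every tunable parameter: the registration map (rig
#' calibration), thermal frame size and rendering window, analysis-window
#' length and overlap, the deflection gate, cardiac and respiratory band
#' edges and SQI thresholds, CLAHE settings, the body-temperature offset
#' and the gap policy. Override any subset via a YAML file and
#' [load_config()].
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    registration = list(sx = 0.4, sy = 0.4, tx = 0, ty = 0),
    thermal = list(width = 256, height = 192, render_window_s = 15),
    window = list(length_s = 15, overlap = 0.5),
    gating = list(deflection_threshold = 0.17, max_gated_fraction = 0.3),
    cardiac = list(low_hz = 0.8, high_hz = 2, order = 3,
                   sqi_threshold = 0.8, fallback = TRUE,
                   min_separation_s = 0.5),
    respiratory = list(low_hz = 0.15, high_hz = 0.5, order = 3,
                       sqi_threshold = 0.7, min_separation_s = 2),
    clahe = list(clip_limit = 2, tile_grid = c(8, 8)),
    bt = list(offset = 0),
    extraction = list(max_gap_s = 0.5)
  )
}

#' Load a configuration file
#'
#' Reads a YAML file and merges it over [default_config()]; keys not present
#' in the file keep their defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return nested configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  utils::modifyList(cfg, user)
}

config_map <- function(config) {
  r <- config$registration
  affine_map(r$sx, r$sy, r$tx, r$ty)
}

#' Sliding analysis windows
#'
#' Splits a recording of `duration_s` seconds into windows of `win_s`
#' seconds with fractional `overlap` between consecutive windows (default
#' 15 s with 50% overlap). Window k starts at `k * win_s * (1 - overlap)`;
#' only windows fully inside the recording are returned.
#'
#' @param duration_s recording length in seconds, `>= win_s`.
#' @param win_s window length in seconds (default 15).
#' @param overlap fractional overlap in `[0, 1)` (default 0.5).
#' @return two-column matrix of `(start, end)` times in seconds.
#' @export
sliding_windows <- function(duration_s, win_s = 15, overlap = 0.5) {
  if (duration_s < win_s)
    stop("recording shorter than one window", call. = FALSE)
  if (overlap < 0 || overlap >= 1)
    stop("`overlap` must lie in [0, 1)", call. = FALSE)
  step <- win_s * (1 - overlap)
  starts <- seq(0, duration_s - win_s + 1e-9, by = step)
  cbind(start = starts, end = starts + win_s)
}

#' Run the full pipeline on one recording
#'
#' Orchestrates every stage per subject and per sliding window: gates
#' deflected frames, locates the three ROIs, registers the nostril box and
#' forehead point onto the thermal grid, extracts the channel traces,
#' estimates HR (cardiac chain), RR (respiratory chain) and BT (median of
#' per-frame forehead lookups), and attaches signal-quality and gating
#' diagnostics. A window is invalid for every modality when more than
#' `gating$max_gated_fraction` of its frames are gated; individual
#' modalities can additionally fail on signal quality or unbridgeable gaps.
#'
#' RGB and thermal frames are paired by nearest timestamp; faces listed
#' under different `subject_id`s are processed independently.
#'
#' @param rgb list with `frames` (list of `h x w x 3` arrays, 0-255), `fs`,
#'   `t0` — see [read_rgb_frames()].
#' @param thermal list with `frames` (list of temperature matrices), `fs`,
#'   `t0` — see [read_thermal_csv()].
#' @param landmarks list of `landmark_frame` (or path to a sidecar CSV).
#' @param config nested configuration list (default [default_config()]).
#' @return an object of class `vital_windows`: a list of per-window result
#'   records, one sub-list per subject and window, with an
#'   [as.data.frame()] method.
#' @export
run_subject <- function(rgb, thermal, landmarks, config = default_config()) {
  if (is.character(landmarks)) landmarks <- read_landmarks(landmarks)
  n_rgb <- length(rgb$frames)
  if (n_rgb == 0 || length(thermal$frames) == 0)
    stop("empty frame stream", call. = FALSE)
  idx_bad <- vapply(landmarks, function(l)
    l$frame_index < 0 || l$frame_index >= n_rgb, logical(1))
  if (any(idx_bad))
    stop(sprintf("landmark frame_index %d outside the RGB stream (0..%d)",
                 landmarks[[which(idx_bad)[1]]]$frame_index, n_rgb - 1),
         call. = FALSE)
  dm <- dim(rgb$frames[[1]])
  rgb_dim <- c(dm[2], dm[1])
  thermal_dim <- c(config$thermal$width, config$thermal$height)
  m <- config_map(config)
  duration <- n_rgb / rgb$fs
  wins <- sliding_windows(duration, config$window$length_s,
                          config$window$overlap)

  # thermal rendering + CLAHE once for the whole stream
  rendered <- render_thermal(thermal$frames, thermal$fs,
                             config$thermal$render_window_s)
  enhanced <- lapply(rendered, clahe_enhance,
                     clip_limit = config$clahe$clip_limit,
                     tile_grid = config$clahe$tile_grid)
  t_rgb <- rgb$t0 + (seq_len(n_rgb) - 1) / rgb$fs
  t_th <- thermal$t0 + (seq_along(thermal$frames) - 1) / thermal$fs

  subjects <- unique(vapply(landmarks, `[[`, character(1), "subject_id"))
  results <- list()
  for (sid in subjects) {
    lms_s <- Filter(function(l) l$subject_id == sid, landmarks)
    # per-RGB-frame slots: landmark, gated flag, ROIs
    slot <- vector("list", n_rgb)
    for (l in lms_s) slot[[l$frame_index + 1L]] <- l
    gated <- vapply(seq_len(n_rgb), function(i) {
      l <- slot[[i]]
      is.null(l) || isTRUE(is_deflected(face_deflection(l),
                                        config$gating$deflection_threshold))
    }, logical(1))
    rois <- lapply(seq_len(n_rgb), function(i) {
      if (gated[i]) return(NULL)
      locate_rois(slot[[i]], frame_dim = rgb_dim)
    })
    hr_boxes <- lapply(seq_len(n_rgb), function(i) {
      r <- rois[[i]]
      if (is.null(r) || !r$valid[["hr"]]) NULL else r$hr_box
    })
    rr_boxes_th <- lapply(seq_len(n_rgb), function(i) {
      r <- rois[[i]]
      if (is.null(r) || !r$valid[["rr"]]) return(NULL)
      b <- map_roi(m, r$rr_box, thermal_dim)
      if (isTRUE(attr(b, "valid"))) b else NULL
    })
    bt_pts_th <- lapply(seq_len(n_rgb), function(i) {
      r <- rois[[i]]
      if (is.null(r) || !r$valid[["bt"]]) NULL
      else apply_map(m, r$bt_point)
    })

    for (k in seq_len(nrow(wins))) {
      w0 <- wins[k, 1]; w1 <- wins[k, 2]
      in_rgb <- which(t_rgb >= w0 - 1e-9 & t_rgb < w1 - 1e-9)
      in_th <- which(t_th >= w0 - 1e-9 & t_th < w1 - 1e-9)
      gf <- mean(gated[in_rgb])
      res <- list(subject_id = sid, window_start_s = w0,
                  deflected_fraction = gf,
                  hr = NULL, rr = NULL,
                  bt_celsius = NA_real_, bt_valid = FALSE)
      if (gf > config$gating$max_gated_fraction) {
        res$hr <- invalid_rbvp("too many gated frames")
        res$rr <- invalid_resp("too many gated frames")
        res$bt_reason <- "too many gated frames"
      } else {
        ## cardiac
        res$hr <- tryCatch({
          ch <- rgb_roi_means(rgb$frames[in_rgb], hr_boxes[in_rgb],
                              fs = rgb$fs, t0 = t_rgb[in_rgb[1]],
                              max_gap_s = config$extraction$max_gap_s)
          if (anyNA(ch$green$values))
            invalid_rbvp("gap longer than the interpolation limit")
          else
            estimate_hr(ch$red, ch$green, ch$blue,
                        band = c(config$cardiac$low_hz,
                                 config$cardiac$high_hz),
                        order = config$cardiac$order,
                        sqi_threshold = config$cardiac$sqi_threshold,
                        fallback = config$cardiac$fallback,
                        min_separation_s = config$cardiac$min_separation_s)
        }, error = function(e) invalid_rbvp(conditionMessage(e)))
        ## respiratory: nearest RGB frame supplies each thermal frame's ROI
        res$rr <- tryCatch({
          near <- pmin(pmax(round((t_th[in_th] - rgb$t0) * rgb$fs) + 1L,
                            1L), n_rgb)
          skew <- abs(t_th[in_th] - t_rgb[near])
          boxes <- lapply(seq_along(in_th), function(j) {
            if (skew[j] > 1 / (2 * rgb$fs) + 1e-9) return(NULL)
            rr_boxes_th[[near[j]]]
          })
          xn <- thermal_roi_mean(enhanced[in_th], boxes, fs = thermal$fs,
                                 t0 = t_th[in_th[1]],
                                 max_gap_s = config$extraction$max_gap_s)
          if (anyNA(xn$values))
            invalid_resp("gap longer than the interpolation limit")
          else
            estimate_rr(xn,
                        band = c(config$respiratory$low_hz,
                                 config$respiratory$high_hz),
                        order = config$respiratory$order,
                        sqi_threshold = config$respiratory$sqi_threshold,
                        min_separation_s =
                          config$respiratory$min_separation_s)
        }, error = function(e) invalid_resp(conditionMessage(e)))
        ## body temperature: median of per-frame lookups on raw matrices
        bt_vals <- unlist(lapply(seq_along(in_th), function(j) {
          near_j <- pmin(pmax(round((t_th[in_th[j]] - rgb$t0) * rgb$fs) + 1L,
                              1L), n_rgb)
          p <- bt_pts_th[[near_j]]
          if (is.null(p)) return(NULL)
          tryCatch(bt_lookup(thermal$frames[[in_th[j]]], p,
                             offset = config$bt$offset),
                   error = function(e) NULL)
        }))
        if (length(bt_vals) >= 1) {
          res$bt_celsius <- stats::median(bt_vals)
          res$bt_valid <- TRUE
        } else res$bt_reason <- "no valid forehead lookups"
      }
      results[[length(results) + 1L]] <- res
    }
  }
  structure(results, class = "vital_windows")
}

#' @export
print.vital_windows <- function(x, ...) {
  cat(sprintf("<vital_windows: %d window results>\n", length(x)))
  print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Flatten pipeline results to a data frame
#'
#' One row per subject and window with the HR, RR and BT estimates, SQI
#' values, validity flags, reason codes and the gated-frame fraction.
#'
#' @param x a `vital_windows` object from [run_subject()].
#' @param row.names,optional,... ignored (S3 signature).
#' @return `data.frame`.
#' @export
as.data.frame.vital_windows <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  rows <- lapply(x, function(r) {
    data.frame(subject_id = r$subject_id,
               window_start_s = r$window_start_s,
               hr_bpm = r$hr$hr_bpm, hr_sqi = r$hr$sqi,
               hr_valid = r$hr$valid,
               hr_reason = if (r$hr$valid) "" else r$hr$reason,
               rr_brpm = r$rr$rr_brpm, rr_sqi = r$rr$sqi,
               rr_valid = r$rr$valid,
               rr_reason = if (r$rr$valid) "" else r$rr$reason,
               bt_celsius = r$bt_celsius, bt_valid = r$bt_valid,
               deflected_fraction = r$deflected_fraction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Agreement between estimates and a reference
#'
#' Standard evaluation utilities for paired estimate/reference values:
#' mean absolute error with its standard deviation, the Pearson
#' correlation, and the Bland-Altman bias with 95% limits of agreement
#' (`bias +/- 1.96 * SD` of the paired differences). Pairs with a missing
#' value on either side are dropped.
#'
#' @param estimates,reference numeric vectors of equal length (same windows
#'   or cycles, same units).
#' @return list with `n`, `mae`, `sd_ae`, `pearson_r` (`NA` with
#'   `r_defined = FALSE` when either side has zero variance), `bias`,
#'   `loa_lower`, `loa_upper`.
#' @export
evaluate_agreement <- function(estimates, reference) {
  if (length(estimates) != length(reference))
    stop("estimates and reference must pair up", call. = FALSE)
  ok <- is.finite(estimates) & is.finite(reference)
  e <- estimates[ok]; r <- reference[ok]
  if (length(e) == 0) stop("no overlapping finite pairs", call. = FALSE)
  d <- e - r
  r_def <- length(e) > 1 && stats::sd(e) > 0 && stats::sd(r) > 0
  list(n = length(e),
       mae = mean(abs(d)),
       sd_ae = stats::sd(abs(d)),
       pearson_r = if (r_def) stats::cor(e, r) else NA_real_,
       r_defined = r_def,
       bias = mean(d),
       loa_lower = mean(d) - 1.96 * stats::sd(d),
       loa_upper = mean(d) + 1.96 * stats::sd(d))
}
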