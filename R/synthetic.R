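#' Specification of a synthetic two-camera recording
#'
#' Describes a synthetic subject standing in front of the paired RGB and
#' thermal cameras: a rigid face-box/landmark geometry, forehead pixels
#' whose intensity is modulated at the cardiac frequency (green channel
#' strongest, mimicking plethysmographic dominance), nostril pixels in the
#' thermal matrix oscillating at the respiratory frequency over a slow
#' random-walk drift, and a constant forehead temperature. Thermal geometry
#' is the registration map applied to the RGB geometry. With a fixed seed
#' the generated streams are bitwise reproducible.
#'
#' Defaults reflect the target rig: 25 frames per second on both streams,
#' a 640 x 480 RGB frame, a 256 x 192 thermal matrix at a 0.4 pixel scale,
#' per-pixel sensor noise of 2 gray levels (RGB) and 0.05 degrees C
#' (thermal, a typical uncooled-core noise floor), a 1 gray-level green
#' pulse amplitude and a 0.3 degrees C nostril swing.
#'
#' @param duration_s recording length in seconds (default 15).
#' @param fs_rgb,fs_thermal frame rates in Hz (default 25 each; set them
#'   apart to exercise per-stream rate handling).
#' @param hr_bpm true heart rate, within 48-120 (default 72).
#' @param rr_brpm true respiration rate, within 9-30 (default 15).
#' @param bt_celsius true forehead temperature (default 36.5).
#' @param pulse_amplitude named per-channel gains in gray levels
#'   (default `c(r = 0.4, g = 1, b = 0.5)`).
#' @param resp_amplitude nostril temperature swing in degrees C (default 0.3).
#' @param noise_sd_rgb per-pixel RGB noise SD in gray levels (default 2).
#' @param illum_sd per-frame shared illumination fluctuation SD in gray
#'   levels (default 0.3); unlike pixel noise it does not average out over
#'   the ROI.
#' @param noise_sd_thermal per-pixel thermal noise SD in degrees C
#'   (default 0.05).
#' @param drift_sd per-frame random-walk step SD of the nostril baseline in
#'   degrees C (default 0.005), included to exercise the band-pass filter.
#' @param deflection_profile optional per-frame horizontal eye-midpoint
#'   offset as a fraction of the face-box width (scalar or vector recycled
#'   to the frame count); 0 keeps the face frontal.
#' @param registration `affine_map` from RGB to thermal coordinates
#'   (default `affine_map(0.4, 0.4, 0, 0)`).
#' @param rgb_dim,thermal_dim frame sizes `c(w, h)` (defaults `c(640, 480)`
#'   and `c(256, 192)`); the face geometry scales with `rgb_dim`.
#' @param subject_id label written into the landmark records.
#' @param seed RNG seed; fixed seed implies reproducible output.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(duration_s = 15, fs_rgb = 25, fs_thermal = 25,
                         hr_bpm = 72, rr_brpm = 15, bt_celsius = 36.5,
                         pulse_amplitude = c(r = 0.4, g = 1, b = 0.5),
                         resp_amplitude = 0.3, noise_sd_rgb = 2,
                         illum_sd = 0.3, noise_sd_thermal = 0.05,
                         drift_sd = 0.005, deflection_profile = 0,
                         registration = affine_map(0.4, 0.4, 0, 0),
                         rgb_dim = c(640, 480), thermal_dim = c(256, 192),
                         subject_id = "s1", seed = 1) {
  if (hr_bpm < 48 || hr_bpm > 120)
    stop("hr_bpm must lie in [48, 120]", call. = FALSE)
  if (rr_brpm < 9 || rr_brpm > 30)
    stop("rr_brpm must lie in [9, 30]", call. = FALSE)
  if (resp_amplitude < 0 || any(pulse_amplitude < 0))
    stop("amplitudes must be non-negative", call. = FALSE)
  if (is.null(names(pulse_amplitude))) {
    stopifnot(length(pulse_amplitude) == 3)
    names(pulse_amplitude) <- c("r", "g", "b")
  }
  structure(as.list(environment()), class = "fixture_spec")
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat(sprintf(paste0("<fixture_spec: %g s, HR %g bpm, RR %g brpm, ",
                     "BT %g C, seed %d>\n"),
              x$duration_s, x$hr_bpm, x$rr_brpm, x$bt_celsius, x$seed))
  invisible(x)
}

# Rigid face geometry in 640x480 reference units, scaled to the frame size.
fixture_geometry <- function(spec) {
  s <- spec$rgb_dim / c(640, 480)
  sc <- function(p) p * s
  list(box = c(220 * s[1], 100 * s[2], 200 * s[1], 280 * s[2]),
       left_eye = sc(c(280, 180)), right_eye = sc(c(360, 180)),
       nose_tip = sc(c(320, 230)),
       mouth_left = sc(c(290, 265)), mouth_right = sc(c(350, 265)))
}

fixture_landmarks <- function(spec) {
  g <- fixture_geometry(spec)
  n <- round(spec$duration_s * spec$fs_rgb)
  defl <- rep_len(spec$deflection_profile, n)
  lapply(seq_len(n), function(i) {
    dx <- defl[i] * g$box[3]
    landmark_frame(i - 1L, g$box,
                   g$left_eye + c(dx, 0), g$right_eye + c(dx, 0),
                   g$nose_tip, g$mouth_left, g$mouth_right,
                   confidence = 0.99, subject_id = spec$subject_id)
  })
}

# pulse waveform: fundamental plus a small second harmonic, unit peak scale
pulse_wave <- function(t, hr_bpm) {
  f <- hr_bpm / 60
  sin(2 * pi * f * t) + 0.25 * sin(4 * pi * f * t + 1)
}

#' Generate a synthetic two-camera recording
#'
#' Renders the full frame streams described by a [fixture_spec()]: RGB
#' frames with pulse-modulated forehead pixels, thermal matrices with a
#' breathing nostril patch and a constant-temperature forehead point, rigid
#' landmarks (with optional horizontal deflection), and the ground-truth
#' record. Memory grows with `duration_s * prod(rgb_dim)`; for long
#' parameter-recovery studies prefer the ROI-level generators
#' [fixture_channel_series()] and [fixture_nostril_series()].
#'
#' @param spec a `fixture_spec`.
#' @return list with `rgb` (`frames`, `fs`, `t0`), `thermal` (`frames`,
#'   `fs`, `t0`), `landmarks` (list of `landmark_frame`), `truth`
#'   (`hr_bpm`, `rr_brpm`, `bt_celsius`), and `spec`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_seed(spec$seed, {
    lms <- fixture_landmarks(spec)
    rois <- lapply(lms, locate_rois, frame_dim = spec$rgb_dim)
    g <- fixture_geometry(spec)

    n_rgb <- round(spec$duration_s * spec$fs_rgb)
    t_rgb <- (seq_len(n_rgb) - 1) / spec$fs_rgb
    pulse <- pulse_wave(t_rgb, spec$hr_bpm)
    base <- c(150, 120, 110)  # skin-toned background, gray levels
    w <- spec$rgb_dim[1]; h <- spec$rgb_dim[2]
    gains <- unname(spec$pulse_amplitude[c("r", "g", "b")])
    rgb_frames <- vector("list", n_rgb)
    for (i in seq_len(n_rgb)) {
      fr <- array(stats::rnorm(h * w * 3, sd = spec$noise_sd_rgb),
                  dim = c(h, w, 3))
      illum <- stats::rnorm(3, sd = spec$illum_sd)
      hr_px <- roi_pixel_range(rois[[i]]$hr_box, spec$rgb_dim)
      for (ch in 1:3) {
        fr[, , ch] <- fr[, , ch] + base[ch] + illum[ch]
        if (!is.null(hr_px))
          fr[hr_px$rows, hr_px$cols, ch] <-
            fr[hr_px$rows, hr_px$cols, ch] + gains[ch] * pulse[i]
      }
      rgb_frames[[i]] <- fr
    }

    n_th <- round(spec$duration_s * spec$fs_thermal)
    t_th <- (seq_len(n_th) - 1) / spec$fs_thermal
    resp <- spec$resp_amplitude * sin(2 * pi * spec$rr_brpm / 60 * t_th)
    drift <- cumsum(stats::rnorm(n_th, sd = spec$drift_sd))
    tw <- spec$thermal_dim[1]; th <- spec$thermal_dim[2]
    m <- spec$registration
    face_th <- map_roi(m, g$box, spec$thermal_dim)
    # frontal-face nostril box and forehead point on the thermal grid
    rr_th <- map_roi(m, locate_rr_box(lms_frontal(spec)), spec$thermal_dim)
    bt_th <- apply_map(m, locate_bt_point(lms_frontal(spec)))
    face_px <- roi_pixel_range(face_th, spec$thermal_dim)
    rr_px <- roi_pixel_range(rr_th, spec$thermal_dim)
    bt_col <- floor(bt_th[1] + 0.5) + 1L
    bt_row <- floor(bt_th[2] + 0.5) + 1L
    bt_rows <- max(1, bt_row - 1):min(th, bt_row + 1)
    bt_cols <- max(1, bt_col - 1):min(tw, bt_col + 1)
    thermal_frames <- vector("list", n_th)
    for (i in seq_len(n_th)) {
      fr <- matrix(28 + stats::rnorm(th * tw, sd = spec$noise_sd_thermal),
                   th, tw)
      if (!is.null(face_px))
        fr[face_px$rows, face_px$cols] <-
          33 + stats::rnorm(length(face_px$rows) * length(face_px$cols),
                            sd = spec$noise_sd_thermal)
      if (!is.null(rr_px))
        fr[rr_px$rows, rr_px$cols] <-
          33 + drift[i] + resp[i] +
          stats::rnorm(length(rr_px$rows) * length(rr_px$cols),
                       sd = spec$noise_sd_thermal)
      fr[bt_rows, bt_cols] <- spec$bt_celsius +
        stats::rnorm(length(bt_rows) * length(bt_cols),
                     sd = spec$noise_sd_thermal)
      thermal_frames[[i]] <- fr
    }

    list(rgb = list(frames = rgb_frames, fs = spec$fs_rgb, t0 = 0),
         thermal = list(frames = thermal_frames, fs = spec$fs_thermal,
                        t0 = 0),
         landmarks = lms,
         truth = list(hr_bpm = spec$hr_bpm, rr_brpm = spec$rr_brpm,
                      bt_celsius = spec$bt_celsius),
         spec = spec)
  })
}

# frontal (zero-deflection) landmark frame for painting thermal geometry
lms_frontal <- function(spec) {
  g <- fixture_geometry(spec)
  landmark_frame(0L, g$box, g$left_eye, g$right_eye, g$nose_tip,
                 g$mouth_left, g$mouth_right, subject_id = spec$subject_id)
}

#' Forehead colour-channel series of a synthetic recording
#'
#' Memory-lean generator for parameter-recovery studies: synthesizes only
#' the forehead-box pixel block of each frame (same modulation, illumination
#' fluctuation and per-pixel noise as [generate_fixture()]) and extracts the
#' channel means through [rgb_roi_means()]. Statistically equivalent to
#' running the extraction on full frames, at a fraction of the memory.
#'
#' @param spec a `fixture_spec`.
#' @return list with `r`, `g`, `b` (`vital_ts`) and `truth`.
#' @export
fixture_channel_series <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_seed(spec$seed, {
    lm <- lms_frontal(spec)
    hr_box <- locate_hr_box(lm, frame_dim = spec$rgb_dim)
    px <- roi_pixel_range(hr_box, spec$rgb_dim)
    if (is.null(px)) stop("degenerate forehead box", call. = FALSE)
    nr <- length(px$rows); nc <- length(px$cols)
    n <- round(spec$duration_s * spec$fs_rgb)
    t <- (seq_len(n) - 1) / spec$fs_rgb
    pulse <- pulse_wave(t, spec$hr_bpm)
    base <- c(150, 120, 110)
    gains <- unname(spec$pulse_amplitude[c("r", "g", "b")])
    frames <- vector("list", n)
    roi <- c(0, 0, nc, nr)  # the block is the ROI
    for (i in seq_len(n)) {
      fr <- array(stats::rnorm(nr * nc * 3, sd = spec$noise_sd_rgb),
                  dim = c(nr, nc, 3))
      illum <- stats::rnorm(3, sd = spec$illum_sd)
      for (ch in 1:3)
        fr[, , ch] <- fr[, , ch] + base[ch] + illum[ch] + gains[ch] * pulse[i]
      frames[[i]] <- fr
    }
    out <- rgb_roi_means(frames, rep(list(roi), n), fs = spec$fs_rgb)
    list(r = out$red, g = out$green, b = out$blue,
         truth = list(hr_bpm = spec$hr_bpm))
  })
}

#' Nostril temperature series of a synthetic recording
#'
#' Memory-lean counterpart of [fixture_channel_series()] for the thermal
#' stream: synthesizes only the registered nostril-box pixel block (breath
#' oscillation + random-walk drift + sensor noise) and extracts the
#' per-frame raw-temperature mean through [thermal_roi_mean()].
#'
#' @param spec a `fixture_spec`.
#' @return list with `x` (`vital_ts`, nostril trace) and `truth`.
#' @export
fixture_nostril_series <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_seed(spec$seed, {
    rr_th <- map_roi(spec$registration, locate_rr_box(lms_frontal(spec)),
                     spec$thermal_dim)
    px <- roi_pixel_range(rr_th, spec$thermal_dim)
    if (is.null(px)) stop("degenerate nostril box", call. = FALSE)
    nr <- length(px$rows); nc <- length(px$cols)
    n <- round(spec$duration_s * spec$fs_thermal)
    t <- (seq_len(n) - 1) / spec$fs_thermal
    resp <- spec$resp_amplitude * sin(2 * pi * spec$rr_brpm / 60 * t)
    drift <- cumsum(stats::rnorm(n, sd = spec$drift_sd))
    frames <- lapply(seq_len(n), function(i)
      matrix(33 + drift[i] + resp[i] +
               stats::rnorm(nr * nc, sd = spec$noise_sd_thermal), nr, nc))
    x <- thermal_roi_mean(frames, rep(list(c(0, 0, nc, nr)), n),
                          fs = spec$fs_thermal)
    list(x = x, truth = list(rr_brpm = spec$rr_brpm))
  })
}

#' Write a generated fixture to disk
#'
#' Writes the streams in the same dialects the readers consume: RGB frames
#' as a PNG directory, thermal frames as a CSV-per-frame directory, the
#' landmark sidecar as CSV and the ground-truth record as JSON.
#'
#' @param fix output of [generate_fixture()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_rgb_frames(fix$rgb$frames, file.path(dir, "rgb"))
  write_thermal_csv(fix$thermal$frames, file.path(dir, "thermal"))
  write_landmarks(fix$landmarks, file.path(dir, "landmarks.csv"))
  meta <- c(fix$truth, list(fs_rgb = fix$rgb$fs, fs_thermal = fix$thermal$fs))
  jsonlite::write_json(meta, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
with_fixture_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
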