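#' Per-frame colour-channel means over the forehead box
#'
#' For each RGB frame, averages the red, green and blue channels over the
#' heart-rate ROI. Frames with a missing or invalid ROI (for example,
#' deflection-gated frames) produce gap markers; interior gaps no longer
#' than `max_gap_s` are bridged by linear interpolation, longer gaps stay
#' `NA` so [fill_gaps()] can split the trace into segments.
#'
#' @param frames list of `h x w x 3` arrays with values in 0-255.
#' @param rois list of `c(x, y, w, h)` forehead boxes, one per frame; `NULL`
#'   or `NA` entries mark gated/undetected frames.
#' @param fs frame rate in Hz.
#' @param t0 time of the first frame (s).
#' @param max_gap_s longest gap bridged by interpolation (default 0.5 s).
#' @return named list of three `vital_ts` (`red`, `green`, `blue`).
#' @export
rgb_roi_means <- function(frames, rois, fs, t0 = 0, max_gap_s = 0.5) {
  stopifnot(length(frames) == length(rois))
  n <- length(frames)
  vals <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    r <- rois[[i]]
    if (is.null(r) || anyNA(r)) next
    fr <- frames[[i]]
    dm <- dim(fr)
    px <- roi_pixel_range(r, frame_dim = c(dm[2], dm[1]))
    if (is.null(px)) next
    for (ch in 1:3) vals[i, ch] <- mean(fr[px$rows, px$cols, ch])
  }
  if (all(is.na(vals[, 1])))
    stop("no valid frames: every ROI was missing or degenerate", call. = FALSE)
  out <- lapply(1:3, function(ch)
    interp_short_gaps(time_series(vals[, ch], fs, t0,
                                  label = c("red", "green", "blue")[ch]),
                      max_gap_s))
  names(out) <- c("red", "green", "blue")
  out
}

# bridge interior NA runs of at most max_gap_s seconds; leave longer runs
interp_short_gaps <- function(x, max_gap_s) {
  v <- x$values
  if (!anyNA(v)) return(x)
  max_run <- floor(max_gap_s * x$fs + 1e-9)
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (!r$values[k] || r$lengths[k] > max_run) next
    if (starts[k] == 1L || ends[k] == length(v)) next
    i0 <- starts[k] - 1L; i1 <- ends[k] + 1L
    v[starts[k]:ends[k]] <-
      stats::approx(c(i0, i1), v[c(i0, i1)], xout = starts[k]:ends[k])$y
  }
  time_series(v, x$fs, x$t0, x$label)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Spreads out the most frequent intensity values tile by tile, amplifying
#' the weak respiration-induced contrast around the nostrils before the
#' thermal trace is extracted. Wraps the CLAHE implementation in EBImage.
#'
#' @param img 2-D numeric matrix (rows = y) with values in 0-255.
#' @param clip_limit contrast clip limit (default 2).
#' @param tile_grid integer `c(nx, ny)` tile counts (default `c(8, 8)`).
#' @return enhanced matrix, same shape, values in 0-255.
#' @export
clahe_enhance <- function(img, clip_limit = 2, tile_grid = c(8, 8)) {
  if (!is.matrix(img)) stop("`img` must be a 2-D matrix", call. = FALSE)
  rng <- range(img)
  if (rng[1] == rng[2]) return(img)  # uniform image: no contrast to create
  e <- EBImage::clahe(EBImage::Image(t(img) / 255),
                      nx = tile_grid[1], ny = tile_grid[2],
                      limit = clip_limit)
  t(EBImage::imageData(e)) * 255
}

#' Render raw thermal frames to 8-bit grayscale
#'
#' Min-max normalizes each frame's temperatures to 0-255 using the range
#' observed over a rolling window (default 15 s) centred on the frame, so
#' one hot outlier frame does not re-scale the whole stream.
#'
#' @param frames list of temperature matrices (degrees C, rows = y).
#' @param fs frame rate in Hz.
#' @param window_s rolling normalization window length (s); `Inf` uses the
#'   global range.
#' @return list of 8-bit matrices (numeric, 0-255).
#' @export
render_thermal <- function(frames, fs, window_s = 15) {
  n <- length(frames)
  lo <- vapply(frames, min, numeric(1))
  hi <- vapply(frames, max, numeric(1))
  half <- if (is.finite(window_s)) floor(window_s * fs / 2) else n
  lapply(seq_len(n), function(i) {
    w <- max(1, i - half):min(n, i + half)
    a <- min(lo[w]); b <- max(hi[w])
    if (b <= a) return(frames[[i]] * 0)
    pmin(pmax((frames[[i]] - a) / (b - a) * 255, 0), 255)
  })
}

#' Mean nostril temperature trace
#'
#' Averages all pixels inside the (registered, clipped) nostril box of each
#' frame, typically after [render_thermal()] + [clahe_enhance()]. Follows
#' the same gap policy as [rgb_roi_means()].
#'
#' @param frames list of 2-D matrices (rendered gray values or raw degrees C).
#' @param rois list of `c(x, y, w, h)` boxes in thermal coordinates; `NULL`
#'   or `NA` entries mark gaps.
#' @param fs frame rate in Hz.
#' @param t0 time of the first frame (s).
#' @param max_gap_s longest gap bridged by interpolation (default 0.5 s).
#' @return a `vital_ts` labelled `"nostril"`.
#' @export
thermal_roi_mean <- function(frames, rois, fs, t0 = 0, max_gap_s = 0.5) {
  stopifnot(length(frames) == length(rois))
  n <- length(frames)
  vals <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    r <- rois[[i]]
    if (is.null(r) || anyNA(r)) next
    fr <- frames[[i]]
    px <- roi_pixel_range(r, frame_dim = c(ncol(fr), nrow(fr)))
    if (is.null(px)) next
    vals[i] <- mean(fr[px$rows, px$cols])
  }
  if (all(is.na(vals)))
    stop("no valid frames: every nostril ROI was missing or degenerate",
         call. = FALSE)
  interp_short_gaps(time_series(vals, fs, t0, label = "nostril"), max_gap_s)
}

#' Forehead temperature readout
#'
#' Reads the raw temperature matrix at the forehead point, nearest-pixel,
#' with no interpolation: the thermal stream delivers calibrated degrees
#' Celsius per pixel, and the point readout reproduces the matrix entry
#' exactly. An optional additive offset supports a rig-specific skin-to-core
#' correction.
#'
#' @param temps 2-D temperature matrix (rows = y, degrees C).
#' @param p `c(x, y)` point in thermal coordinates (0-based).
#' @param offset additive correction in degrees C (default 0).
#' @return temperature in degrees C.
#' @export
bt_lookup <- function(temps, p, offset = 0) {
  col <- floor(p[1] + 0.5) + 1L
  row <- floor(p[2] + 0.5) + 1L
  if (row < 1 || row > nrow(temps) || col < 1 || col > ncol(temps))
    stop(sprintf("point (%g, %g) lies outside the %d x %d thermal frame",
                 p[1], p[2], ncol(temps), nrow(temps)), call. = FALSE)
  temps[row, col] + offset
}

# ---- frame stream I/O -----------------------------------------------------

#' Read an RGB frame directory
#'
#' Loads a directory of 8-bit PNG frames (sorted by file name) into a frame
#' stream. Values are rescaled to 0-255.
#'
#' @param dir directory containing `.png` frames.
#' @param fs frame rate in Hz.
#' @param t0 time of the first frame (s).
#' @return list with `frames` (list of `h x w x 3` arrays), `fs`, `t0`.
#' @export
read_rgb_frames <- function(dir, fs, t0 = 0) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no .png frames in ", dir, call. = FALSE)
  frames <- lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
    a[, , 1:3, drop = FALSE] * 255
  })
  list(frames = frames, fs = fs, t0 = t0)
}

#' Write an RGB frame directory
#' @param frames list of `h x w x 3` arrays, values 0-255.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_rgb_frames <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(frames)) {
    png::writePNG(pmin(pmax(frames[[i]] / 255, 0), 1),
                  file.path(dir, sprintf("frame_%06d.png", i - 1L)))
  }
  invisible(dir)
}

#' Read raw thermal frames from a CSV directory
#'
#' One CSV file per frame (sorted by name), each a plain numeric matrix of
#' temperatures in degrees Celsius, no header.
#'
#' @param dir directory of `.csv` frames.
#' @param fs frame rate in Hz.
#' @param t0 time of the first frame (s).
#' @return list with `frames` (list of matrices), `fs`, `t0`.
#' @export
read_thermal_csv <- function(dir, fs, t0 = 0) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) stop("no .csv frames in ", dir, call. = FALSE)
  frames <- lapply(files, function(f)
    as.matrix(utils::read.table(f, sep = ",", header = FALSE)))
  frames <- lapply(frames, function(m) {
    dimnames(m) <- NULL
    m
  })
  list(frames = frames, fs = fs, t0 = t0)
}

#' Write raw thermal frames to a CSV directory
#' @param frames list of temperature matrices.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_thermal_csv <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(frames)) {
    utils::write.table(frames[[i]],
                       file.path(dir, sprintf("frame_%06d.csv", i - 1L)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read a binary thermal stream
#'
#' Reads concatenated frames of little-endian signed 16-bit centi-degrees
#' (the raw sensor dialect), row-major within each frame.
#'
#' @param path binary file path.
#' @param frame_dim `c(w, h)` frame size (default `c(256, 192)`).
#' @param fs frame rate in Hz.
#' @param t0 time of the first frame (s).
#' @return list with `frames` (list of matrices, degrees C), `fs`, `t0`.
#' @export
read_thermal_bin <- function(path, fs, frame_dim = c(256, 192), t0 = 0) {
  npx <- prod(frame_dim)
  raw <- readBin(path, integer(), n = file.size(path) / 2, size = 2,
                 signed = TRUE, endian = "little")
  if (length(raw) %% npx != 0)
    stop("file length is not a whole number of ", frame_dim[1], " x ",
         frame_dim[2], " frames", call. = FALSE)
  nframes <- length(raw) %/% npx
  frames <- lapply(seq_len(nframes), function(i) {
    v <- raw[((i - 1) * npx + 1):(i * npx)] / 100
    matrix(v, nrow = frame_dim[2], ncol = frame_dim[1], byrow = TRUE)
  })
  list(frames = frames, fs = fs, t0 = t0)
}

#' Write a binary thermal stream
#'
#' Temperatures are rounded to centi-degrees and stored as little-endian
#' signed 16-bit integers, row-major per frame; the round trip through
#' [read_thermal_bin()] is exact to 0.005 degrees C.
#'
#' @param frames list of temperature matrices.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_thermal_bin <- function(frames, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (fr in frames) {
    writeBin(as.integer(round(as.vector(t(fr)) * 100)), con, size = 2,
             endian = "little")
  }
  invisible(path)
}
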