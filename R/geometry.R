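#' Per-frame facial landmarks and face box
#'
#' Holds the five facial landmarks (eyes, nose tip, mouth corners) and the
#' face bounding box detected on one RGB frame. Coordinates follow the image
#' convention: 0-based, x rightward, y downward; boxes are
#' `(x_min, y_min, w, h)` with half-open pixel extents.
#'
#' @param frame_index integer frame number (0-based).
#' @param box numeric `c(x, y, w, h)` face bounding box, `w > 0`, `h > 0`.
#' @param left_eye,right_eye,nose_tip,mouth_left,mouth_right numeric `c(x, y)`
#'   landmark points in pixels.
#' @param confidence detector confidence in `[0, 1]`.
#' @param subject_id label identifying the face when several subjects appear.
#' @return An object of class `landmark_frame`.
#' @export
landmark_frame <- function(frame_index, box, left_eye, right_eye, nose_tip,
                           mouth_left, mouth_right, confidence = 1,
                           subject_id = "s1") {
  pts <- list(left_eye = left_eye, right_eye = right_eye, nose_tip = nose_tip,
              mouth_left = mouth_left, mouth_right = mouth_right)
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (!is.numeric(p) || length(p) != 2 || !all(is.finite(p)))
      stop(sprintf("landmark '%s' must be a finite (x, y) pair", nm),
           call. = FALSE)
  }
  if (!is.numeric(box) || length(box) != 4 || !all(is.finite(box)))
    stop("`box` must be finite (x, y, w, h)", call. = FALSE)
  if (box[3] <= 0 || box[4] <= 0)
    stop("face box must have positive width and height", call. = FALSE)
  if (!is.finite(confidence) || confidence < 0 || confidence > 1)
    stop("`confidence` must lie in [0, 1]", call. = FALSE)
  structure(c(list(frame_index = as.integer(frame_index),
                   box = as.numeric(box)),
              lapply(pts, as.numeric),
              list(confidence = confidence, subject_id = subject_id)),
            class = "landmark_frame")
}

#' @export
print.landmark_frame <- function(x, ...) {
  cat(sprintf("<landmark_frame #%d [%s]: box (%.1f, %.1f, %.1f, %.1f), conf %.2f>\n",
              x$frame_index, x$subject_id, x$box[1], x$box[2], x$box[3],
              x$box[4], x$confidence))
  invisible(x)
}

eye_mid <- function(lm) (lm$left_eye + lm$right_eye) / 2

clip_point <- function(p, frame_dim) {
  # frame_dim = c(w, h); keep point inside the half-open pixel extent
  c(min(max(p[1], 0), frame_dim[1] - 1), min(max(p[2], 0), frame_dim[2] - 1))
}

#' Clip a rectangle to frame bounds
#'
#' @param r numeric `c(x, y, w, h)`.
#' @param frame_dim numeric `c(w, h)` of the frame, or `NULL` to skip.
#' @return clipped `c(x, y, w, h)`; width/height may reach 0 when the
#'   rectangle lies outside the frame.
#' @export
clip_rect <- function(r, frame_dim = NULL) {
  if (is.null(frame_dim)) return(r)
  x0 <- max(r[1], 0); y0 <- max(r[2], 0)
  x1 <- min(r[1] + r[3], frame_dim[1]); y1 <- min(r[2] + r[4], frame_dim[2])
  c(x0, y0, max(x1 - x0, 0), max(y1 - y0, 0))
}

# Integer pixel index ranges covered by a rectangle: edges rounded to the
# nearest integer, then half-open slicing. Returns NULL when the clipped
# area is below `min_area` pixels (degenerate ROI).
roi_pixel_range <- function(r, frame_dim, min_area = 4) {
  r <- clip_rect(r, frame_dim)
  x0 <- floor(r[1] + 0.5); x1 <- floor(r[1] + r[3] + 0.5)
  y0 <- floor(r[2] + 0.5); y1 <- floor(r[2] + r[4] + 0.5)
  x1 <- min(x1, frame_dim[1]); y1 <- min(y1, frame_dim[2])
  if ((x1 - x0) * (y1 - y0) < min_area) return(NULL)
  list(cols = (x0 + 1):x1, rows = (y0 + 1):y1)  # 1-based matrix indices
}

#' Forehead point for body-temperature readout
#'
#' The temperature readout point sits on the forehead midline: its x is the
#' mean of the two eye x-coordinates, and its y lies `H1 / 3` above the eye
#' midpoint, where `H1` is the vertical distance from the top edge of the
#' face box down to the eye midpoint (y grows downward).
#'
#' @param lm a `landmark_frame`.
#' @param frame_dim optional `c(w, h)` frame size for clipping.
#' @return numeric `c(x, y)`; carries `attr(, "valid") = FALSE` when the eye
#'   midpoint does not lie below the top of the box (`H1 <= 0`).
#' @export
locate_bt_point <- function(lm, frame_dim = NULL) {
  em <- eye_mid(lm)
  h1 <- em[2] - lm$box[2]
  if (h1 <= 0) {
    p <- em
    attr(p, "valid") <- FALSE
    return(p)
  }
  p <- c(em[1], em[2] - h1 / 3)
  if (!is.null(frame_dim)) p <- clip_point(p, frame_dim)
  attr(p, "valid") <- TRUE
  p
}

#' Nostril box for respiration readout
#'
#' Centered on the nose tip; width is 90% of the horizontal mouth width
#' `W2 = |mouth_right.x - mouth_left.x|` and height is 60% of the vertical
#' distance `H2` from the nose tip down to the mouth midpoint.
#'
#' @inheritParams locate_bt_point
#' @return numeric `c(x, y, w, h)` with `attr(, "valid")`; invalid when the
#'   mouth corners coincide horizontally or the mouth midpoint is not below
#'   the nose tip.
#' @export
locate_rr_box <- function(lm, frame_dim = NULL) {
  w2 <- abs(lm$mouth_right[1] - lm$mouth_left[1])
  mouth_mid_y <- (lm$mouth_left[2] + lm$mouth_right[2]) / 2
  h2 <- mouth_mid_y - lm$nose_tip[2]
  w <- 0.9 * w2
  h <- 0.6 * h2
  if (w2 == 0 || h2 <= 0) {
    r <- c(lm$nose_tip - c(w, h) / 2, w, h)
    attr(r, "valid") <- FALSE
    return(r)
  }
  r <- clip_rect(c(lm$nose_tip[1] - w / 2, lm$nose_tip[2] - h / 2, w, h),
                 frame_dim)
  attr(r, "valid") <- r[3] * r[4] >= 4
  r
}

#' Forehead box for heart-rate readout
#'
#' Centered on the body-temperature point; its height is 0.4 of the face-box
#' height and its width 0.5 of the face-box width. The forehead is preferred
#' over the whole face because it stays visible when a face mask is worn.
#'
#' @param lm a `landmark_frame`.
#' @param bt the point from [locate_bt_point()] on the same frame.
#' @param frame_dim optional `c(w, h)` frame size for clipping.
#' @return numeric `c(x, y, w, h)` with `attr(, "valid")`.
#' @export
locate_hr_box <- function(lm, bt = locate_bt_point(lm, frame_dim),
                          frame_dim = NULL) {
  w <- 0.5 * lm$box[3]
  h <- 0.4 * lm$box[4]
  r <- c(bt[1] - w / 2, bt[2] - h / 2, w, h)
  if (isFALSE(attr(bt, "valid")) || w <= 0 || h <= 0) {
    attr(r, "valid") <- FALSE
    return(r)
  }
  r <- clip_rect(r, frame_dim)
  attr(r, "valid") <- r[3] * r[4] >= 4
  r
}

#' The three regions of interest for one frame
#'
#' Bundles the temperature point, nostril box and forehead box located from
#' one frame's landmarks, with per-ROI validity flags.
#'
#' @inheritParams locate_bt_point
#' @return An object of class `roi_set` with fields `bt_point`, `rr_box`,
#'   `hr_box`, `frame_index`, `valid` (named logical vector).
#' @export
locate_rois <- function(lm, frame_dim = NULL) {
  bt <- locate_bt_point(lm, frame_dim)
  rr <- locate_rr_box(lm, frame_dim)
  hr <- locate_hr_box(lm, bt, frame_dim)
  structure(list(bt_point = bt, rr_box = rr, hr_box = hr,
                 frame_index = lm$frame_index,
                 valid = c(bt = isTRUE(attr(bt, "valid")),
                           rr = isTRUE(attr(rr, "valid")),
                           hr = isTRUE(attr(hr, "valid")))),
            class = "roi_set")
}

#' Horizontal head-deflection ratio
#'
#' Measures how far the subject has turned away from the camera:
#' `|T_x - Face_x| / Face_width`, where `T_x` is the eye-midpoint
#' x-coordinate and `Face_x` the face-box centre x. The ratio is 0 for a
#' frontal face and grows as the head turns; only horizontal turns are
#' considered.
#'
#' @param lm a `landmark_frame`.
#' @return non-negative ratio; `NA_real_` if the face box has zero width.
#' @export
face_deflection <- function(lm) {
  fw <- lm$box[3]
  if (fw <= 0) return(NA_real_)
  face_x <- lm$box[1] + fw / 2
  abs(eye_mid(lm)[1] - face_x) / fw
}

#' Head-deflection gate
#'
#' Frames whose deflection ratio reaches the threshold are treated as
#' non-frontal and excluded from ROI extraction. The default threshold is
#' 0.17 and the comparison is inclusive, so a ratio of exactly 0.17 rejects
#' the frame.
#'
#' @param d deflection ratio from [face_deflection()].
#' @param threshold rejection boundary (default 0.17).
#' @return logical; `TRUE` when the frame must be discarded. `NA` input
#'   (degenerate box) is treated as deflected.
#' @export
is_deflected <- function(d, threshold = 0.17) {
  ifelse(is.na(d), TRUE, d >= threshold)
}

#' Normalized mean error of landmark predictions
#'
#' Mean Euclidean displacement between predicted and ground-truth landmark
#' points, normalized by the face-box size `d = sqrt(W * H)`.
#'
#' @param predicted,truth lists (or N x 2 matrices) of 2-D points, equal
#'   length `N >= 1`.
#' @param box numeric `c(x, y, w, h)` face box supplying the normalization.
#' @return non-negative scalar; 0 iff every prediction coincides with truth.
#' @export
nme <- function(predicted, truth, box) {
  to_mat <- function(p) {
    if (is.matrix(p)) p else do.call(rbind, p)
  }
  pm <- to_mat(predicted); tm <- to_mat(truth)
  if (nrow(pm) == 0) stop("empty landmark list", call. = FALSE)
  if (!all(dim(pm) == dim(tm)))
    stop("predicted and truth must have the same length", call. = FALSE)
  d <- sqrt(box[3] * box[4])
  if (!is.finite(d) || d <= 0) stop("degenerate face box", call. = FALSE)
  mean(sqrt(rowSums((pm - tm)^2))) / d
}

# ---- landmark sidecar file ------------------------------------------------

lm_cols <- c("frame_index", "subject_id", "box_x", "box_y", "box_w", "box_h",
             "left_eye_x", "left_eye_y", "right_eye_x", "right_eye_y",
             "nose_x", "nose_y", "mouth_left_x", "mouth_left_y",
             "mouth_right_x", "mouth_right_y", "confidence")

#' Read a landmark sidecar file
#'
#' The sidecar is a plain CSV with one row per detected face per frame and
#' columns `frame_index, subject_id, box_x, box_y, box_w, box_h,
#' left_eye_x/y, right_eye_x/y, nose_x/y, mouth_left_x/y, mouth_right_x/y,
#' confidence`.
#'
#' @param path CSV file path.
#' @return list of `landmark_frame` objects, ordered as in the file.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(lm_cols, names(df))
  if (length(missing) > 0)
    stop("landmark file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    landmark_frame(r$frame_index,
                   c(r$box_x, r$box_y, r$box_w, r$box_h),
                   c(r$left_eye_x, r$left_eye_y),
                   c(r$right_eye_x, r$right_eye_y),
                   c(r$nose_x, r$nose_y),
                   c(r$mouth_left_x, r$mouth_left_y),
                   c(r$mouth_right_x, r$mouth_right_y),
                   confidence = r$confidence,
                   subject_id = as.character(r$subject_id))
  })
}

#' Write a landmark sidecar file
#'
#' @param lms list of `landmark_frame` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lms, path) {
  rows <- lapply(lms, function(l) {
    data.frame(frame_index = l$frame_index, subject_id = l$subject_id,
               box_x = l$box[1], box_y = l$box[2], box_w = l$box[3],
               box_h = l$box[4],
               left_eye_x = l$left_eye[1], left_eye_y = l$left_eye[2],
               right_eye_x = l$right_eye[1], right_eye_y = l$right_eye[2],
               nose_x = l$nose_tip[1], nose_y = l$nose_tip[2],
               mouth_left_x = l$mouth_left[1], mouth_left_y = l$mouth_left[2],
               mouth_right_x = l$mouth_right[1],
               mouth_right_y = l$mouth_right[2],
               confidence = l$confidence)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
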