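test_that("forehead point sits H1/3 above the eye midpoint", {
  # level eyes
  lm <- make_lm(box = c(100, 100, 440, 300),
                left_eye = c(300, 160), right_eye = c(340, 160))
  expect_equal(unclass(locate_bt_point(lm))[1:2], c(320, 140))
  # coincident eyes degenerate to the same midpoint rule
  lm2 <- make_lm(box = c(100, 100, 440, 300),
                 left_eye = c(320, 160), right_eye = c(320, 160))
  expect_equal(unclass(locate_bt_point(lm2))[1:2], c(320, 140))
  # tilted eyes: the rule uses the midpoint, (320, 160) here
  lm3 <- make_lm(box = c(100, 100, 440, 300),
                 left_eye = c(300, 150), right_eye = c(340, 170))
  expect_equal(unclass(locate_bt_point(lm3))[1:2], c(320, 160 - 60 / 3))
})

test_that("degenerate box (eye midpoint above box top) flags the point invalid", {
  lm <- make_lm(box = c(100, 200, 440, 300),
                left_eye = c(300, 150), right_eye = c(340, 150))
  p <- locate_bt_point(lm)
  expect_false(attr(p, "valid"))
})

test_that("nostril box is 0.9 mouth-width by 0.6 nose-to-mouth, centred on the nose", {
  lm <- make_lm(nose_tip = c(320, 200),
                mouth_left = c(300, 240), mouth_right = c(340, 240))
  r <- locate_rr_box(lm)
  expect_equal(unclass(r)[1:4], c(320 - 18, 200 - 12, 36, 24))
  expect_true(attr(r, "valid"))

  lm2 <- make_lm(nose_tip = c(100, 100),
                 mouth_left = c(80, 130), mouth_right = c(140, 130))
  r2 <- locate_rr_box(lm2)
  expect_equal(unclass(r2)[3:4], c(54, 18))

  # coincident mouth corners: zero width, invalid
  lm3 <- make_lm(mouth_left = c(320, 265), mouth_right = c(320, 265))
  expect_false(attr(locate_rr_box(lm3), "valid"))
})

test_that("forehead box is half the face width by 0.4 of its height, centred on the BT point", {
  lm <- make_lm(box = c(220, 100, 200, 300))
  bt <- c(320, 140)
  r <- locate_hr_box(lm, bt)
  expect_equal(unclass(r)[1:4], c(270, 80, 100, 120))
  # box sized like the thermal grid: fractional extents are kept on the box
  lm2 <- make_lm(box = c(0, 0, 256, 192),
                 left_eye = c(100, 60), right_eye = c(160, 60),
                 nose_tip = c(128, 100),
                 mouth_left = c(110, 130), mouth_right = c(146, 130))
  r2 <- locate_hr_box(lm2, c(128, 40))
  expect_equal(r2[3] * r2[4], 128 * 76.8)
})

test_that("ROI shapes translate rigidly with the landmark set", {
  set.seed(11)
  for (k in 1:20) {
    lm <- random_lm()
    dx <- runif(1, -40, 40); dy <- runif(1, -40, 40)
    sh <- function(p) p + c(dx, dy)
    lm2 <- make_lm(box = lm$box + c(dx, dy, 0, 0),
                   left_eye = sh(lm$left_eye), right_eye = sh(lm$right_eye),
                   nose_tip = sh(lm$nose_tip),
                   mouth_left = sh(lm$mouth_left),
                   mouth_right = sh(lm$mouth_right))
    expect_equal(unclass(locate_bt_point(lm2))[1:2],
                 unclass(locate_bt_point(lm))[1:2] + c(dx, dy),
                 tolerance = 1e-12)
    expect_equal(unclass(locate_rr_box(lm2))[1:4],
                 unclass(locate_rr_box(lm))[1:4] + c(dx, dy, 0, 0),
                 tolerance = 1e-12)
    expect_equal(unclass(locate_hr_box(lm2))[1:4],
                 unclass(locate_hr_box(lm))[1:4] + c(dx, dy, 0, 0),
                 tolerance = 1e-12)
  }
})

test_that("ROI rules match an independent straight-from-definition oracle", {
  # oracle coded directly from the geometric definitions, no shared helpers
  oracle <- function(lm) {
    em <- (lm$left_eye + lm$right_eye) / 2
    h1 <- em[2] - lm$box[2]
    bt <- c(mean(c(lm$left_eye[1], lm$right_eye[1])), em[2] - h1 / 3)
    w2 <- abs(lm$mouth_right[1] - lm$mouth_left[1])
    h2 <- (lm$mouth_left[2] + lm$mouth_right[2]) / 2 - lm$nose_tip[2]
    rr <- c(lm$nose_tip[1] - 0.9 * w2 / 2, lm$nose_tip[2] - 0.6 * h2 / 2,
            0.9 * w2, 0.6 * h2)
    hr <- c(bt[1] - 0.5 * lm$box[3] / 2, bt[2] - 0.4 * lm$box[4] / 2,
            0.5 * lm$box[3], 0.4 * lm$box[4])
    list(bt = bt, rr = rr, hr = hr)
  }
  set.seed(21)
  for (k in 1:100) {
    lm <- random_lm()
    o <- oracle(lm)
    expect_equal(unclass(locate_bt_point(lm))[1:2], o$bt, tolerance = 1e-12)
    expect_equal(unclass(locate_rr_box(lm))[1:4], o$rr, tolerance = 1e-12)
    expect_equal(unclass(locate_hr_box(lm))[1:4], o$hr, tolerance = 1e-12)
  }
})

test_that("deflection ratio matches the worked examples and scales out", {
  # symmetric eyes: zero deflection
  expect_equal(face_deflection(make_lm()), 0)
  # box centre 320, width 200, eye midpoint 354: ratio 0.17
  lm <- make_lm(box = c(220, 100, 200, 280),
                left_eye = c(344, 180), right_eye = c(364, 180))
  expect_equal(face_deflection(lm), 0.17)
  # box centre 100, width 50, midpoint 110: ratio 0.2
  lm2 <- make_lm(box = c(75, 100, 50, 100),
                 left_eye = c(105, 120), right_eye = c(115, 120))
  expect_equal(face_deflection(lm2), 0.2)
  # invariant under uniform coordinate scaling
  set.seed(31)
  for (k in 1:20) {
    lm <- random_lm()
    s <- runif(1, 0.2, 5)
    lms <- make_lm(box = lm$box * s,
                   left_eye = lm$left_eye * s, right_eye = lm$right_eye * s,
                   nose_tip = lm$nose_tip * s,
                   mouth_left = lm$mouth_left * s,
                   mouth_right = lm$mouth_right * s)
    expect_equal(face_deflection(lms), face_deflection(lm),
                 tolerance = 1e-12)
  }
})

test_that("deflection gate is inclusive at the threshold", {
  expect_false(is_deflected(0))
  expect_true(is_deflected(0.17))
  expect_true(is_deflected(0.30))
  expect_true(is_deflected(NA_real_))  # degenerate frame treated as gated
})

test_that("landmark NME normalizes displacement by face-box size", {
  pts <- list(c(10, 10), c(20, 10), c(15, 15), c(12, 20), c(18, 20))
  expect_equal(nme(pts, pts, c(0, 0, 100, 100)), 0)
  expect_equal(nme(list(c(3, 4)), list(c(0, 0)), c(0, 0, 100, 100)), 0.05)
  # brute-force sum oracle on random offsets
  set.seed(41)
  truth <- lapply(1:5, function(i) runif(2, 0, 200))
  pred <- lapply(truth, function(p) p + rnorm(2, sd = 4))
  box <- c(0, 0, 150, 90)
  acc <- 0
  for (i in 1:5) {
    dd <- pred[[i]] - truth[[i]]
    acc <- acc + sqrt(dd[1]^2 + dd[2]^2)
  }
  expect_equal(nme(pred, truth, box), acc / 5 / sqrt(150 * 90),
               tolerance = 1e-12)
  # swapping x and y leaves the metric unchanged for a square box
  swap <- function(l) lapply(l, rev)
  expect_equal(nme(swap(pred), swap(truth), c(0, 0, 120, 120)),
               nme(pred, truth, c(0, 0, 120, 120)), tolerance = 1e-12)
  expect_error(nme(pred[1:3], truth, box), "same length")
})

test_that("landmark sidecar files round-trip", {
  lms <- list(make_lm(0), make_lm(1, subject_id = "s2"),
              make_lm(2, left_eye = c(281.25, 180.5)))
  path <- file.path(tempdir(), "lms.csv")
  write_landmarks(lms, path)
  back <- read_landmarks(path)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$box, lms[[i]]$box)
    expect_equal(back[[i]]$left_eye, lms[[i]]$left_eye)
    expect_equal(back[[i]]$subject_id, lms[[i]]$subject_id)
  }
})
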