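# shared constructors for synthetic landmark geometry and small signals

# frontal face in a 640x480 frame; override any landmark or the box
make_lm <- function(frame_index = 0,
                    box = c(220, 100, 200, 280),
                    left_eye = c(280, 180), right_eye = c(360, 180),
                    nose_tip = c(320, 230),
                    mouth_left = c(290, 265), mouth_right = c(350, 265),
                    confidence = 0.99, subject_id = "s1") {
  landmark_frame(frame_index, box, left_eye, right_eye, nose_tip,
                 mouth_left, mouth_right, confidence, subject_id)
}

# random-but-plausible landmark frame for oracle-equivalence sweeps
random_lm <- function() {
  x0 <- runif(1, 50, 300); y0 <- runif(1, 30, 150)
  w <- runif(1, 80, 250); h <- runif(1, 100, 300)
  ex <- x0 + w * runif(2, 0.2, 0.8)
  ey <- y0 + h * runif(2, 0.2, 0.4)
  nose <- c(x0 + w * runif(1, 0.3, 0.7), y0 + h * runif(1, 0.45, 0.6))
  my <- nose[2] + h * runif(1, 0.05, 0.2)
  mx <- nose[1] + c(-1, 1) * w * runif(2, 0.05, 0.25)
  make_lm(box = c(x0, y0, w, h),
          left_eye = c(ex[1], ey[1]), right_eye = c(ex[2], ey[2]),
          nose_tip = nose,
          mouth_left = c(mx[1], my), mouth_right = c(mx[2], my))
}

# sinusoid as a vital_ts
tone <- function(freq_hz, duration_s = 15, fs = 25, amp = 1, phase = 0,
                 t0 = 0) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  time_series(amp * sin(2 * pi * freq_hz * t + phase), fs, t0 = t0)
}
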