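const_frame <- function(vals, h = 40, w = 60) {
  fr <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) fr[, , ch] <- vals[ch]
  fr
}

test_that("channel means over a constant image reproduce the constants", {
  frames <- replicate(10, const_frame(c(10, 20, 30)), simplify = FALSE)
  rois <- replicate(10, c(5, 5, 20, 20), simplify = FALSE)
  out <- rgb_roi_means(frames, rois, fs = 25)
  expect_equal(out$red$values, rep(10, 10))
  expect_equal(out$green$values, rep(20, 10))
  expect_equal(out$blue$values, rep(30, 10))
})

test_that("an even checkerboard averages to the midpoint gray", {
  fr <- array(0, dim = c(40, 40, 3))
  fr[, , 1] <- outer(1:40, 1:40, function(i, j) ((i + j) %% 2) * 255)
  out <- rgb_roi_means(list(fr), list(c(0, 0, 40, 40)), fs = 25)
  expect_equal(out$red$values, 127.5)
})

test_that("ROI means are invariant to pixel permutation inside the ROI", {
  set.seed(8)
  base <- array(runif(30 * 30 * 3, 0, 255), dim = c(30, 30, 3))
  perm <- base
  for (ch in 1:3) {
    v <- as.vector(base[6:25, 6:25, ch])
    perm[6:25, 6:25, ch] <- matrix(sample(v), 20, 20)
  }
  roi <- list(c(5, 5, 20, 20))
  expect_equal(rgb_roi_means(list(base), roi, 25)$green$values,
               rgb_roi_means(list(perm), roi, 25)$green$values,
               tolerance = 1e-12)
})

test_that("short ROI gaps are interpolated, long ones split the trace", {
  frames <- replicate(50, const_frame(c(10, 20, 30)), simplify = FALSE)
  rois <- replicate(50, c(5, 5, 20, 20), simplify = FALSE)
  rois[21:25] <- list(NULL)            # 0.2 s gap at fs 25: bridged
  out <- rgb_roi_means(frames, rois, fs = 25)
  expect_false(anyNA(out$red$values))
  expect_equal(out$red$values[22], 10)  # interpolation between equal values
  rois[31:45] <- list(NULL)            # 0.6 s gap: left open
  out2 <- rgb_roi_means(frames, rois, fs = 25)
  expect_true(anyNA(out2$red$values))
  segs <- fill_gaps(out2$red)
  expect_length(segs, 2)
  expect_equal(segs[[2]]$t0, 45 / 25)
  expect_error(rgb_roi_means(frames, replicate(50, NULL), fs = 25),
               "no valid frames")
})

test_that("CLAHE expands low-contrast input and leaves uniform input alone", {
  uni <- matrix(128, 64, 64)
  expect_equal(clahe_enhance(uni), uni)
  # two-level image occupying 1/255 of the range: levels pushed apart.
  # With the default clip limit the reference implementation separates the
  # two levels to ~4 gray values (an ~8x contrast gain on the 0.5-gray
  # input spread); the clip limit caps further amplification.
  set.seed(9)
  two <- matrix(sample(c(100, 101), 64 * 64, replace = TRUE), 64, 64)
  out <- clahe_enhance(two)
  expect_equal(dim(out), dim(two))
  lv <- tapply(as.vector(out), as.vector(two), mean)
  expect_gt(abs(lv["101"] - lv["100"]), 3)
  expect_gt(stats::sd(out), 3 * stats::sd(two))
  expect_error(clahe_enhance(array(0, c(4, 4, 2))), "matrix")
})

test_that("CLAHE amplifies the respiratory modulation of rendered thermal frames", {
  # weak-contrast scenario: a hot spot pins the rendering range, squeezing
  # the nostril levels into a narrow band that CLAHE then spreads out
  set.seed(10)
  n <- 250; fs <- 25
  t <- (0:(n - 1)) / fs
  resp <- 0.1 * sin(2 * pi * 0.25 * t)  # weak swing, degrees C
  frames <- lapply(seq_len(n), function(i) {
    fr <- matrix(31 + rnorm(48 * 64, sd = 0.05), 48, 64)
    fr[20:30, 25:40] <- 33 + resp[i] + rnorm(11 * 16, sd = 0.05)
    fr[2:8, 2:8] <- 45 + rnorm(49, sd = 0.05)
    fr
  })
  rendered <- render_thermal(frames, fs = fs, window_s = 10)
  enhanced <- lapply(rendered, clahe_enhance)
  roi <- replicate(n, c(24, 19, 16, 11), simplify = FALSE)
  raw_tr <- thermal_roi_mean(rendered, roi, fs)
  enh_tr <- thermal_roi_mean(enhanced, roi, fs)
  amp <- function(x) diff(range(bandpass(x, 0.15, 0.5,
                                         guard_periods = 1.5)$values))
  expect_gte(amp(enh_tr), amp(raw_tr))
  expect_gt(amp(enh_tr), 0)
})

test_that("nostril trace carries the injected frequency and not elsewhere", {
  set.seed(12)
  n <- 375; fs <- 25
  t <- (0:(n - 1)) / fs
  frames <- lapply(seq_len(n), function(i) {
    fr <- matrix(28 + rnorm(48 * 64, sd = 0.05), 48, 64)
    fr[20:30, 25:40] <- 33 + 0.3 * sin(2 * pi * 0.25 * t[i]) +
      rnorm(11 * 16, sd = 0.05)
    fr
  })
  # constant frames give a constant series
  cst <- thermal_roi_mean(replicate(5, matrix(30, 8, 8), simplify = FALSE),
                          replicate(5, c(0, 0, 8, 8), simplify = FALSE), 25)
  expect_equal(cst$values, rep(30, 5))
  inside <- thermal_roi_mean(frames,
                             replicate(n, c(24, 19, 16, 11),
                                       simplify = FALSE), fs)
  spec_peak <- function(x) {
    v <- x$values - mean(x$values)
    p <- Mod(stats::fft(v))^2
    f <- (seq_along(v) - 1) * x$fs / length(v)
    f[f > 0 & f <= x$fs / 2][which.max(p[f > 0 & f <= x$fs / 2])]
  }
  expect_lt(abs(spec_peak(inside) - 0.25), 0.02)  # one bin at 15 s
  # negative control: ROI away from the nostril sees no 0.25 Hz peak
  outside <- thermal_roi_mean(frames,
                              replicate(n, c(2, 2, 16, 11),
                                        simplify = FALSE), fs)
  expect_lt(band_power_fraction(outside, 0.2, 0.3), 0.2)
})

test_that("forehead temperature lookup is an exact matrix read", {
  allc <- matrix(36.5, 192, 256)
  expect_equal(bt_lookup(allc, c(128, 96)), 36.5)
  m <- matrix(30, 192, 256)
  m[11, 21] <- 37.1  # row 11 = y 10, col 21 = x 20 (0-based coords)
  expect_equal(bt_lookup(m, c(20, 10)), 37.1)
  expect_equal(bt_lookup(allc, c(128, 96), offset = 0.4), 36.9)
  expect_error(bt_lookup(allc, c(300, 10)), "outside")
})

test_that("thermal CSV and binary stream dialects round-trip", {
  set.seed(13)
  frames <- replicate(4, matrix(round(runif(24 * 32, 20, 40), 2), 24, 32),
                      simplify = FALSE)
  d <- file.path(tempdir(), "thermal_csv")
  write_thermal_csv(frames, d)
  back <- read_thermal_csv(d, fs = 25)
  expect_equal(back$frames, frames, tolerance = 1e-9)

  bin <- file.path(tempdir(), "thermal.bin")
  write_thermal_bin(frames, bin)
  back2 <- read_thermal_bin(bin, fs = 25, frame_dim = c(32, 24))
  expect_length(back2$frames, 4)
  for (i in 1:4)
    expect_lt(max(abs(back2$frames[[i]] - frames[[i]])), 0.005 + 1e-12)
})

test_that("RGB PNG frame directories round-trip", {
  set.seed(14)
  frames <- replicate(3, array(sample(0:255, 20 * 24 * 3, TRUE),
                               dim = c(20, 24, 3)), simplify = FALSE)
  d <- file.path(tempdir(), "rgbdir")
  write_rgb_frames(frames, d)
  back <- read_rgb_frames(d, fs = 25)
  expect_length(back$frames, 3)
  for (i in 1:3)
    expect_equal(back$frames[[i]], frames[[i]], tolerance = 1e-9)
})
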