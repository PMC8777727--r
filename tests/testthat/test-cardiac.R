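test_that("cardiac band-pass keeps the passband and kills DC and drift", {
  x <- tone(1.2)
  y <- bandpass(x, 0.8, 2)
  expect_gte(stats::sd(y$values) / stats::sd(x$values), 0.9)

  # 0.1 Hz tone: compare against the analytic filter magnitude response
  # (forward-backward filtering squares the single-pass gain)
  bf <- signal::butter(3, c(0.8, 2) / 12.5, type = "pass")
  z <- exp(-1i * 2 * pi * 0.1 / 25 * seq(0, length(bf$b) - 1))
  gain2 <- Mod(sum(bf$b * z) / sum(bf$a * z))^2
  x2 <- tone(0.1, duration_s = 40)
  y2 <- bandpass(x2, 0.8, 2)
  mid <- 250:750  # away from filter edges
  measured <- stats::sd(y2$values[mid]) / stats::sd(x2$values[mid])
  expect_lte(measured, 0.1)
  expect_equal(measured, gain2, tolerance = 0.5)  # within 50% of the oracle

  dc <- time_series(rep(5, 375), 25)
  expect_lt(abs(mean(bandpass(dc, 0.8, 2)$values)), 1e-6 * 5)

  expect_error(bandpass(tone(1.2, duration_s = 5), 0.8, 2), "too short")
})

test_that("normalization gives exact zero mean and unit variance", {
  n <- ts_normalize(time_series(c(1, 2, 3), 25))
  expect_equal(mean(n$values), 0, tolerance = 1e-9)
  expect_equal(stats::var(n$values), 1, tolerance = 1e-9)
  expect_equal(n$values, (c(1, 2, 3) - 2) / 1)
  # idempotence
  expect_equal(ts_normalize(n)$values, n$values, tolerance = 1e-9)
  set.seed(22)
  g <- ts_normalize(time_series(rnorm(1000, 5, 4), 25))
  expect_equal(mean(g$values), 0, tolerance = 1e-9)
  expect_equal(stats::var(g$values), 1, tolerance = 1e-9)
  expect_error(ts_normalize(time_series(rep(2, 10), 25)), "constant")
})

test_that("the second component is returned unless it is not pulse-like", {
  set.seed(23)
  noise <- function() time_series(rnorm(375), 25)
  clean <- tone(1.2)
  # second component already pulse-like: returned, no flag
  got <- select_rbvp(list(noise(), clean, noise()))
  expect_identical(got$values, clean$values)
  expect_equal(attr(got, "component"), 2L)
  # broadband second component: guard substitutes the tonal source, flagged
  got2 <- select_rbvp(list(clean, noise(), noise()))
  expect_identical(got2$values, clean$values)
  expect_equal(attr(got2, "component"), 1L)
  expect_true(attr(got2, "substituted"))
  # guard off: the second component is taken regardless
  got2b <- select_rbvp(list(clean, noise(), noise()), fallback = FALSE)
  expect_equal(attr(got2b, "component"), 2L)
  # three pure in-band tones: all equally tonal, second kept, no flag
  got3 <- select_rbvp(list(tone(0.9), tone(1.2), tone(1.8)))
  expect_equal(attr(got3, "component"), 2L)
  expect_false(attr(got3, "substituted"))
})

test_that("peak detection matches counts and spacing of a slow oscillation", {
  x <- tone(1, duration_s = 15.2)
  pk <- detect_peaks(x, min_separation_s = 0.5)
  expect_equal(length(pk), 15)
  expect_equal(diff(pk), rep(1, 14), tolerance = 0.02)
  flat <- time_series(rep(1, 300), 25)
  expect_true(isTRUE(attr(detect_peaks(flat, 0.5), "insufficient")))
})

test_that("peak detection equals a brute-force oracle under identical rules", {
  # independent re-statement of the rules: local maxima, walk-out prominence,
  # greedy height-ordered refractory pruning
  oracle_peaks <- function(v, fs, min_sep_s, prom_frac = 0.3) {
    cand <- integer(0)
    for (i in 2:(length(v) - 1))
      if (v[i] > v[i - 1] && v[i] >= v[i + 1] &&
          !(i > 2 && v[i] == v[i - 1])) cand <- c(cand, i)
    prom <- vapply(cand, function(i) {
      lmin <- min(v); j <- i - 1
      while (j >= 1) {
        if (v[j] >= v[i]) { lmin <- min(v[j:(i - 1)]); break }
        j <- j - 1
      }
      if (j == 0) lmin <- min(v[1:(i - 1)])
      rmin <- min(v); j <- i + 1
      while (j <= length(v)) {
        if (v[j] >= v[i]) { rmin <- min(v[(i + 1):j]); break }
        j <- j + 1
      }
      if (j == length(v) + 1) rmin <- min(v[(i + 1):length(v)])
      v[i] - max(lmin, rmin)
    }, numeric(1))
    cand <- cand[prom >= prom_frac * stats::sd(v)]
    kept <- integer(0)
    for (i in cand[order(v[cand], decreasing = TRUE)])
      if (all(abs(kept - i) >= min_sep_s * fs)) kept <- c(kept, i)
    (sort(kept) - 1) / fs
  }
  set.seed(24)
  for (k in 1:10) {
    t <- (0:374) / 25
    v <- sin(2 * pi * runif(1, 0.9, 1.8) * t) +
      rnorm(375, sd = 0.32)  # ~10 dB SNR
    x <- time_series(v, 25)
    expect_equal(as.numeric(detect_peaks(x, 0.5)),
                 oracle_peaks(v, 25, 0.5), tolerance = 1e-12)
  }
})

test_that("rate follows 60 over the mean peak interval", {
  expect_equal(rate_from_peaks(0:14), 60)
  expect_equal(rate_from_peaks(c(0, 0.75, 1.5)), 80)
  set.seed(25)
  pk <- cumsum(runif(12, 0.6, 1.1))
  expect_equal(rate_from_peaks(pk), 60 / mean(diff(pk)))
  expect_error(rate_from_peaks(3), "two peaks")
})

test_that("the full cardiac chain recovers fixture heart rate", {
  ch <- fixture_channel_series(fixture_spec(hr_bpm = 72, seed = 1))
  res <- estimate_hr(ch$r, ch$g, ch$b)
  expect_true(res$valid)
  expect_equal(res$hr_bpm, 72, tolerance = 3 / 72)
  expect_true(all(diff(res$peak_times) > 0))

  # band-edge rate still yields an in-band result
  ch48 <- fixture_channel_series(fixture_spec(hr_bpm = 48, seed = 2))
  res48 <- estimate_hr(ch48$r, ch48$g, ch48$b)
  expect_gte(res48$hr_bpm, 48)
  expect_lte(res48$hr_bpm, 120)

  # pure-noise channels must fail the quality screen
  set.seed(26)
  mk <- function() time_series(rnorm(375), 25)
  resn <- estimate_hr(mk(), mk(), mk())
  expect_false(resn$valid)
})

test_that("the cardiac chain is deterministic for fixed input", {
  ch <- fixture_channel_series(fixture_spec(hr_bpm = 85, seed = 3))
  a <- estimate_hr(ch$r, ch$g, ch$b)
  b <- estimate_hr(ch$r, ch$g, ch$b)
  expect_identical(a$hr_bpm, b$hr_bpm)
  expect_identical(a$waveform$values, b$waveform$values)
  expect_identical(a$sqi, b$sqi)
})

test_that("windows shorter than 15 s are rejected with a reason", {
  short <- tone(1.2, duration_s = 10)
  res <- estimate_hr(short, short, short)
  expect_false(res$valid)
  expect_match(res$reason, "15 s")
})
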