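# Pitch tracking and contour statistics.

test_that("tracker handles known signals: pure tone, silence, FM", {
  ct <- track_pitch(tone(220))
  expect_gt(mean(!is.na(ct$f0)), 0.9)
  expect_lt(abs(median(ct$f0, na.rm = TRUE) - 220), 1)

  expect_true(all(is.na(track_pitch(waveform(numeric(FS), FS))$f0)))

  # 10 Hz FM of +/-1 st: contour oscillates with period ~4 frames,
  # median near the carrier
  cf <- track_pitch(fm_tone(220, 10, 1, dur = 2))
  expect_lt(abs(median(cf$f0, na.rm = TRUE) - 220), 220 * 0.02)
  st <- 12 * log2(cf$f0[!is.na(cf$f0)])
  d <- diff(st)
  sign_changes <- sum(diff(sign(d[d != 0])) != 0)
  # ~10 cycles/s * 2 s * 2 extrema each = ~40 reversals
  expect_gt(sign_changes, 25)

  expect_error(track_pitch(waveform(numeric(0), FS)), "empty")
  expect_error(track_pitch(tone(220), search_range = c(60, 44100)), "rate/2")
})

test_that("lowpass_contour matches its frequency-response design", {
  # constant contour unchanged
  cc <- pitch_contour(rep(150, 80))
  expect_equal(lowpass_contour(cc, 10)$f0, cc$f0, tolerance = 1e-10)

  # 12 Hz FM is in the stopband of a 10 Hz low-pass
  c12 <- fm_contour(200, 12, 1)
  lp <- lowpass_contour(c12, 10)
  amp_ratio <- sd(12 * log2(lp$f0)) / sd(12 * log2(c12$f0))
  expect_lt(amp_ratio, 0.1)

  # 0.5 Hz drift preserved within 5% by a 1 Hz low-pass
  c05 <- fm_contour(200, 0.5, 2, dur = 4)
  lp2 <- lowpass_contour(c05, 1)
  expect_gt(sd(12 * log2(lp2$f0)) / sd(12 * log2(c05$f0)), 0.95)

  expect_error(lowpass_contour(cc, 25), "Nyquist")
})

test_that("count_inflections counts extrema of the smoothed contour", {
  # monotone rising: none
  expect_equal(count_inflections(pitch_contour(seq(100, 200, length.out = 40)), 10), 0)
  # smooth single-peak contour: exactly one inflection
  tt <- seq(0.0125, 2, by = 0.025)
  bump <- pitch_contour(150 * 2^(2 * exp(-(tt - 1)^2 / (2 * 0.3^2)) / 12))
  expect_equal(count_inflections(bump, 10) * length(tt) * 0.025, 1)
  # 2 Hz sinusoid over 2 s: 4 extrema/s (brute-force count agrees)
  c2 <- fm_contour(200, 2, 1, dur = 2)
  d <- diff(c2$f0)
  d <- d[d != 0]
  brute <- sum(diff(sign(d)) != 0) / 2
  expect_equal(count_inflections(c2, 10), brute, tolerance = 0.15)
  expect_equal(count_inflections(c2, 10), 4, tolerance = 0.15)
  # fewer than 3 voiced frames: undefined, not an error
  expect_true(is.na(count_inflections(pitch_contour(c(100, 110, NA)), 10)))
})

test_that("count_inflections at 1 Hz never exceeds the 10 Hz count", {
  set.seed(7)
  for (i in 1:20) {
    f0 <- 150 * 2^(cumsum(rnorm(80, 0, 0.3)) / 12)
    f0[sample(80, 10)] <- NA
    cc <- pitch_contour(f0)
    if (sum(!is.na(f0)) < 3) next
    expect_lte(count_inflections(cc, 1), count_inflections(cc, 10))
  }
})

test_that("fm_depth isolates the 8-14 Hz band", {
  # constant contour: 0 (no events at all -> NA counts as no tremor here)
  expect_true(is.na(fm_depth(pitch_contour(rep(200, 80)))) ||
                fm_depth(pitch_contour(rep(200, 80))) == 0)
  # in-band 10 Hz FM of +/-1 st recovered within 20%
  expect_equal(fm_depth(fm_contour(200, 10, 1)), 1, tolerance = 0.2)
  # out-of-band 3 Hz FM rejected
  expect_lt(fm_depth(fm_contour(200, 3, 1)), 0.1)
  # transposition invariance
  c10 <- fm_contour(200, 10, 0.5)
  shifted <- pitch_contour(c10$f0 * 2^(5 / 12), step = c10$step)
  expect_equal(fm_depth(c10), fm_depth(shifted), tolerance = 1e-6)
  # band must respect the contour Nyquist
  expect_error(fm_depth(c10, band = c(8, 25)), "Nyquist")
  # no analyzable stretch: undefined marker
  expect_true(is.na(fm_depth(pitch_contour(c(rep(NA, 30), 200, 210, 200)))))
})

test_that("fm_depth bridges short unvoiced gaps but not long ones", {
  c10 <- fm_contour(200, 10, 1, dur = 2)
  gappy <- c10
  gappy$f0[30:35] <- NA # 150 ms gap: bridged
  expect_equal(fm_depth(gappy), fm_depth(c10), tolerance = 0.25)
  short <- pitch_contour(c(c10$f0[1:8], rep(NA, 20), c10$f0[29:36]))
  expect_true(is.na(fm_depth(short))) # both stretches < 0.3 s
})

test_that("pitch_stats follows the documented conventions", {
  # constant contour
  ps <- pitch_stats(pitch_contour(rep(220, 40)))
  expect_equal(ps$iqr_st, 0)
  expect_equal(ps$slope_st_s, 0)
  expect_equal(ps$median_st, 12 * log2(220))
  # octave glide over 1 s: 12 st/s
  glide <- track_pitch(waveform({
    t <- (seq_len(FS) - 1) / FS
    f0 <- 200 * 2^t
    0.5 * sin(2 * pi * cumsum(f0) / FS)
  }, FS))
  expect_equal(pitch_stats(glide)$slope_st_s, 12, tolerance = 0.05)
  # even-count median: midpoint on the Hz scale, then semitones
  ps4 <- pitch_stats(pitch_contour(c(200, 200, 300, 300)))
  expect_equal(ps4$median_st, 12 * log2(250))
  # < 2 voiced frames: undefined markers
  expect_true(is.na(pitch_stats(pitch_contour(c(NA, 200, NA)))$median_st))
})

test_that("contours serialize to CSV", {
  cc <- fm_contour(200, 10, 1)
  cc$f0[5] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_contour_csv(cc, path)
  back <- read.csv(path)
  expect_equal(back$f0_hz, cc$f0)
  expect_false(back$voiced[5])
})
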