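# Spectral and voice-quality descriptors.

frame_spec <- function(x, fs = FS) {
  s <- effortvoice:::stft(x, fs)
  list(freq = s$freq, mag = s$mag[, max(1, ncol(s$mag) %/% 2)])
}

test_that("loudness_stats matches closed forms", {
  # full-scale square wave: 0 dB RMS
  sq <- waveform(rep(c(1, -1), each = 50, times = 500), FS)
  expect_equal(loudness_stats(sq)$rms_db, 0, tolerance = 0.01)
  # doubling amplitude adds 20*log10(2) dB
  w <- tone(220, amp = 0.25)
  w2 <- waveform(w$samples * 2, FS)
  expect_equal(loudness_stats(w2)$rms_db - loudness_stats(w)$rms_db,
               20 * log10(2), tolerance = 0.01)
  # constant-amplitude tone: IQR ~ 0
  expect_lt(loudness_stats(tone(220))$iqr_db, 0.2)
  expect_true(is.na(loudness_stats(waveform(numeric(FS), FS))$rms_db))
})

test_that("harmonic_energy matches the sawtooth closed form", {
  # ideal sawtooth (amplitudes 1/n): proportion above 1.5 f0 is
  # (pi^2/6 - 1) / (pi^2/6); brute-force summation oracle agrees
  brute <- {
    e <- (1 / (1:10000))^2
    sum(e[-1]) / sum(e)
  }
  closed <- (pi^2 / 6 - 1) / (pi^2 / 6)
  expect_equal(brute, closed, tolerance = 1e-4)
  fr <- frame_spec(saw_frame(200, 40, dur = 0.5))
  expect_equal(harmonic_energy(fr$freq, fr$mag, 200), closed, tolerance = 0.03)
  # pure sine: everything below 1.5 f0
  fs2 <- frame_spec(0.5 * sin(2 * pi * 200 * (0:22049) / FS))
  expect_lt(harmonic_energy(fs2$freq, fs2$mag, 200), 0.02)
  # sine at f0 plus equal sine at 2 f0: half the energy above 1.5 f0
  t <- (0:22049) / FS
  fr2 <- frame_spec(sin(2 * pi * 200 * t) + sin(2 * pi * 400 * t))
  expect_equal(harmonic_energy(fr2$freq, fr2$mag, 200), 0.5, tolerance = 0.03)
})

test_that("harmonics_height finds the last detectable harmonic", {
  fr <- frame_spec(saw_frame(200, 10, dur = 0.5))
  expect_equal(harmonics_height(fr$freq, fr$mag, 200), 2000, tolerance = 0.11)
  # pure sine: falls back to f0
  fs2 <- frame_spec(0.5 * sin(2 * pi * 200 * (0:22049) / FS))
  expect_equal(harmonics_height(fs2$freq, fs2$mag, 200), 200)
  # robust to weak broadband noise (-40 dB): individual frames may be
  # fooled by a noise cluster, but the median over frames (the aggregation
  # used in the profile) matches the clean signal
  set.seed(1)
  x <- saw_frame(200, 10, dur = 0.5)
  xn <- x + rnorm(length(x)) * max(abs(x)) * 10^(-40 / 20)
  height_med <- function(sig) {
    s <- effortvoice:::stft(sig, FS)
    median(apply(s$mag[, 5:45], 2, function(m) {
      harmonics_height(s$freq, m, 200)
    }))
  }
  expect_equal(height_med(xn), height_med(x))
})

test_that("spectral_moments handle point masses and mixtures", {
  fs1 <- frame_spec(0.5 * sin(2 * pi * 440 * (0:22049) / FS))
  sm <- spectral_moments(fs1$freq, fs1$mag)
  expect_equal(sm$centroid, 440, tolerance = 0.02)
  expect_equal(sm$q25, 440, tolerance = 0.08)
  t <- (0:22049) / FS
  sm2 <- frame_spec(sin(2 * pi * 100 * t) + sin(2 * pi * 300 * t))
  expect_equal(spectral_moments(sm2$freq, sm2$mag)$centroid, 200,
               tolerance = 0.05)
  # flat spectrum 0-1000 Hz: first quartile at ~250 Hz
  freq <- seq(0, 1000, by = 5)
  expect_equal(spectral_moments(freq, rep(1, length(freq)))$q25, 250,
               tolerance = 0.02)
  expect_true(is.na(spectral_moments(freq, rep(0, length(freq)))$q25))
})

test_that("cpp separates periodic frames from noise", {
  set.seed(2)
  n <- round(0.06 * FS)
  pulse <- as.numeric(seq_len(n) %% round(FS / 150) == 0)
  cpp_pulse <- cpp(pulse, FS)
  cpp_noise <- replicate(20, cpp(rnorm(n), FS))
  expect_gt(cpp_pulse, max(cpp_noise) + 10)
  expect_lt(mean(cpp_noise), 2) # noise CPP near 0 dB
  expect_identical(cpp(pulse, FS), cpp_pulse) # deterministic
  expect_true(is.na(cpp(rep(0.3, n), FS))) # degenerate frame
  expect_error(cpp(rnorm(100), FS), "2 periods")
})

test_that("hnr reflects tonality", {
  n <- round(0.06 * FS)
  t <- (seq_len(n) - 1) / FS
  expect_gt(hnr(sin(2 * pi * 220 * t), FS), 0.95)
  set.seed(3)
  noise_hnr <- replicate(20, hnr(rnorm(n), FS))
  expect_lt(mean(noise_hnr), 0.25)
  # tone + equal-power noise: r ~ SNR/(SNR+1) = 0.5
  set.seed(4)
  sig <- sin(2 * pi * 220 * t)
  mix <- sig + rnorm(n) * sqrt(mean(sig^2))
  expect_equal(hnr(mix, FS), 0.5, tolerance = 0.12)
})

test_that("roughness picks out 30-150 Hz amplitude modulation", {
  t <- (0:(FS - 1)) / FS
  expect_lt(roughness(tone(1000)), 0.05)
  am70 <- waveform(0.5 * (1 + sin(2 * pi * 70 * t)) / 2 * sin(2 * pi * 1000 * t), FS)
  expect_gt(roughness(am70), 0.5)
  am4 <- waveform(0.5 * (1 + sin(2 * pi * 4 * t)) / 2 * sin(2 * pi * 1000 * t), FS)
  expect_lt(roughness(am4), 0.05)
  expect_true(is.na(roughness(tone(1000, dur = 0.3)))) # too short
})

test_that("spectral_novelty marks spectrotemporal change", {
  nov_tone <- spectral_novelty(tone(300))
  t <- (0:(FS / 2 - 1)) / FS
  two <- waveform(c(0.5 * sin(2 * pi * 300 * t), 0.5 * sin(2 * pi * 800 * t)), FS)
  nov_two <- spectral_novelty(two)
  expect_gt(nov_two, nov_tone + 0.005)
  # symmetric kernel: time reversal leaves novelty unchanged
  expect_equal(spectral_novelty(waveform(rev(two$samples), FS)), nov_two,
               tolerance = 1e-6)
  expect_true(is.na(spectral_novelty(waveform(numeric(64), FS))))
})

test_that("formants and vocal tract length recover generator truth", {
  set.seed(6)
  w <- synth_utterance(voice_spec(base_f0 = 120,
                                  formants = c(500, 1500, 2500, 3500)))
  fv <- formants_and_vtl(w)
  expect_equal(unname(fv$formants), c(500, 1500, 2500, 3500),
               tolerance = 0.05)
  # neutral tube: VTL = c / (4 * 500) = 17.5 cm
  expect_equal(fv$vtl_cm, 17.5, tolerance = 0.05)
  # scaling all formants by 1.1 scales VTL by ~1/1.1
  set.seed(6)
  w2 <- synth_utterance(voice_spec(base_f0 = 120,
                                   formants = c(500, 1500, 2500, 3500) * 1.1))
  expect_equal(formants_and_vtl(w2)$vtl_cm / fv$vtl_cm, 1 / 1.1,
               tolerance = 0.05)
})

test_that("descriptors are robust to resampling 44.1 -> 22.05 kHz", {
  set.seed(5)
  w <- synth_utterance(voice_spec(base_f0 = 150)) # band-limited < 8 kHz
  d <- effortvoice:::decimate_fir(w$samples, w$rate, 2)
  p1 <- unlist(acoustic_profile(w))
  p2 <- unlist(acoustic_profile(waveform(d$x, d$fs)))
  # 10% relative, with absolute floors where the descriptor value is near
  # zero and a relative bound is ill-posed (cpp/roughness of a clean
  # synthetic voice are tiny)
  floors <- c(loudness_iqr_db = 0.3, cpp_db = 0.3, roughness_prop = 0.025,
              novelty = 0.01, fm_depth_st = 0.02)
  for (f in profile_fields()) {
    tol <- max(0.1 * abs(p1[[f]]), floors[f], 0, na.rm = TRUE)
    expect_lt(abs(p2[[f]] - p1[[f]]), tol + 1e-12, label = f)
  }
})

test_that("acoustic_profile assembles 19 descriptors with the stated rules", {
  set.seed(8)
  w <- synth_utterance(voice_spec(base_f0 = 180))
  p <- acoustic_profile(w)
  expect_identical(names(p), profile_fields())
  expect_equal(ncol(p), 19)
  # proportions in [0, 1]; harmonics height at or above the median f0
  expect_true(p$harm_energy_prop >= 0 && p$harm_energy_prop <= 1)
  expect_true(p$roughness_prop >= 0 && p$roughness_prop <= 1)
  expect_true(p$hnr >= 0 && p$hnr <= 1)
  expect_gte(p$harm_height_hz, st_to_hz(p$f0_median_st))
  expect_gt(p$vtl_cm, 0)
  # determinism
  expect_identical(acoustic_profile(w), p)
  # doubling amplitude changes only the loudness fields
  w2 <- waveform(w$samples / 2, w$rate)
  p2 <- acoustic_profile(w2)
  expect_equal(p$loudness_db - p2$loudness_db, 20 * log10(2), tolerance = 0.1)
  same <- setdiff(profile_fields(), c("loudness_db", "loudness_iqr_db"))
  for (f in same) expect_equal(p2[[f]], p[[f]], tolerance = 0.05)
  # fully unvoiced input still yields a profile, with NA pitch fields
  set.seed(9)
  pn <- acoustic_profile(waveform(rnorm(FS) * 0.1, FS))
  expect_true(is.na(pn$f0_median_st))
  expect_true(is.na(pn$fm_depth_st))
  expect_false(is.na(pn$loudness_db))
  expect_false(is.na(pn$novelty))
})
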