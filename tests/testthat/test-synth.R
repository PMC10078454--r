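# Voice synthesis and corpus generation.

test_that("sample_speaker draws from sex-specific distributions", {
  cfg <- corpus_config()
  s1 <- with(list(), { set.seed(5); sample_speaker(cfg, "female") })
  s2 <- with(list(), { set.seed(5); sample_speaker(cfg, "female") })
  expect_identical(s1, s2) # same seed, same speaker

  expect_error(sample_speaker(cfg, "robot"), "unknown sex")

  set.seed(9)
  f0_f <- replicate(1000, sample_speaker(cfg, "female")$base_f0)
  f0_m <- replicate(1000, sample_speaker(cfg, "male")$base_f0)
  expect_gt(mean(f0_f), mean(f0_m))
  # Monte-Carlo check against the configured lognormal: mean of log-f0
  # within 2 standard errors of the configured sex mean
  se <- cfg$speaker_sd[["f0_st"]] / sqrt(1000)
  expect_lt(abs(mean(hz_to_st(f0_f)) - hz_to_st(cfg$female_f0)), 2.5 * se)
  expect_lt(abs(mean(hz_to_st(f0_m)) - hz_to_st(cfg$male_f0)), 2.5 * se)
})

test_that("synth_utterance honors its contract", {
  set.seed(3)
  spec <- voice_spec(base_f0 = 220)
  w <- synth_utterance(spec)
  expect_lte(max(abs(w$samples)), 1)
  expect_equal(wav_duration(w),
               sum(spec$syllables$duration) * spec$duration_scale,
               tolerance = 0.03) # within one frame
  # closed loop: tracked median f0 within 3% of the requested f0
  ct <- track_pitch(w)
  expect_lt(abs(median(ct$f0, na.rm = TRUE) - 220) / 220, 0.03)
  # steeper tilt means strictly less energy in the harmonics
  set.seed(4)
  w_steep <- synth_utterance(voice_spec(base_f0 = 150, source_tilt = -18))
  set.seed(4)
  w_flat <- synth_utterance(voice_spec(base_f0 = 150, source_tilt = -6))
  he <- function(w) acoustic_profile(w)$harm_energy_prop
  expect_gt(he(w_flat), he(w_steep))
  # f0 above Nyquist/2 of the configured rate is rejected
  expect_error(synth_utterance(voice_spec(base_f0 = 400), rate = 1200),
               "Nyquist")
})

test_that("voice_spec validates invariants", {
  expect_error(voice_spec(base_f0 = 50)) # below 75 Hz
  expect_error(voice_spec(formants = c(1500, 500, 2500, 3500))) # not ascending
  expect_error(voice_spec(amplitude_db = 3)) # above full scale
  expect_error(voice_spec(duration_scale = 0))
})

test_that("condition_offsets enforces an all-zero baseline", {
  off <- condition_offsets()
  rel <- off[off$condition == "relaxed", -1]
  expect_true(all(rel == 0))
  bad <- as.data.frame(off)
  bad$f0_st[bad$condition == "relaxed"] <- 1
  expect_error(condition_offsets(bad))
  bad2 <- as.data.frame(off)
  bad2$tremor_st[2] <- -0.1
  expect_error(condition_offsets(bad2))
})

test_that("generate_corpus produces the full design with ground truth", {
  sc <- small_corpus()
  meta <- sc$corpus$meta
  expect_equal(nrow(meta), 8 * 4 * 2)
  expect_setequal(levels(meta$condition), conditions())
  expect_equal(anyDuplicated(meta[, c("speaker", "condition", "take")]), 0)
  # relaxed utterances carry zero ground-truth tremor
  expect_true(all(meta$gt_tremor_st[meta$condition == "relaxed"] == 0))
  # ground-truth closure: every calibratable physical parameter is emitted
  expect_true(all(c("gt_f0_hz", "gt_amp_db", "gt_tilt_db_oct",
                    "gt_dur_scale", "gt_tremor_st") %in% names(meta)))
  # determinism: same seed, bit-identical corpus
  corp2 <- generate_corpus(sc$config)
  expect_identical(corp2$meta, meta)
  expect_identical(corp2$audio[[5]]$samples, sc$corpus$audio[[5]]$samples)
})

test_that("realized contrasts scale about linearly with the f0 offset", {
  base_off <- as.data.frame(condition_offsets())
  base_off[, -1] <- 0
  contrast_at <- function(d) {
    off <- base_off
    off$f0_st[off$condition == "pretended"] <- d
    cfg <- corpus_config(n_female = 3, n_male = 3, takes = 2,
                         offsets = condition_offsets(off), seed = 77)
    feats <- corpus_features(generate_corpus(cfg))
    std <- standardize_features(feats, fields = "f0_median_st")
    eff <- estimate_condition_effects(std, fields = "f0_median_st")
    eff$contrast[eff$condition == "pretended"]
  }
  c1 <- contrast_at(1.5)
  c2 <- contrast_at(3.0)
  expect_gt(c2, c1) # monotone
  expect_equal(c2 / c1, 2, tolerance = 0.35) # locally ~linear
})

test_that("calibrate_offsets maps zero targets to zero offsets", {
  targets <- data.frame(
    feature = c("f0_median_st", "fm_depth_st"),
    condition = c("pretended", "real"),
    target = c(0, 0)
  )
  cal <- calibrate_offsets(targets, corpus_config(seed = 1))
  expect_true(cal$converged)
  expect_equal(cal$offsets$f0_st[cal$offsets$condition == "pretended"], 0)
  expect_equal(cal$offsets$tremor_st[cal$offsets$condition == "real"], 0)
})
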