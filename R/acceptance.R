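# End-to-end parameter-recovery analysis: calibrate the generator to the
# published standardized condition contrasts, regenerate a fresh corpus,
# and recover the contrasts through the full pipeline. Used by both the
# acceptance script and the acceptance tests.

#' Published standardized condition contrasts used as calibration targets
#'
#' The study's text reports, for the 33-speaker corpus, standardized
#' (SD-unit) contrasts of each effort condition against relaxed baseline:
#' median pitch +0.25 / +0.44 / +0.72 SD (concealed / real / pretended),
#' duration -0.54 / -0.42 / +0.26 SD, and 8-14 Hz FM depth +0.76 / +0.54
#' SD (concealed / real). These are the generator's calibration targets.
#'
#' @return data.frame with `feature`, `condition`, `target`
#' @export
effort_contrast_targets <- function() {
  data.frame(
    feature = c(rep("f0_median_st", 3), rep("duration_s", 3),
                rep("fm_depth_st", 2)),
    condition = c("concealed", "real", "pretended",
                  "concealed", "real", "pretended",
                  "concealed", "real"),
    target = c(0.25, 0.44, 0.72, -0.54, -0.42, 0.26, 0.76, 0.54)
  )
}

#' End-to-end recovery of the published contrasts on synthetic audio
#'
#' Calibrates the generator's condition offsets to
#' [effort_contrast_targets()] on pilot corpora, regenerates the default
#' 33 x 4 x 3 corpus with a fresh seed, extracts all features, fits the
#' mixed models, and simulates/fits the listener rating model. Everything
#' is recomputed from scratch; runtime is dominated by synthesis and
#' feature extraction (roughly ten minutes on one CPU).
#'
#' Pilot design: several single-take pilot rounds rather than few
#' multi-take ones — the binding uncertainty is the between-panel
#' variability of each feature's standardizing SD, which depends on the
#' number of independent speaker panels, not on takes per speaker.
#'
#' @param seed master integer seed
#' @param pilot_n,pilot_takes,max_iter calibration controls
#' @param n_listeners,ratings_per_listener simulated rating design
#' @return list with `contrasts` (recovered effect estimates), `targets`,
#'   `rating_fit`, `calibration`, and `n` (corpus size)
#' @export
acceptance_recovery <- function(seed = 1, pilot_n = 33, pilot_takes = 1,
                                max_iter = 5, n_listeners = 39,
                                ratings_per_listener = 99) {
  targets <- effort_contrast_targets()
  cfg <- corpus_config(seed = child_seed(seed, "cal"))
  cal <- calibrate_offsets(targets, cfg, pilot_n = pilot_n,
                           pilot_takes = pilot_takes, max_iter = max_iter,
                           seed = child_seed(seed, "cal"))
  final_cfg <- corpus_config(offsets = cal$offsets,
                             seed = child_seed(seed, "final"))
  corp <- generate_corpus(final_cfg)
  feats <- corpus_features(corp)
  std <- standardize_features(feats)
  eff <- estimate_condition_effects(
    std, fields = c("f0_median_st", "duration_s", "fm_depth_st")
  )
  ratings <- simulate_ratings(std, rating_model_spec(),
                              n_listeners = n_listeners,
                              ratings_per_listener = ratings_per_listener,
                              seed = child_seed(seed, "ratings"))
  fit <- fit_rating_model(ratings, std)
  list(contrasts = eff, targets = targets, rating_fit = fit,
       calibration = cal, n = nrow(feats), n_ratings = nrow(ratings))
}

#' Extract the acceptance quantities from a recovery run
#' @param rec result of [acceptance_recovery()]
#' @return named list of numeric values
#' @export
acceptance_values <- function(rec) {
  eff <- rec$contrasts
  grab <- function(f, cond) {
    eff$contrast[eff$feature == f & eff$condition == cond]
  }
  pitch_eff <- rec$rating_fit$estimate[rec$rating_fit$feature == "f0_median_st"]
  list(
    t3 = grab("f0_median_st", "pretended"),
    t4 = grab("f0_median_st", "real"),
    t5 = grab("f0_median_st", "concealed"),
    t6 = grab("fm_depth_st", "concealed"),
    t7 = grab("fm_depth_st", "real"),
    t8 = grab("duration_s", "concealed"),
    t9 = pitch_eff
  )
}
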