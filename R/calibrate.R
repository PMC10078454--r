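# Calibration of generator condition offsets to standardized contrast
# targets, via iterated pilot corpora.

# mapping from calibratable features to the physical offset column
offset_knob <- function(feature) {
  switch(feature,
    f0_median_st = "f0_st",
    fm_depth_st = "tremor_st",
    duration_s = "dur_scale",
    loudness_db = "amp_db",
    harm_energy_prop = "tilt_db_oct",
    stop("feature '", feature, "' is not calibratable")
  )
}

# fallback physical-to-feature gains (feature units per offset unit), used
# when a knob is currently at zero so no empirical gain is measurable
default_gain <- function(feature) {
  switch(feature,
    f0_median_st = 1, # semitone offset -> semitone median
    fm_depth_st = 0.35, # band share of the stochastic anchor contour
    duration_s = 1.74, # seconds of baseline utterance per unit dur_scale
    loudness_db = 1,
    harm_energy_prop = 0.03 # proportion per dB/oct of tilt, local slope
  )
}

#' Calibrate condition offsets to standardized contrast targets
#'
#' Finds physical generator offsets such that the realized standardized
#' condition contrasts (through the full synthesis -> tracking ->
#' features -> mixed-model pipeline) match the requested targets within
#' `tol` SD.
#'
#' Because every feature is z-scored across the corpus, the condition
#' offsets themselves contribute to the standardizing SD: pushing an
#' offset up inflates the denominator of every contrast of that feature.
#' Each round therefore (1) generates a pilot corpus under the current
#' offsets, (2) estimates, per feature, the raw-unit condition effects,
#' the physical-to-feature gain of each knob, and the non-condition
#' variance, and (3) solves the self-standardization fixed point
#' `SD^2 = Var_cond(target * SD) + sigma_other^2` for the standardizing
#' SD, from which the physical offsets follow directly. Linear knobs
#' (pitch, level, duration) converge in one round; the tremor knob's
#' mildly nonlinear gain is refreshed each round. Zero targets map to
#' zero offsets. Deterministic given `seed`.
#'
#' @param targets data.frame with columns `feature` (one of
#'   `f0_median_st`, `fm_depth_st`, `duration_s`, `loudness_db`,
#'   `harm_energy_prop`), `condition` (non-baseline), `target` (SD units)
#' @param config a [corpus_config()]; its `offsets` seed the iteration
#' @param pilot_n pilot speakers (default: all of `config`'s)
#' @param pilot_takes takes per cell in the pilot (default 2)
#' @param tol convergence tolerance in SD (default 0.1)
#' @param max_iter maximum pilot rounds (default 3)
#' @param seed integer seed for the pilot corpora
#' @return list: `offsets` (calibrated [condition_offsets()]), `realized`
#'   (last pilot contrasts, aligned with non-zero targets), `residuals`,
#'   `iterations`, `converged`, `targets`. On non-convergence the last
#'   residuals are reported in a warning.
#' @export
calibrate_offsets <- function(targets, config = corpus_config(),
                              pilot_n = config$n_speakers, pilot_takes = 2,
                              tol = 0.1, max_iter = 3, seed = config$seed,
                              verbose = FALSE) {
  stopifnot(all(c("feature", "condition", "target") %in% names(targets)),
            all(targets$condition %in% setdiff(conditions(), "relaxed")))
  off <- config$offsets
  for (i in seq_len(nrow(targets))) { # zero target = identity case
    if (targets$target[i] == 0) {
      off[off$condition == targets$condition[i],
          offset_knob(targets$feature[i])] <- 0
    }
  }
  active <- targets[targets$target != 0, , drop = FALSE]
  if (nrow(active) == 0) {
    return(list(offsets = off, realized = targets$target * 0,
                residuals = targets$target * 0, iterations = 0L,
                converged = TRUE, targets = active))
  }
  feats_cal <- unique(active$feature)
  n_f <- max(1L, round(pilot_n * config$n_female / config$n_speakers))
  n_m <- max(1L, pilot_n - n_f)
  non_baseline <- setdiff(conditions(), "relaxed")
  realized <- rep(NA_real_, nrow(active))
  converged <- FALSE
  iter <- 0L
  pool_sigma <- list() # running per-feature estimates across pilots:
  pool_gain <- list()  # pooling damps the chase of pilot-to-pilot noise
  while (iter < max_iter) {
    iter <- iter + 1L
    pcfg <- corpus_config(
      n_female = n_f, n_male = n_m, takes = pilot_takes, offsets = off,
      rate = config$rate, speaker_sd = config$speaker_sd,
      take_sd = config$take_sd, female_f0 = config$female_f0,
      male_f0 = config$male_f0, seed = child_seed(seed, "pilot", iter)
    )
    feats <- corpus_features(generate_corpus(pcfg))
    stats_f <- list()
    for (f in feats_cal) {
      y <- feats[[f]]
      ok <- is.finite(y)
      d <- feats[ok, c("condition", "sex", "channel", "speaker")]
      d$y <- y[ok]
      # raw condition effects (controlling sex/channel) and the variance
      # not attributable to condition
      fit <- lm(y ~ condition + sex + channel, data = d)
      raw <- setNames(numeric(length(non_baseline)), non_baseline)
      for (cc in non_baseline) {
        nm <- paste0("condition", cc)
        raw[cc] <- if (nm %in% names(coef(fit))) coef(fit)[[nm]] else 0
      }
      cond_means <- tapply(d$y, d$condition, mean)
      sigma_o <- sd(d$y - cond_means[d$condition])
      sd_tot <- sd(d$y)
      # realized standardized contrasts (for the convergence check)
      rows_f <- which(active$feature == f)
      for (i in rows_f) realized[i] <- raw[active$condition[i]] / sd_tot
      if (offset_knob(f) == "tremor_st") {
        # the FM estimator's noise scales with the injection level, so
        # sigma from earlier rounds (different injections) is not
        # exchangeable: use the current pilot only
        pool_sigma[[f]] <- sigma_o^2
      } else {
        pool_sigma[[f]] <- c(pool_sigma[[f]], sigma_o^2)
      }
      stats_f[[f]] <- list(raw = raw, sigma_o = sqrt(mean(pool_sigma[[f]])),
                           base = unname(cond_means["relaxed"]))
      if (verbose) {
        message(sprintf(
          "iter %d %s: raw=%s sd_tot=%.3f sigma_o=%.3f offsets=%s", iter, f,
          paste(round(raw, 3), collapse = "/"), sd_tot, sigma_o,
          paste(round(off[[offset_knob(f)]], 3), collapse = "/")))
      }
    }
    if (all(abs(realized - active$target) <= tol, na.rm = TRUE)) {
      converged <- TRUE
      break # keep the offsets that produced the converged pilot
    }
    for (f in feats_cal) {
      raw <- stats_f[[f]]$raw
      sigma_o <- stats_f[[f]]$sigma_o
      rows_f <- which(active$feature == f)
      # freeze whole features, never single targets: all of a feature's
      # offsets share one standardizing SD, so updating one condition
      # while freezing another would silently de-calibrate the frozen one
      if (all(abs(realized[rows_f] - active$target[rows_f]) <= 0.75 * tol,
              na.rm = TRUE)) {
        next
      }
      knob <- offset_knob(f)
      if (knob == "tremor_st") {
        gain <- NULL # handled by the empirical update below
      } else if (f %in% c("f0_median_st", "loudness_db")) {
        # exact physical gains: a semitone offset shifts the tracked
        # median by one semitone, a dB offset shifts frame RMS by one dB
        # (tracker/level biases are constant and cancel in the contrast)
        gain <- setNames(rep(1, length(non_baseline)), non_baseline)
      } else if (f == "duration_s") {
        # duration responds exactly linearly with gain = the mean relaxed
        # utterance duration (measured with ~1% error on the pilot)
        pool_gain[[f]] <- c(pool_gain[[f]], stats_f[[f]]$base)
        gain <- setNames(rep(mean(pool_gain[[f]]), length(non_baseline)),
                         non_baseline)
      } else {
        # pooled empirical gain (least squares through the origin over the
        # conditions whose knob is active); fall back to the nominal gain
        deltas <- off[match(non_baseline, off$condition), knob]
        use <- abs(deltas) > 1e-9
        g <- if (any(use)) {
          sum(raw[use] * deltas[use]) / sum(deltas[use]^2)
        } else {
          default_gain(f)
        }
        if (!is.finite(g) || g * default_gain(f) <= 0) g <- default_gain(f)
        pool_gain[[f]] <- c(pool_gain[[f]], g)
        gain <- setNames(rep(mean(pool_gain[[f]]), length(non_baseline)),
                         non_baseline)
      }
      # solve SD^2 = Var_cond(u) + sigma_o^2 with u = t * SD for targeted
      # conditions and u fixed at the current raw effect otherwise
      t_vec <- setNames(rep(NA_real_, length(non_baseline)), non_baseline)
      for (i in rows_f) t_vec[active$condition[i]] <- active$target[i]
      SD <- sd_tot
      for (it in 1:30) {
        u <- ifelse(is.na(t_vec), raw, t_vec * SD)
        u_all <- c(0, u) # relaxed included
        SD <- sqrt(max(stats::var(u_all) * (length(u_all) - 1) / length(u_all), 0) +
                     sigma_o^2)
      }
      for (i in rows_f) {
        cc <- active$condition[i]
        if (knob == "tremor_st") {
          # the injected-tremor knob responds through a quadrature floor,
          # r(s) = sqrt(b^2 + (a s)^2) - b, which is super-linear in s on
          # the way down: plain multiplicative steps overshoot. Invert the
          # model instead, with the band gain `a` estimated from every
          # condition carrying a sizable injection (pooled across rounds).
          b <- max(stats_f[[f]]$base, 1e-3)
          s_cur <- off[off$condition == cc, knob]
          if (s_cur > 0.02 && is.finite(raw[cc]) && raw[cc] > 0.005) {
            a_hat <- sqrt((raw[cc] + b)^2 - b^2) / s_cur
            pool_gain[[paste0(f, "_quad")]] <-
              c(pool_gain[[paste0(f, "_quad")]], a_hat)
          }
          a <- if (length(pool_gain[[paste0(f, "_quad")]])) {
            mean(pool_gain[[paste0(f, "_quad")]])
          } else {
            default_gain(f)
          }
          u_req <- max(active$target[i], 0) * SD
          off[off$condition == cc, knob] <-
            sqrt(max((u_req + b)^2 - b^2, 0)) / a
        } else {
          u <- active$target[i] * SD # required raw-unit condition effect
          new <- u / gain[cc]
          if (knob == "dur_scale") new <- max(-0.5, min(1, new))
          off[off$condition == cc, knob] <- new
        }
      }
    }
  }
  residuals <- realized - active$target
  if (!converged && any(abs(residuals) > tol, na.rm = TRUE)) {
    warning("calibration did not converge after ", iter,
            " iterations; last residuals: ",
            paste(sprintf("%s/%s=%.3f", active$feature, active$condition,
                          residuals), collapse = ", "))
  }
  list(offsets = off, realized = realized, residuals = residuals,
       iterations = iter, converged = converged, targets = active)
}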