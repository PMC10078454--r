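# Source-filter synthesis of speech-like utterances and corpus generation.
# The synthesizer is a Klatt-style additive scheme: a tilted harmonic
# source (plus jitter, shimmer, optional tremor FM, and aspiration noise)
# passed through four formant resonators for voiced syllables, shaped
# noise for unvoiced ones. It is deliberately simple: just rich enough to
# drive all 19 acoustic descriptors with known ground truth.

#' Condition labels of the study design
#' @return character vector: relaxed, real, concealed, pretended
#' @export
conditions <- function() c("relaxed", "real", "concealed", "pretended")

default_syllables <- function() {
  data.frame(
    voiced = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    duration = c(0.30, 0.28, 0.24, 0.16, 0.34, 0.42),
    amp = c(0.90, 0.80, 0.75, 0.45, 1.00, 0.85) # phrase accent on syllable 5
  )
}

#' Voice specification for the synthesizer
#'
#' Describes one utterance: source fundamental and spectral tilt, four
#' formant frequencies, aspiration level, cycle-level perturbations, the
#' syllable pattern, overall level, an optional tremor injection, and a
#' time-scale factor.
#'
#' @param base_f0 fundamental frequency (Hz), in `[75, 500]`
#' @param formants four ascending resonance frequencies F1-F4 (Hz)
#' @param source_tilt glottal source rolloff (dB/octave, negative;
#'   e.g. -12 = each octave 12 dB weaker)
#' @param breath_noise aspiration level relative to the voiced source (dB)
#' @param jitter cycle-to-cycle f0 perturbation (%)
#' @param shimmer cycle amplitude perturbation (%)
#' @param syllables data.frame with columns `voiced` (logical), `duration`
#'   (s, > 0), `amp` (relative amplitude)
#' @param amplitude_db overall peak level (dB re full scale, <= 0)
#' @param tremor optional [tremor_spec()] injected at synthesis time
#' @param duration_scale multiplicative time factor (> 0)
#' @return object of class `VoiceSpec`
#' @export
voice_spec <- function(base_f0 = 120, formants = c(500, 1500, 2500, 3500),
                       source_tilt = -12, breath_noise = -25, jitter = 1,
                       shimmer = 3, syllables = default_syllables(),
                       amplitude_db = -3, tremor = NULL, duration_scale = 1) {
  stopifnot(
    base_f0 >= 75, base_f0 <= 500,
    length(formants) == 4, all(diff(formants) > 0),
    all(syllables$duration > 0),
    amplitude_db <= 0, duration_scale > 0,
    jitter >= 0, shimmer >= 0
  )
  structure(list(
    base_f0 = base_f0, formants = formants, source_tilt = source_tilt,
    breath_noise = breath_noise, jitter = jitter, shimmer = shimmer,
    syllables = syllables, amplitude_db = amplitude_db, tremor = tremor,
    duration_scale = duration_scale
  ), class = "VoiceSpec")
}

#' Per-condition physical offsets of the generator
#'
#' One row per condition with additive offsets on log-pitch (semitones),
#' level (dB), source tilt (dB/octave), duration scale (added to 1), and
#' the injected 8-14 Hz tremor depth (semitones, >= 0). The relaxed
#' (baseline) row is all zero by construction. Defaults are conventions
#' chosen to mimic the direction and rough size of the observed condition
#' contrasts; [calibrate_offsets()] tunes them to standardized targets.
#'
#' @param df optional data.frame with columns `condition`, `f0_st`,
#'   `amp_db`, `tilt_db_oct`, `dur_scale`, `tremor_st`
#' @return object of class `ConditionOffsets` (a data.frame)
#' @export
condition_offsets <- function(df = NULL) {
  if (is.null(df)) {
    df <- data.frame(
      condition = conditions(),
      f0_st = c(0, 2.3, 1.3, 3.8),
      amp_db = c(0, 6, 2, 8),
      tilt_db_oct = c(0, 3.5, 1.0, 4.5),
      dur_scale = c(0, -0.040, -0.055, 0.025),
      tremor_st = c(0, 0.35, 0.45, 0)
    )
  }
  stopifnot(
    setequal(df$condition, conditions()),
    all(df$tremor_st >= 0)
  )
  rel <- df[df$condition == "relaxed",
            c("f0_st", "amp_db", "tilt_db_oct", "dur_scale", "tremor_st")]
  stopifnot(all(abs(unlist(rel)) < 1e-12))
  df <- df[match(conditions(), df$condition), ]
  rownames(df) <- NULL
  class(df) <- c("ConditionOffsets", "data.frame")
  df
}

#' Corpus configuration
#'
#' Study-design defaults: 33 speakers (15 female + 18 male), 4 conditions,
#' 3 takes of one short utterance per cell, i.e. 396 utterances.
#'
#' @param n_female,n_male speaker counts (default 15 + 18)
#' @param takes takes per speaker x condition (default 3)
#' @param offsets a [condition_offsets()] table
#' @param rate audio sampling rate (Hz, default 44100)
#' @param speaker_sd between-speaker SDs: `f0_st` (semitones around the
#'   sex mean), `formant_frac` (fractional apparent-VTL scatter),
#'   `tilt` (dB/oct), `amp_db` (habitual level, dB), `dur_frac`
#'   (fractional speech-rate scatter)
#' @param take_sd within-speaker take-to-take SDs: `f0_st`, `amp_db`,
#'   `tilt`, `dur_frac`
#' @param female_f0,male_f0 sex mean fundamentals (Hz)
#' @param seed integer seed; a fixed seed yields a bit-identical corpus
#' @return object of class `CorpusConfig`
#' @export
corpus_config <- function(n_female = 15, n_male = 18, takes = 3,
                          offsets = condition_offsets(), rate = 44100,
                          speaker_sd = c(f0_st = 2, formant_frac = 0.05,
                                         tilt = 2, amp_db = 2, dur_frac = 0.08),
                          take_sd = c(f0_st = 0.5, amp_db = 1.2, tilt = 1, dur_frac = 0.04),
                          female_f0 = 210, male_f0 = 120, seed = 1) {
  stopifnot(n_female >= 0, n_male >= 0, n_female + n_male >= 1, takes >= 1)
  structure(list(
    n_speakers = n_female + n_male, n_female = n_female, n_male = n_male,
    takes = takes, conditions = conditions(), offsets = offsets,
    rate = rate, speaker_sd = speaker_sd, take_sd = take_sd,
    female_f0 = female_f0, male_f0 = male_f0, seed = seed
  ), class = "CorpusConfig")
}

#' Draw a random speaker
#'
#' Samples speaker-level acoustics from sex-specific distributions:
#' base f0 lognormal around the sex mean (SD in semitones), formants
#' scaled by an apparent-vocal-tract-length factor (females shorter tracts,
#' higher formants), and spectral tilt. Deterministic given the RNG state.
#'
#' @param config a [corpus_config()]
#' @param sex `"female"` or `"male"`
#' @return a [voice_spec()]
#' @export
sample_speaker <- function(config, sex) {
  stopifnot(inherits(config, "CorpusConfig"))
  if (!sex %in% c("female", "male")) {
    stop("unknown sex label '", sex, "': must be 'female' or 'male'")
  }
  mu_f0 <- if (sex == "female") config$female_f0 else config$male_f0
  f0 <- st_to_hz(hz_to_st(mu_f0) + rnorm(1, 0, config$speaker_sd[["f0_st"]]))
  f0 <- min(500, max(75, f0))
  vtl_factor <- (if (sex == "female") 1.15 else 1.0) *
    exp(rnorm(1, 0, config$speaker_sd[["formant_frac"]]))
  tilt <- -12 + rnorm(1, 0, config$speaker_sd[["tilt"]])
  voice_spec(
    base_f0 = f0,
    formants = c(500, 1500, 2500, 3500) * vtl_factor,
    source_tilt = min(-4, tilt),
    breath_noise = -25 + rnorm(1, 0, 2),
    jitter = max(0.2, rnorm(1, 1, 0.3)),
    shimmer = max(0.5, rnorm(1, 3, 0.8)),
    amplitude_db = min(0, -12 + rnorm(1, 0, config$speaker_sd[["amp_db"]])),
    duration_scale = exp(rnorm(1, 0, config$speaker_sd[["dur_frac"]]))
  )
}

# per-cycle perturbation track: gaussian noise at one anchor per glottal
# cycle, linearly interpolated to the sample grid
cycle_noise <- function(n, fs, f0) {
  n_anchors <- max(3L, ceiling(n / fs * f0) + 1L)
  at <- seq(0, n - 1, length.out = n_anchors)
  approx(at, rnorm(n_anchors), xout = seq_len(n) - 1)$y
}

#' Synthesize one utterance
#'
#' Source-filter synthesis of a multi-syllable utterance. Voiced syllables
#' use an additive harmonic source with spectral tilt (`source_tilt`
#' dB/octave), jitter/shimmer perturbations, an optional tremor FM factor,
#' and aspiration noise, filtered by four formant resonators. Unvoiced
#' syllables are band-passed noise. Harmonics are band-limited below
#' `band_limit` Hz. The waveform is peak-normalized to `amplitude_db`.
#'
#' Uses the current RNG state; wrap in `set.seed()` for reproducibility.
#'
#' @param spec a [voice_spec()]
#' @param rate sampling rate (Hz, default 44100)
#' @param band_limit highest synthesized harmonic frequency (Hz)
#' @return a [waveform()] of duration
#'   `sum(syllable durations) * duration_scale`
#' @export
synth_utterance <- function(spec, rate = 44100, band_limit = 8000) {
  stopifnot(inherits(spec, "VoiceSpec"))
  if (spec$base_f0 > rate / 4) {
    stop("base_f0 above Nyquist/2 of the configured rate")
  }
  fs <- rate
  syl <- spec$syllables
  durs <- syl$duration * spec$duration_scale
  n_tot <- round(sum(durs) * fs)
  total_dur <- n_tot / fs
  x <- numeric(n_tot)
  # utterance-level intonation on the semitone scale: declination plus a
  # gentle per-syllable accent, shared across syllables via global time
  t_all <- (seq_len(n_tot) - 1) / fs
  decl <- -1.5 * t_all / total_dur
  n_acc <- nrow(syl) + 2
  acc_anchors <- rnorm(n_acc, 0, 0.7)
  accent <- splinefun(seq(0, total_dur, length.out = n_acc), acc_anchors,
                      method = "natural")(t_all)
  # center the intonation so base_f0 is the utterance's median source pitch
  intonation <- decl + accent
  intonation <- intonation - median(intonation)
  # optional tremor factor over the whole utterance; salience proxy built
  # from the syllable amplitude pattern
  trem_st <- numeric(n_tot)
  if (!is.null(spec$tremor)) {
    sal_t <- rep(syl$amp * ifelse(syl$voiced, 1, 0.2), times = round(durs * fs))
    sal_t <- sal_t[seq_len(n_tot)]
    step <- 0.025
    sal <- sal_t[seq(1, n_tot, by = round(step * fs))]
    fac <- tremor_factor_contour(total_dur, spec$tremor, salience = sal,
                                 fs_out = fs, n_out = n_tot)
    trem_st <- 12 * log2(fac)
  }
  resort <- function(sig) { # formant cascade
    bws <- c(80, 100, 120, 150)
    for (i in 1:4) sig <- resonator(sig, spec$formants[i], bws[i], fs)
    sig
  }
  offset <- 0L
  for (s in seq_len(nrow(syl))) {
    n_syl <- round(durs[s] * fs)
    if (n_syl < 8) { offset <- offset + n_syl; next }
    idx <- offset + seq_len(n_syl)
    offset <- offset + n_syl
    idx <- idx[idx <= n_tot]
    n_s <- length(idx)
    if (n_s < 8) next
    if (syl$voiced[s]) {
      jit <- cycle_noise(n_s, fs, spec$base_f0) * spec$jitter / 100
      st_dev <- intonation[idx] + trem_st[idx]
      f0_t <- spec$base_f0 * 2^(st_dev / 12) * (1 + jit)
      phase <- 2 * pi * cumsum(f0_t) / fs
      n_harm <- max(1L, floor(band_limit / max(f0_t)))
      amps <- 10^(spec$source_tilt * log2(seq_len(n_harm)) / 20)
      src <- numeric(n_s)
      for (k in seq_len(n_harm)) src <- src + amps[k] * sin(k * phase)
      shim <- 1 + cycle_noise(n_s, fs, spec$base_f0) * spec$shimmer / 100
      src <- src * shim
      asp <- rnorm(n_s) * 10^(spec$breath_noise / 20) * max(abs(src))
      sig <- resort(src + asp)
      sig <- sig / max(abs(sig)) # relative level set by the syllable pattern
    } else {
      noise <- rnorm(n_s)
      sig <- resonator(noise, 4500, 2500, fs) + 0.4 * resonator(noise, 2500, 1500, fs)
      sig <- sig / max(abs(sig)) * 0.25
    }
    ramp <- round(min(0.02 * fs, n_s / 4))
    env <- rep(1, n_s)
    env[seq_len(ramp)] <- 0.5 - 0.5 * cos(pi * seq_len(ramp) / ramp)
    env[n_s + 1 - seq_len(ramp)] <- env[seq_len(ramp)]
    x[idx] <- sig * env * syl$amp[s]
  }
  peak <- max(abs(x))
  if (peak > 0) x <- x / peak * 10^(spec$amplitude_db / 20)
  waveform(x, fs)
}

#' Generate a synthetic corpus
#'
#' Produces one utterance per speaker x condition x take cell (default
#' 33 x 4 x 3 = 396). Condition offsets shift pitch, level, tilt, and
#' duration and inject tremor; takes add small within-speaker parameter
#' noise; each utterance gets a random binary recording channel whose
#' only acoustic consequence is a small additive spectral-tilt change
#' (+0.8 dB/oct on channel B), so the statistical channel covariate is
#' exercisable. All realized physical parameters are emitted in the
#' metadata table (ground-truth closure). Byte-identical given
#' `config$seed`.
#'
#' @param config a [corpus_config()]
#' @param keep_audio if `FALSE`, waveforms are dropped (metadata only)
#' @return list with `audio` (list of [waveform()]) and `meta`
#'   (data.frame: `id`, `speaker`, `sex`, `condition`, `take`, `channel`,
#'   plus realized ground-truth parameters)
#' @export
generate_corpus <- function(config = corpus_config(), keep_audio = TRUE) {
  stopifnot(inherits(config, "CorpusConfig"))
  sexes <- rep(c("female", "male"), c(config$n_female, config$n_male))
  off <- config$offsets
  rows <- list()
  audio <- list()
  n <- 0L
  for (sp in seq_len(config$n_speakers)) {
    spk <- with_seed(child_seed(config$seed, "speaker", sp),
                     sample_speaker(config, sexes[sp]))
    for (cond in config$conditions) {
      o <- off[off$condition == cond, ]
      for (take in seq_len(config$takes)) {
        n <- n + 1L
        seed_utt <- child_seed(config$seed, "utt", sp, cond, take)
        res <- with_seed(seed_utt, {
          tk <- config$take_sd
          f0 <- st_to_hz(hz_to_st(spk$base_f0) + o$f0_st +
                           rnorm(1, 0, tk[["f0_st"]]))
          f0 <- min(500, max(75, f0))
          channel <- sample(c("A", "B"), 1)
          tilt <- min(-3, spk$source_tilt + o$tilt_db_oct +
                        rnorm(1, 0, tk[["tilt"]]) +
                        if (channel == "B") 0.8 else 0)
          amp <- min(0, spk$amplitude_db + o$amp_db + rnorm(1, 0, tk[["amp_db"]]))
          dscale <- max(0.5, spk$duration_scale * (1 + o$dur_scale) *
                          exp(rnorm(1, 0, tk[["dur_frac"]])))
          trem <- if (o$tremor_st > 0) {
            tremor_spec(anchors_per_s = 20, sd_semitones = o$tremor_st,
                        envelope = "uniform")
          } else {
            NULL
          }
          sp2 <- spk
          sp2$base_f0 <- f0
          sp2$source_tilt <- tilt
          sp2$amplitude_db <- amp
          sp2$duration_scale <- dscale
          sp2$tremor <- trem
          w <- synth_utterance(sp2, rate = config$rate)
          list(w = w, meta = data.frame(
            id = sprintf("spk%02d_%s_t%d", sp, cond, take),
            speaker = sprintf("spk%02d", sp), sex = sexes[sp],
            condition = cond, take = take, channel = channel,
            gt_f0_hz = f0, gt_amp_db = amp, gt_tilt_db_oct = tilt,
            gt_dur_scale = dscale, gt_tremor_st = o$tremor_st,
            spk_f0_hz = spk$base_f0, spk_formant_scale = spk$formants[1] / 500
          ))
        })
        rows[[n]] <- res$meta
        if (keep_audio) audio[[n]] <- res$w
      }
    }
  }
  meta <- do.call(rbind, rows)
  meta$condition <- factor(meta$condition, levels = conditions())
  if (keep_audio) names(audio) <- meta$id
  list(audio = if (keep_audio) audio else NULL, meta = meta)
}

#' Extract acoustic profiles for a whole corpus
#'
#' Runs [acoustic_profile()] on every utterance and binds the results to
#' the metadata, yielding the feature table consumed by the statistical
#' layer.
#'
#' @param corpus result of [generate_corpus()] (needs `audio`)
#' @param search_range pitch search range (Hz)
#' @return data.frame: metadata columns + 19 descriptor columns
#' @export
corpus_features <- function(corpus, search_range = c(60, 600)) {
  stopifnot(!is.null(corpus$audio))
  profs <- lapply(corpus$audio, acoustic_profile, search_range = search_range)
  cbind(corpus$meta, do.call(rbind, profs))
}
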