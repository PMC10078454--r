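# Tremor resynthesis: a stochastic multiplicative f0 factor contour applied
# through a phase vocoder that preserves timing and the spectral envelope
# (formants).

#' Tremor manipulation parameters
#'
#' The tremor condition draws Gaussian f0 deviations at 20 anchor points
#' per second with SD 1 semitone and concentrates them under a Gaussian
#' amplitude envelope spanning 50% of the sound's duration, centered on the
#' loudest voiced section. The control condition uses the same machinery
#' with a time-uniform envelope and SD 0.17 semitones (= 1% in frequency,
#' see [st_from_percent()]), so any perceptual or acoustic difference
#' between the two isolates the tremor itself from resynthesis artifacts.
#'
#' @param anchors_per_s anchor rate (1/s, > 0)
#' @param sd_semitones SD of the Gaussian anchor deviations (semitones,
#'   >= 0)
#' @param envelope `"gaussian"` (localized) or `"uniform"` (constant)
#' @param envelope_span fraction of the duration spanned by the Gaussian
#'   envelope (in `(0, 1]`; the envelope SD is `span * duration / 4`)
#' @param center_policy `"loudest_voiced"` or `"midpoint"`
#' @param seed optional integer seed for the anchor noise
#' @return object of class `TremorSpec`
#' @export
tremor_spec <- function(anchors_per_s = 20, sd_semitones = 1,
                        envelope = c("gaussian", "uniform"),
                        envelope_span = 0.5,
                        center_policy = c("loudest_voiced", "midpoint"),
                        seed = NULL) {
  envelope <- match.arg(envelope)
  center_policy <- match.arg(center_policy)
  stopifnot(anchors_per_s > 0, sd_semitones >= 0,
            envelope_span > 0, envelope_span <= 1)
  structure(list(
    anchors_per_s = anchors_per_s, sd_semitones = sd_semitones,
    envelope = envelope, envelope_span = envelope_span,
    center_policy = center_policy, seed = seed
  ), class = "TremorSpec")
}

#' Stochastic f0 factor contour
#'
#' Draws independent normal deviates (SD `sd_semitones`) at
#' `anchors_per_s` anchor points, interpolates between anchors with a
#' monotone cubic spline, multiplies by the amplitude envelope, and
#' converts semitone deviations to multiplicative frequency factors
#' `2^(dev/12)`. The Gaussian envelope peaks at the frame maximizing the
#' smoothed (300 ms moving average) salience profile — i.e. the loudest
#' voiced stretch — or at the midpoint.
#'
#' @param duration sound duration (s, > 0)
#' @param spec a [tremor_spec()]
#' @param salience optional per-frame voiced-loudness profile aligned to
#'   25 ms frames (linear RMS, 0 for unvoiced); required for the
#'   `"loudest_voiced"` center policy
#' @param fs_out output sampling rate of the contour (Hz)
#' @param n_out number of output samples (default `round(duration * fs_out)`)
#' @param salience_step step of the salience frames (s)
#' @return numeric vector of positive factors, length `n_out`
#' @export
tremor_factor_contour <- function(duration, spec, salience = NULL,
                                  fs_out = 40, n_out = round(duration * fs_out),
                                  salience_step = 0.025) {
  stopifnot(inherits(spec, "TremorSpec"), duration > 0, n_out >= 2)
  t_out <- seq(0, duration, length.out = n_out)
  if (spec$sd_semitones == 0) return(rep(1, n_out))
  n_anchors <- max(4L, ceiling(duration * spec$anchors_per_s) + 1L)
  t_anchor <- seq(0, duration, length.out = n_anchors)
  draw <- function() rnorm(n_anchors, 0, spec$sd_semitones)
  dev_anchor <- if (is.null(spec$seed)) draw() else with_seed(spec$seed, draw())
  dev <- splinefun(t_anchor, dev_anchor, method = "monoH.FC")(t_out)
  if (spec$envelope == "gaussian") {
    center <- duration / 2
    if (spec$center_policy == "loudest_voiced" && !is.null(salience) &&
        any(salience > 0)) {
      k <- max(1L, round(0.3 / salience_step))
      sm <- stats::filter(salience, rep(1 / k, k), sides = 2)
      sm[is.na(sm)] <- 0
      center <- (which.max(sm) - 0.5) * salience_step
      center <- min(max(center, 0), duration)
    }
    sigma <- spec$envelope_span * duration / 4
    dev <- dev * exp(-0.5 * ((t_out - center) / sigma)^2)
  }
  2^(dev / 12)
}

#' Time-varying pitch shift with a phase vocoder
#'
#' Shifts the fundamental frequency by a (possibly time-varying)
#' multiplicative factor while preserving speech rate and formant
#' frequencies. Analysis/synthesis uses 2048-sample FFT frames with 4x
#' overlap and identity phase locking; formants are preserved by dividing
#' each frame's magnitude by its 40-coefficient cepstral envelope before
#' remapping bins and re-imposing the original envelope at the target
#' frequency. Output duration equals input duration within one hop.
#'
#' @param w a [waveform()]
#' @param factor positive finite scalar, or a numeric vector of per-sample
#'   factors with `length(w$samples)` entries
#' @param wl FFT length (default 2048)
#' @param overlap overlap factor (default 4, i.e. hop = wl/4)
#' @param n_lifter cepstral envelope coefficients (default 40)
#' @return a [waveform()]
#' @export
shift_pitch <- function(w, factor, wl = 2048, overlap = 4, n_lifter = 40) {
  stopifnot(inherits(w, "Waveform"))
  n <- length(w$samples)
  if (length(factor) == 1) factor <- rep(factor, n)
  if (length(factor) != n) {
    stop("factor contour length (", length(factor),
         ") must match the number of samples (", n, ")")
  }
  if (any(!is.finite(factor)) || any(factor <= 0)) {
    stop("factor contour must be positive and finite")
  }
  hop <- wl %/% overlap
  win <- hann_window(wl)
  xp <- c(numeric(wl), w$samples, numeric(2 * wl))
  fp <- c(rep(factor[1], wl), factor, rep(factor[n], 2 * wl))
  starts <- seq(1, n + wl, by = hop)
  nb <- wl %/% 2 + 1
  bin_w <- 2 * pi * (seq_len(nb) - 1) / wl # rad/sample
  y <- numeric(length(xp) + wl)
  wsum <- numeric(length(xp) + wl)
  phi_prev <- numeric(nb)
  psi <- numeric(nb)
  first <- TRUE
  for (st in starts) {
    frame <- xp[st:(st + wl - 1)] * win
    X <- fft(frame)[seq_len(nb)]
    mag <- abs(X)
    phi <- Arg(X)
    alpha <- fp[st + wl %/% 2]
    # instantaneous frequency per input bin
    dphi <- phi - phi_prev - bin_w * hop
    dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
    omega <- bin_w + dphi / hop
    phi_prev <- phi
    # cepstral spectral envelope (on log magnitude)
    logm <- log(pmax(mag, 1e-9))
    cep <- Re(fft(c(logm, rev(logm[2:(nb - 1)])), inverse = TRUE)) / (2 * (nb - 1))
    lift <- cep
    keep <- c(seq_len(n_lifter + 1), (length(cep) - n_lifter + 1):length(cep))
    lift[-keep] <- 0
    env <- exp(Re(fft(lift))[seq_len(nb)])
    flat <- mag / env
    kk <- round((seq_len(nb) - 1) * alpha) + 1L
    ok <- kk >= 1 & kk <= nb
    if (first) {
      psi <- phi * alpha
      first <- FALSE
    } else {
      # dominant contributor per target bin drives the phase (identity lock)
      ordm <- order(flat, decreasing = TRUE)
      kk_o <- kk[ordm]
      keep_dom <- ok[ordm] & !duplicated(kk_o)
      dom_in <- ordm[keep_dom]
      dom_out <- kk[dom_in]
      psi_new <- psi
      psi_new[dom_out] <- psi[dom_out] + alpha * omega[dom_in] * hop
      psi <- psi_new
    }
    mag_out <- numeric(nb)
    contrib <- flat[ok] * env[kk[ok]]
    mag_out[seq_len(nb)] <- 0
    tab <- rowsum(contrib, kk[ok])
    mag_out[as.integer(rownames(tab))] <- tab[, 1]
    Y <- mag_out * exp(1i * psi)
    full <- c(Y, Conj(rev(Y[2:(nb - 1)])))
    yfr <- Re(fft(full, inverse = TRUE)) / wl
    idx <- st:(st + wl - 1)
    y[idx] <- y[idx] + yfr * win
    wsum[idx] <- wsum[idx] + win^2
  }
  wsum[wsum < 1e-6] <- 1
  y <- y / wsum
  out <- y[wl + seq_len(n)]
  waveform(out, w$rate)
}

#' Apply the tremor or control manipulation to a recording
#'
#' Tracks the pitch of `w` to obtain a voiced-loudness salience profile,
#' builds the stochastic factor contour for the requested condition
#' (`"tremor"`: 20 anchors/s, SD 1 semitone, Gaussian envelope spanning
#' 50% of the duration centered on the loudest voiced section;
#' `"control"`: same anchors, SD 0.17 semitones, uniform envelope), and
#' applies it with [shift_pitch()]. Output RMS is matched to the input.
#' Deterministic given `seed`.
#'
#' @param w a [waveform()]
#' @param condition `"tremor"` or `"control"`
#' @param seed integer seed for the anchor noise
#' @param search_range pitch search range (Hz)
#' @return a [waveform()] of the same duration
#' @export
apply_manipulation <- function(w, condition = c("tremor", "control"),
                               seed = 1, search_range = c(60, 600)) {
  condition <- match.arg(condition)
  contour <- track_pitch(w, search_range = search_range)
  if (all(is.na(contour$f0))) {
    stop("pitch tracking failed: no voiced frames found")
  }
  spec <- if (condition == "tremor") {
    tremor_spec(20, 1.0, "gaussian", 0.5, "loudest_voiced", seed = seed)
  } else {
    tremor_spec(20, st_from_percent(1), "uniform", seed = seed)
  }
  salience <- contour$salience
  salience[is.na(contour$f0)] <- 0
  fac <- tremor_factor_contour(wav_duration(w), spec, salience = salience,
                               fs_out = w$rate, n_out = length(w$samples),
                               salience_step = contour$step)
  out <- shift_pitch(w, fac)
  in_rms <- sqrt(mean(w$samples^2))
  out_rms <- sqrt(mean(out$samples^2))
  if (out_rms > 0) out$samples <- out$samples * in_rms / out_rms
  out$samples <- pmax(-1, pmin(1, out$samples))
  out
}
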