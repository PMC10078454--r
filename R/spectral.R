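# Spectral / voice-quality descriptors and assembly of the 19-value
# acoustic profile. Per-frame measures take a one-sided magnitude spectrum
# (freq, mag); utterance-level wrappers share a single STFT and pitch track.

#' Names of the 19 acoustic descriptors
#'
#' Column order of the per-utterance acoustic profile: duration, loudness
#' (mean frame RMS in dB re full scale) and its IQR, pitch median/IQR/slope
#' on the semitone scale, fast (10 Hz) and slow (1 Hz) inflection rates,
#' 8-14 Hz FM depth, proportion of spectral energy above 1.5 f0, height of
#' detectable harmonics, first spectral quartile, spectral centroid,
#' spectral novelty, cepstral peak prominence, harmonics-to-noise ratio
#' (max autocorrelation), modulation-spectrum roughness, F1, and apparent
#' vocal tract length.
#'
#' @return character vector of length 19
#' @export
profile_fields <- function() {
  c("duration_s", "loudness_db", "loudness_iqr_db", "f0_median_st",
    "f0_iqr_st", "pitch_slope_st_s", "infl_fast_per_s", "infl_slow_per_s",
    "fm_depth_st", "harm_energy_prop", "harm_height_hz", "spec_q25_hz",
    "spec_centroid_hz", "novelty", "cpp_db", "hnr", "roughness_prop",
    "f1_hz", "vtl_cm")
}

# descriptor columns measured in Hz (log-transformed before z-scoring)
hz_fields <- function() c("harm_height_hz", "spec_q25_hz", "spec_centroid_hz", "f1_hz")

#' Frame-level loudness statistics
#'
#' Per-frame RMS in dB re full scale (40 ms frames, 10 ms step); the
#' utterance loudness is the mean over frames above the silence floor
#' (`silence_db` re the loudest frame), its variability the IQR over the
#' same frames.
#'
#' @param w a [waveform()]
#' @param wl_s,step_s frame length and step in seconds
#' @param silence_db silence floor relative to the loudest frame (dB)
#' @return list with `rms_db`, `iqr_db` (both `NA` for silent input)
#' @export
loudness_stats <- function(w, wl_s = 0.040, step_s = 0.010, silence_db = -45) {
  stopifnot(inherits(w, "Waveform"))
  if (length(w$samples) == 0) stop("empty waveform")
  wl <- round(wl_s * w$rate)
  hop <- round(step_s * w$rate)
  starts <- seq(1, max(1, length(w$samples) - wl + 1), by = hop)
  xp <- c(w$samples, numeric(wl))
  idx <- outer(seq_len(wl) - 1L, starts, `+`)
  rms <- sqrt(colMeans(matrix(xp[idx], nrow = wl)^2))
  if (max(rms) <= 0) return(list(rms_db = NA_real_, iqr_db = NA_real_))
  db <- 20 * log10(pmax(rms, 1e-12))
  keep <- db >= max(db) + silence_db
  list(
    rms_db = mean(db[keep]),
    iqr_db = diff(quantile(db[keep], c(0.25, 0.75), names = FALSE))
  )
}

#' Proportion of spectral energy in the harmonics
#'
#' Fraction of frame energy (squared magnitude) above `1.5 * f0` — the
#' classic correlate of pressed versus breathy phonation: a flatter source
#' spectrum puts more energy into upper harmonics.
#'
#' @param freq frequencies of the one-sided spectrum (Hz)
#' @param mag linear magnitudes (same length)
#' @param f0 fundamental frequency of the frame (Hz)
#' @return proportion in `[0, 1]`
#' @export
harmonic_energy <- function(freq, mag, f0) {
  stopifnot(length(freq) == length(mag), f0 > 0)
  e <- mag^2
  tot <- sum(e)
  if (tot <= 0) return(NA_real_)
  sum(e[freq > 1.5 * f0]) / tot
}

#' Height of detectable harmonics
#'
#' Scans multiples of `f0` upward and returns the frequency of the highest
#' harmonic whose local spectral peak exceeds the median level of its
#' `+/- f0/2` neighborhood by `threshold_db`. Scanning stops after two
#' consecutive misses so isolated noise excursions at high frequencies do
#' not inflate the estimate. Returns `f0` if no harmonic above the first is
#' detectable.
#'
#' @inheritParams harmonic_energy
#' @param threshold_db detection threshold above the local median (dB)
#' @return frequency in Hz
#' @export
harmonics_height <- function(freq, mag, f0, threshold_db = 6) {
  stopifnot(length(freq) == length(mag), f0 > 0)
  db <- 20 * log10(pmax(mag, 1e-12))
  n_max <- floor(max(freq) / f0)
  best <- f0
  misses <- 0L
  if (n_max >= 2) {
    for (n in 2:n_max) {
      # the peak must stand out against BOTH inter-harmonic valleys:
      # a one-sided test is fooled by the window skirt of the previous
      # harmonic
      left <- freq >= (n - 0.5) * f0 & freq < (n - 0.2) * f0
      right <- freq > (n + 0.2) * f0 & freq <= (n + 0.5) * f0
      peak_win <- which(freq >= (n - 0.25) * f0 & freq <= (n + 0.25) * f0)
      if (sum(left) < 2 || sum(right) < 2 || !length(peak_win)) break
      # level = median over the mainlobe around the local maximum, so a
      # single noise bin cannot imitate a harmonic peak
      pk_bin <- peak_win[which.max(db[peak_win])]
      lobe <- abs(freq - freq[pk_bin]) <= 25
      pk <- median(db[lobe])
      # a true harmonic dominates its whole +/- f0/2 neighborhood; noise
      # clusters and window skirts do not
      nb <- left | right | (seq_along(freq) %in% peak_win)
      if (db[pk_bin] < max(db[nb])) {
        misses <- misses + 1L
        if (misses >= 2L) break
        next
      }
      # peaks below the 60 dB analysis dynamic range are window sidelobes
      # or numerical noise, not harmonics
      if (pk >= max(db) - 60 &&
          pk - median(db[left]) >= threshold_db &&
          pk - median(db[right]) >= threshold_db) {
        best <- n * f0
        misses <- 0L
      } else {
        misses <- misses + 1L
        if (misses >= 2L) break
      }
    }
  }
  best
}

#' Spectral quartile and centroid
#'
#' First quartile (25th percentile) and center of gravity of the frame's
#' energy distribution over frequency, with linear interpolation between
#' bins for the quartile.
#'
#' @inheritParams harmonic_energy
#' @return list with `q25`, `centroid` (Hz); `NA` for zero-energy frames
#' @export
spectral_moments <- function(freq, mag) {
  stopifnot(length(freq) == length(mag))
  e <- mag^2
  tot <- sum(e)
  if (tot <= 0) return(list(q25 = NA_real_, centroid = NA_real_))
  centroid <- sum(freq * e) / tot
  cum <- cumsum(e) / tot
  i <- which(cum >= 0.25)[1]
  q25 <- if (i == 1) {
    freq[1]
  } else {
    prev <- cum[i - 1]
    freq[i - 1] + (freq[i] - freq[i - 1]) * (0.25 - prev) / (cum[i] - prev)
  }
  list(q25 = q25, centroid = centroid)
}

#' Cepstral peak prominence
#'
#' Height of the cepstral peak at the pitch quefrency above the linear
#' regression trend through the cepstrum: the real cepstrum of the
#' log-magnitude (dB) spectrum is searched within the quefrency band of
#' `search_range`, and the regression line is fit over quefrencies from
#' 0.5 ms to the maximum search quefrency. High CPP marks clear
#' periodicity; breathy or noisy frames score low.
#'
#' @param x numeric frame samples
#' @param rate sampling rate (Hz)
#' @param search_range f0 search range in Hz
#' @return CPP in dB, `NA` for degenerate (constant) frames
#' @export
cpp <- function(x, rate, search_range = c(60, 600)) {
  n <- length(x)
  if (n < 2 * rate / search_range[1]) {
    stop("frame shorter than 2 periods of the minimum f0")
  }
  if (sd(x) == 0) return(NA_real_)
  nfft <- next_pow2(n)
  spec_db <- 20 * log10(pmax(abs(fft(c(x * hann_window(n), numeric(nfft - n)))), 1e-12))
  cep <- Re(fft(spec_db, inverse = TRUE)) / nfft
  q <- (seq_len(nfft) - 1) / rate
  lo <- ceiling(rate / search_range[2])
  hi <- floor(rate / search_range[1])
  band <- (lo:hi) + 1L
  peak_i <- band[which.max(cep[band])]
  trend_idx <- which(q >= 0.0005 & q <= q[max(band)])
  qx <- q[trend_idx]
  cy <- cep[trend_idx]
  slope <- sum((qx - mean(qx)) * (cy - mean(cy))) / sum((qx - mean(qx))^2)
  trend_at_peak <- mean(cy) + slope * (q[peak_i] - mean(qx))
  as.numeric(cep[peak_i] - trend_at_peak)
}

#' Harmonics-to-noise ratio (tonality)
#'
#' Maximum of the unbiased normalized autocorrelation within the lag range
#' of `search_range`, clamped to `[0, 1]`: near 1 for a pure tone, near 0
#' for white noise.
#'
#' @inheritParams cpp
#' @return value in `[0, 1]`, `NA` for silent frames
#' @export
hnr <- function(x, rate, search_range = c(60, 600)) {
  n <- length(x)
  if (sqrt(mean(x^2)) <= 0) return(NA_real_)
  nfft <- next_pow2(2 * n)
  sp <- fft(c(x, numeric(nfft - n)))
  ac <- Re(fft(sp * Conj(sp), inverse = TRUE)) / nfft
  lo <- max(2L, floor(rate / search_range[2]))
  hi <- min(n - 2L, ceiling(rate / search_range[1]))
  if (hi <= lo) return(NA_real_)
  lags <- lo:hi
  r <- ac[lags + 1] / ac[1] * (n / (n - lags))
  max(0, min(1, max(r)))
}

#' Modulation-spectrum roughness
#'
#' Extracts amplitude envelopes of spectral bands (512-sample windows,
#' 128-sample hop), computes each band's modulation spectrum, and returns
#' the energy-weighted fraction of modulation power falling in the
#' roughness band (default 30-150 Hz) relative to all modulation power
#' above 0.5 Hz. Amplitude modulation at syllabic rates (< 30 Hz) or pure
#' unmodulated tones score near 0.
#'
#' @param w a [waveform()]
#' @param band roughness band `c(lo, hi)` in Hz
#' @return proportion in `[0, 1]`, `NA` for input shorter than 0.5 s
#' @export
roughness <- function(w, band = c(30, 150)) {
  stopifnot(inherits(w, "Waveform"))
  if (wav_duration(w) < 0.5) return(NA_real_)
  fs <- w$rate
  wl <- 512
  hop <- 128
  s <- stft(w$samples, fs, wl_s = wl / fs, step_s = hop / fs, window = "hann")
  env_fs <- fs / hop
  nt <- ncol(s$mag)
  if (nt < 8) return(NA_real_)
  win <- hann_window(nt)
  num <- 0
  den <- 0
  # group bins into ~8-bin bands to stabilize envelopes
  groups <- split(seq_along(s$freq), (seq_along(s$freq) - 1) %/% 8)
  for (g in groups) {
    env <- colSums(s$mag[g, , drop = FALSE])
    if (max(env) <= 0) next
    wgt <- mean(env^2)
    mod <- abs(fft((env - mean(env)) * win))^2
    fmod <- (seq_along(mod) - 1) / nt * env_fs
    half <- fmod <= env_fs / 2
    in_band <- half & fmod >= band[1] & fmod <= band[2]
    above_dc <- half & fmod >= 0.5
    num <- num + wgt * sum(mod[in_band])
    den <- den + wgt * sum(mod[above_dc])
  }
  if (den <= 1e-12 * max(num, 1e-300) || den == 0) return(0)
  num / den
}

# checkerboard kernel with gaussian taper, half-width K frames
checker_kernel <- function(K) {
  i <- -K:K
  g <- exp(-0.5 * (i / (K / 2))^2)
  outer(g * sign(i), g * sign(i))
}

#' Spectral novelty
#'
#' Mean of a Gaussian-tapered checkerboard kernel (default span 200 ms)
#' convolved along the diagonal of the cosine self-similarity matrix of
#' STFT frames. Stationary sounds score near 0; spectrotemporal change
#' (e.g. a transition between two different sustained sounds) produces
#' novelty peaks. Symmetric under time reversal.
#'
#' @param w a [waveform()]
#' @param kernel_s kernel span in seconds (default 0.2)
#' @param s optional precomputed [stft()] of `w`
#' @return mean novelty (>= 0), `NA` if fewer than 2 frames
#' @export
spectral_novelty <- function(w, kernel_s = 0.2, s = NULL) {
  stopifnot(inherits(w, "Waveform"))
  if (is.null(s)) s <- stft(w$samples, w$rate)
  nt <- ncol(s$mag)
  if (nt < 2) return(NA_real_)
  M <- s$mag
  nrm <- sqrt(colSums(M^2))
  nrm[nrm == 0] <- 1
  U <- sweep(M, 2, nrm, "/")
  S <- crossprod(U)
  step_s <- diff(s$times[1:2])
  K <- max(2L, round(kernel_s / (2 * step_s)))
  if (nt < 2 * K + 1) return(0)
  ker <- checker_kernel(K)
  ker <- ker / sum(abs(ker))
  nov <- vapply((K + 1):(nt - K), function(t) {
    sum(ker * S[(t - K):(t + K), (t - K):(t + K)])
  }, numeric(1))
  mean(pmax(nov, 0))
}

#' Formant frequencies and apparent vocal tract length
#'
#' LPC formant analysis: the signal is decimated to ~11 kHz, pre-emphasized
#' (+6 dB/oct above 50 Hz), and each voiced 40 ms frame is fit with an LPC
#' model of order `2 + fs/1000`; roots of the prediction polynomial with
#' bandwidth < 600 Hz become formant candidates, and utterance F1-F4 are
#' the per-slot medians over frames. Apparent vocal tract length assumes a
#' uniform quarter-wave resonator: `F_i ~ (2i - 1) c / (4 L)` with
#' `c = 35000` cm/s, fit by regression through the origin of F1-F4 on the
#' odd multiples, so the neutral pattern 500/1500/2500/3500 Hz gives
#' 17.5 cm.
#'
#' @param w a [waveform()]
#' @param contour optional precomputed [track_pitch()] contour (used to
#'   select voiced frames; if `NULL` it is computed)
#' @param max_formant_freq analysis bandwidth (Hz), default 5500
#' @return list with `formants` (named F1-F4, Hz, `NA` where unstable) and
#'   `vtl_cm` (`NA` if fewer than 4 stable formants)
#' @export
formants_and_vtl <- function(w, contour = NULL, max_formant_freq = 5500) {
  stopifnot(inherits(w, "Waveform"))
  if (is.null(contour)) contour <- track_pitch(w)
  m <- max(1L, floor(w$rate / (2 * max_formant_freq)))
  d <- decimate_fir(w$samples, w$rate, m)
  fs <- d$fs
  x <- preemphasis(preemphasis(d$x, fs), fs) # ~+12 dB/oct against source tilt
  wl <- round(0.040 * fs)
  hop <- round(contour$step * fs)
  p <- round(2 + fs / 1000) + 2L
  win <- hann_window(wl)
  voiced_frames <- which(!is.na(contour$f0))
  cand <- list()
  for (i in seq_along(voiced_frames)) {
    st <- (voiced_frames[i] - 1L) * hop + 1L
    if (st + wl - 1L > length(x)) next
    fr <- x[st:(st + wl - 1L)] * win
    r <- as.numeric(stats::acf(fr, lag.max = p, plot = FALSE,
                               demean = FALSE, type = "covariance")$acf)
    a <- levinson(r, p)
    if (is.null(a)) next
    rts <- polyroot(c(1, -a))
    ang <- Arg(rts)
    keep <- ang > 0.001 & ang < pi - 0.001
    fr_hz <- ang[keep] / (2 * pi) * fs
    bw <- -fs / pi * log(pmin(Mod(rts[keep]), 0.9999))
    ok <- fr_hz > 150 & fr_hz < fs / 2 - 150 & bw < 400
    cand[[length(cand) + 1]] <- fr_hz[ok]
  }
  pool <- unlist(cand)
  formants <- setNames(rep(NA_real_, 4), paste0("F", 1:4))
  vtl <- NA_real_
  if (length(pool) >= 8) {
    # density peaks of the pooled candidates; spurious LPC roots scatter
    # while true formants recur across frames
    den <- stats::density(pool, bw = 80, from = 0, to = fs / 2, n = 512)
    pk <- which(diff(sign(diff(den$y))) < 0) + 1L
    pk <- pk[order(den$y[pk], decreasing = TRUE)]
    pk <- pk[seq_len(min(8, length(pk)))]
    pf <- den$x[pk]
    ph <- den$y[pk] / max(den$y[pk])
    # choose the formant spacing (quarter-wave pattern F_i ~ (2i-1)*delta/2)
    # best supported by the peaks: VTL 12.5-23 cm <-> delta 760-1400 Hz
    best <- -Inf
    best_delta <- NA_real_
    for (delta in seq(760, 1400, by = 10)) {
      slots <- (2 * (1:4) - 1) * delta / 2
      sc <- 0
      for (s in slots) {
        i_near <- which.min(abs(pf - s))
        if (abs(pf[i_near] - s) < 0.14 * s) sc <- sc + ph[i_near]
      }
      if (sc > best) {
        best <- sc
        best_delta <- delta
      }
    }
    slots <- (2 * (1:4) - 1) * best_delta / 2
    for (j in 1:4) {
      i_near <- which.min(abs(pf - slots[j]))
      if (abs(pf[i_near] - slots[j]) < 0.18 * slots[j]) {
        # refine off the density grid: median of the pooled candidates
        # supporting this peak
        close <- pool[abs(pool - pf[i_near]) < 0.08 * pf[i_near]]
        formants[j] <- if (length(close) >= 3) median(close) else pf[i_near]
      }
    }
    if (all(is.finite(formants))) {
      odd <- c(1, 3, 5, 7)
      slope <- sum(odd * formants) / sum(odd^2)
      vtl <- 35000 / (4 * slope)
    }
  } else if (length(pool)) {
    formants["F1"] <- median(pool[pool < 1000], na.rm = TRUE)
  }
  list(formants = formants, vtl_cm = vtl)
}

#' Assemble the 19-descriptor acoustic profile of an utterance
#'
#' Runs the pitch tracker and a shared STFT, then computes all 19
#' descriptors (see [profile_fields()]). Frame-dependent spectral measures
#' (harmonic energy/height, quartile, centroid, CPP, HNR) are evaluated in
#' voiced frames only, while loudness, novelty, roughness, and formants use
#' all (non-silent) frames. Per-frame values are aggregated by the mean for
#' energy measures and the median for f0-anchored measures (harmonics
#' height). Pitch-dependent fields are `NA` for fully unvoiced input; the
#' profile is still returned.
#'
#' @param w a [waveform()]
#' @param search_range pitch search range in Hz
#' @param contour optional precomputed pitch contour
#' @return one-row `data.frame` with the 19 descriptor columns
#' @export
acoustic_profile <- function(w, search_range = c(60, 600), contour = NULL) {
  stopifnot(inherits(w, "Waveform"))
  if (is.null(contour)) {
    contour <- track_pitch(w, search_range = search_range)
  }
  loud <- loudness_stats(w)
  ps <- pitch_stats(contour)
  s <- stft(w$samples, w$rate, wl_s = 0.040, step_s = 0.010)
  # f0 per STFT frame, from the nearest pitch frame
  pit_idx <- pmin(length(contour$f0),
                  pmax(1L, round(s$times / contour$step + 0.5)))
  f0_frame <- contour$f0[pit_idx]
  voiced <- which(!is.na(f0_frame))
  he <- hh <- q25 <- cen <- cppv <- hnrv <- rep(NA_real_, length(voiced))
  wl <- round(0.040 * w$rate)
  hopf <- round(0.010 * w$rate)
  xp <- c(w$samples, numeric(wl))
  for (j in seq_along(voiced)) {
    i <- voiced[j]
    mag <- s$mag[, i]
    f0 <- f0_frame[i]
    he[j] <- harmonic_energy(s$freq, mag, f0)
    hh[j] <- harmonics_height(s$freq, mag, f0)
    sm <- spectral_moments(s$freq, mag)
    q25[j] <- sm$q25
    cen[j] <- sm$centroid
    st0 <- (i - 1L) * hopf + 1L
    fr <- xp[st0:(st0 + wl - 1L)]
    cppv[j] <- cpp(fr, w$rate, search_range)
    hnrv[j] <- hnr(fr, w$rate, search_range)
  }
  fv <- formants_and_vtl(w, contour = contour)
  out <- data.frame(
    duration_s = wav_duration(w),
    loudness_db = loud$rms_db,
    loudness_iqr_db = loud$iqr_db,
    f0_median_st = ps$median_st,
    f0_iqr_st = ps$iqr_st,
    pitch_slope_st_s = ps$slope_st_s,
    infl_fast_per_s = count_inflections(contour, 10),
    infl_slow_per_s = count_inflections(contour, 1),
    fm_depth_st = fm_depth(contour),
    harm_energy_prop = if (length(voiced)) mean(he, na.rm = TRUE) else NA_real_,
    harm_height_hz = if (length(voiced)) median(hh, na.rm = TRUE) else NA_real_,
    spec_q25_hz = if (length(voiced)) mean(q25, na.rm = TRUE) else NA_real_,
    spec_centroid_hz = if (length(voiced)) mean(cen, na.rm = TRUE) else NA_real_,
    novelty = spectral_novelty(w, s = s),
    cpp_db = if (length(voiced)) mean(cppv, na.rm = TRUE) else NA_real_,
    hnr = if (length(voiced)) mean(hnrv, na.rm = TRUE) else NA_real_,
    roughness_prop = roughness(w),
    f1_hz = unname(fv$formants["F1"]),
    vtl_cm = fv$vtl_cm
  )
  stopifnot(identical(names(out), profile_fields()))
  out
}
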