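#' Pitch contours
#'
#' A `PitchContour` holds the fundamental frequency tracked every `step`
#' seconds (default 25 ms, giving a contour Nyquist of 20 Hz, see
#' [contour_nyquist()]). Unvoiced frames are `NA`. All intonation and
#' tremor statistics in the package are defined on this container.
#'
#' @param f0 numeric vector of f0 values in Hz, `NA` = unvoiced
#' @param step frame step in seconds
#' @param search_range f0 search range `c(min, max)` in Hz
#' @param salience optional per-frame loudness (linear RMS), used to time
#'   the tremor manipulation
#' @return object of class `PitchContour` with fields `f0`, `step`,
#'   `times`, `search_range`, `salience`
#' @export
pitch_contour <- function(f0, step = 0.025, search_range = c(60, 600),
                          salience = NULL) {
  stopifnot(step > 0, length(search_range) == 2)
  structure(list(
    f0 = as.numeric(f0), step = step,
    times = (seq_along(f0) - 0.5) * step,
    search_range = search_range,
    salience = salience
  ), class = "PitchContour")
}

#' @export
print.PitchContour <- function(x, ...) {
  nv <- sum(!is.na(x$f0))
  cat(sprintf("<PitchContour: %d frames @ %.0f ms, %d voiced, median %.1f Hz>\n",
              length(x$f0), x$step * 1000, nv,
              if (nv) median(x$f0, na.rm = TRUE) else NA_real_))
  invisible(x)
}

#' Track the fundamental frequency of a waveform
#'
#' Autocorrelation pitch tracker. For each 40 ms frame (stepped every
#' `step` s) the unbiased normalized autocorrelation is searched for
#' candidate periods inside `search_range`; frames whose best candidate
#' falls below the voicing threshold (normalized peak >= 0.45 and frame
#' RMS >= -45 dB re the loudest frame) are marked unvoiced. Octave jumps
#' are suppressed by a Viterbi-style best path over candidates with a
#' per-semitone transition cost, replacing the interactive manual
#' correction used with real recordings.
#'
#' @param w a [waveform()]
#' @param search_range numeric `c(min, max)` Hz, inside `(0, rate/2)`
#' @param step frame step in seconds (default 0.025)
#' @param voicing_threshold minimum normalized autocorrelation (default 0.45)
#' @param silence_db frame RMS floor relative to the loudest frame (dB)
#' @return a [pitch_contour()]
#' @export
track_pitch <- function(w, search_range = c(60, 600), step = 0.025,
                        voicing_threshold = 0.45, silence_db = -45) {
  stopifnot(inherits(w, "Waveform"))
  if (length(w$samples) == 0) stop("empty waveform")
  fs <- w$rate
  if (search_range[1] <= 0 || search_range[2] >= fs / 2) {
    stop("search_range must lie inside (0, rate/2)")
  }
  wl <- round(0.040 * fs)
  hop <- round(step * fs)
  n_frames <- max(1L, ceiling(length(w$samples) / hop))
  xp <- c(w$samples, numeric(wl + hop))
  starts <- (seq_len(n_frames) - 1L) * hop + 1L
  idx <- outer(seq_len(wl) - 1L, starts, `+`)
  frames <- matrix(xp[idx], nrow = wl)
  rms <- sqrt(colMeans(frames^2))
  max_rms <- max(rms)
  lag_min <- max(2L, floor(fs / search_range[2]))
  lag_max <- min(wl - 2L, ceiling(fs / search_range[1]))
  if (lag_max <= lag_min) stop("search_range too narrow for the frame length")
  nfft <- next_pow2(2 * wl)
  fr <- rbind(frames, matrix(0, nfft - wl, n_frames))
  sp <- mvfft(fr)
  ac <- Re(mvfft(sp * Conj(sp), inverse = TRUE)) / nfft
  lags <- lag_min:lag_max
  # unbiased normalized autocorrelation
  norm <- ac[1, ]
  norm[norm <= 0] <- Inf
  r <- sweep(ac[lags + 1, , drop = FALSE], 2, norm, "/")
  r <- r * (wl / (wl - lags))
  cands <- vector("list", n_frames)
  voiced_ok <- logical(n_frames)
  for (i in seq_len(n_frames)) {
    if (max_rms <= 0 || 20 * log10(rms[i] / max_rms) < silence_db) next
    ri <- r[, i]
    peaks <- which(diff(sign(diff(ri))) < 0) + 1L
    if (!length(peaks)) next
    # octave cost: favor shorter lags when peaks are near-equal, so the
    # subharmonic at 2x the period does not win on the unbiased correction
    score <- ri[peaks] - 0.07 * log2(lags[peaks] / lag_min)
    ord <- peaks[order(score, decreasing = TRUE)]
    ord <- ord[seq_len(min(4, length(ord)))]
    strengths <- ri[ord]
    if (max(ri[peaks]) < voicing_threshold) next
    keep <- strengths >= max(voicing_threshold * 0.8,
                             0.8 * strengths[1])
    keep[1] <- TRUE
    # parabolic interpolation of the peak lag
    lag_est <- vapply(ord[keep], function(p) {
      if (p <= 1 || p >= length(ri)) return(lags[p])
      a <- ri[p - 1]; b <- ri[p]; cc <- ri[p + 1]
      d <- (a - cc) / (2 * (a - 2 * b + cc))
      if (!is.finite(d) || abs(d) > 1) d <- 0
      lags[p] + d
    }, numeric(1))
    voiced_ok[i] <- TRUE
    cands[[i]] <- list(f0 = fs / lag_est, strength = strengths[keep])
  }
  f0 <- rep(NA_real_, n_frames)
  # Viterbi path per voiced run: cost = -log(strength) + 0.35 * |delta st|
  runs <- rle(voiced_ok)
  pos <- cumsum(c(1, runs$lengths))
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    span <- pos[k]:(pos[k + 1] - 1)
    prev_cost <- -log(pmax(cands[[span[1]]]$strength, 1e-6))
    prev_f <- cands[[span[1]]]$f0
    back <- vector("list", length(span))
    for (j in seq_along(span)[-1]) {
      f_j <- cands[[span[j]]]$f0
      s_j <- pmax(cands[[span[j]]]$strength, 1e-6)
      trans <- abs(outer(hz_to_st(prev_f), hz_to_st(f_j), "-")) * 0.35
      tot <- sweep(trans, 1, prev_cost, "+")
      best_prev <- apply(tot, 2, which.min)
      prev_cost <- tot[cbind(best_prev, seq_along(f_j))] - log(s_j)
      back[[j]] <- best_prev
      prev_f <- f_j
    }
    sel <- which.min(prev_cost)
    for (j in rev(seq_along(span))) {
      f0[span[j]] <- cands[[span[j]]]$f0[sel]
      if (j > 1) sel <- back[[j]][sel]
    }
  }
  # clamp estimates within 3% of the range edges; drop anything further out
  f0 <- pmin(pmax(f0, ifelse(f0 > search_range[1] / 1.03, search_range[1], NA)),
             ifelse(f0 < search_range[2] * 1.03, search_range[2], NA))
  # despike: residual octave glitches (frames deviating > 4 st from a
  # 5-frame running median) are marked unvoiced — the automatic stand-in
  # for interactive manual pitch correction
  if (any(!is.na(f0)) && length(f0) >= 5) {
    st <- hz_to_st(f0)
    med5 <- stats::runmed(na_interp(st), 5, endrule = "median")
    spike <- abs(st - med5) > 4
    # sustained octave runs survive a short running median; anything more
    # than 7 st from the utterance median is not plausible intonation
    spike <- spike | abs(st - median(st, na.rm = TRUE)) > 7
    f0[!is.na(st) & spike] <- NA_real_
  }
  pitch_contour(f0, step = step, search_range = search_range, salience = rms)
}

# semitone-scale contour with unvoiced gaps interpolated; returns NULL if
# fewer than min_voiced voiced frames
contour_st_filled <- function(c, min_voiced = 2) {
  v <- hz_to_st(c$f0)
  if (sum(!is.na(v)) < min_voiced) return(NULL)
  na_interp(v)
}

#' Low-pass filter a pitch contour
#'
#' Zero-phase low-pass (frequency-domain, raised-cosine transition from
#' `0.9 * cutoff` to `1.1 * cutoff`) applied to the contour on the semitone
#' scale. Unvoiced gaps are bridged by linear interpolation for filtering
#' and restored to `NA` afterwards.
#'
#' @param c a [pitch_contour()]
#' @param cutoff low-pass cutoff in Hz; must be below the contour Nyquist
#'   `1/(2*step)`
#' @return a filtered [pitch_contour()]
#' @export
lowpass_contour <- function(c, cutoff) {
  stopifnot(inherits(c, "PitchContour"))
  if (cutoff >= contour_nyquist(c$step)) {
    stop("cutoff must be below the contour Nyquist frequency ",
         contour_nyquist(c$step), " Hz")
  }
  st <- contour_st_filled(c)
  if (is.null(st)) return(c)
  y <- fft_filter(st, fs = 1 / c$step, f_pass_hi = 0.9 * cutoff,
                  f_stop_hi = 1.1 * cutoff)
  f0 <- st_to_hz(y)
  f0[is.na(c$f0)] <- NA_real_
  out <- c
  out$f0 <- f0
  out
}

#' Count pitch inflections per second
#'
#' An inflection is a sign change of the first difference of the low-passed
#' voiced contour (computed within each contiguous voiced run); the rate is
#' the total count divided by the voiced duration. With a 10 Hz cutoff this
#' counts rapid inflections, with 1 Hz only slow intonation movements
#' survive, so the 1 Hz count can never exceed the 10 Hz count.
#'
#' @inheritParams lowpass_contour
#' @return inflections per second, or `NA` if fewer than 3 voiced frames
#' @export
count_inflections <- function(c, cutoff) {
  stopifnot(inherits(c, "PitchContour"))
  voiced <- !is.na(c$f0)
  if (sum(voiced) < 3) return(NA_real_)
  lp <- lowpass_contour(c, cutoff)
  st <- hz_to_st(lp$f0)
  count <- 0L
  runs <- rle(voiced)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in seq_along(runs$values)) {
    if (!runs$values[k] || runs$lengths[k] < 3) next
    seg <- st[starts[k]:ends[k]]
    d <- diff(seg)
    d <- d[abs(d) > 1e-6] # numerical floor: flat is flat
    if (length(d) >= 2) count <- count + sum(diff(sign(d)) != 0)
  }
  count / (sum(voiced) * c$step)
}

#' Depth of frequency modulation in the vocal-tremor band
#'
#' Band-passes the semitone-scale contour in `band` (default 8-14 Hz, the
#' range associated with vocal tremor) and measures modulation events as
#' successive local extrema of the filtered contour: event depth is half
#' the absolute difference between consecutive extrema. Unvoiced gaps
#' shorter than `bridge_s` are bridged by linear interpolation on the
#' semitone scale; only voiced stretches of at least `min_stretch_s` are
#' analyzed. Event depths pooled over stretches are summarized by their
#' upper quartile (`summary_quantile = 0.75`): natural tremor comes in
#' brief episodes, and an episode covering less than half of the voiced
#' frames moves the median of event depths only marginally, whereas the
#' upper quartile registers it. For stationary FM (the oracle cases) the
#' quartile and the median agree to within the event-noise scatter.
#'
#' The estimate is invariant to transposing the whole contour because the
#' band-pass removes the contour mean.
#'
#' @param c a [pitch_contour()]
#' @param band numeric `c(lo, hi)` Hz; `hi` must be below the contour
#'   Nyquist
#' @param bridge_s maximum unvoiced gap to interpolate across (s)
#' @param min_stretch_s minimum analyzable voiced stretch (s)
#' @param summary_quantile quantile of event depths reported (default 0.75)
#' @return FM depth in semitones, or `NA` if no analyzable stretch
#' @export
fm_depth <- function(c, band = c(8, 14), bridge_s = 0.25, min_stretch_s = 0.3,
                     summary_quantile = 0.75) {
  stopifnot(inherits(c, "PitchContour"), length(band) == 2, band[1] < band[2])
  if (band[2] >= contour_nyquist(c$step)) {
    stop("band upper edge must be below the contour Nyquist frequency")
  }
  voiced <- !is.na(c$f0)
  if (!any(voiced)) return(NA_real_)
  # bridge short gaps
  bridged <- voiced
  runs <- rle(voiced)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in seq_along(runs$values)) {
    if (runs$values[k]) next
    interior <- k > 1 && k < length(runs$values)
    if (interior && runs$lengths[k] * c$step < bridge_s) {
      bridged[starts[k]:ends[k]] <- TRUE
    }
  }
  st_full <- na_interp(hz_to_st(c$f0))
  min_len <- ceiling(min_stretch_s / c$step)
  depths <- numeric(0)
  runs2 <- rle(bridged)
  ends2 <- cumsum(runs2$lengths)
  starts2 <- ends2 - runs2$lengths + 1L
  for (k in seq_along(runs2$values)) {
    if (!runs2$values[k] || runs2$lengths[k] < min_len) next
    seg <- st_full[starts2[k]:ends2[k]]
    y <- fft_filter(seg - mean(seg), fs = 1 / c$step,
                    f_pass_lo = band[1], f_stop_lo = band[1] - 1,
                    f_pass_hi = band[2], f_stop_hi = band[2] + 1)
    # the filtered contour is band-limited, so sinc interpolation recovers
    # true extrema between the 25 ms samples
    y <- upsample_fft(y, 4L)
    ext <- which(diff(sign(diff(y))) != 0) + 1L
    if (length(ext) >= 2) {
      depths <- c(depths, abs(diff(y[ext])) / 2)
    }
  }
  if (!length(depths)) return(NA_real_)
  unname(quantile(depths, summary_quantile))
}

#' Pitch distribution statistics
#'
#' Median, inter-quartile range, and mean absolute slope of the voiced
#' contour on the semitone scale (re 1 Hz). The median uses the midpoint
#' convention on the Hz scale for even counts (the Hz midpoint is computed
#' first, then converted to semitones); the IQR and slope are computed on
#' the semitone scale. Slope averages `|delta semitones| / step` over pairs
#' of adjacent voiced frames.
#'
#' @param c a [pitch_contour()]
#' @return list with `median_st`, `iqr_st`, `slope_st_s` (each `NA` if
#'   fewer than 2 voiced frames)
#' @export
pitch_stats <- function(c) {
  stopifnot(inherits(c, "PitchContour"))
  hz <- c$f0[!is.na(c$f0)]
  if (length(hz) < 2) {
    return(list(median_st = NA_real_, iqr_st = NA_real_, slope_st_s = NA_real_))
  }
  st <- hz_to_st(c$f0)
  adj <- which(!is.na(st[-1]) & !is.na(st[-length(st)]))
  slope <- if (length(adj)) {
    mean(abs(st[adj + 1] - st[adj])) / c$step
  } else {
    NA_real_
  }
  list(
    median_st = hz_to_st(median(hz)),
    iqr_st = diff(quantile(hz_to_st(hz), c(0.25, 0.75), names = FALSE)),
    slope_st_s = slope
  )
}

#' Serialize a pitch contour to CSV
#' @param c a [pitch_contour()]
#' @param path output file
#' @export
write_contour_csv <- function(c, path) {
  write.csv(data.frame(time_s = c$times, f0_hz = c$f0,
                       voiced = !is.na(c$f0)),
            path, row.names = FALSE)
  invisible(path)
}
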