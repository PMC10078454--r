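# Shared signal-processing primitives: STFT, zero-phase FFT filters,
# resonators, FIR decimation. All functions operate on plain numeric
# vectors; sample rates are passed explicitly.

next_pow2 <- function(n) 2^ceiling(log2(n))

gaussian_window <- function(n, sigma_frac = 1 / 6) {
  t <- seq_len(n) - (n + 1) / 2
  exp(-0.5 * (t / (sigma_frac * n))^2)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

#' Short-time Fourier transform
#'
#' Frames the signal with a tapered window and returns linear magnitude
#' spectra. Frames are centered every `step_s` seconds starting at
#' `wl_s / 2`; the signal is zero-padded at the tail so the last partial
#' frame is kept.
#'
#' @param x numeric samples in `[-1, 1]`
#' @param rate sampling rate (Hz)
#' @param wl_s window length (s), default 0.040
#' @param step_s frame step (s), default 0.010
#' @param window `"gaussian"` (default, sd = wl/6) or `"hann"`
#' @param zp zero-padding factor for the FFT (default 1)
#' @return list with `mag` (freq x time matrix), `freq` (Hz), `times` (s,
#'   frame centers), `phase` (complex spectra), `wl`, `hop` (samples)
#' @keywords internal
stft <- function(x, rate, wl_s = 0.040, step_s = 0.010,
                 window = c("gaussian", "hann"), zp = 1) {
  window <- match.arg(window)
  wl <- max(16, round(wl_s * rate))
  hop <- max(1, round(step_s * rate))
  win <- if (window == "gaussian") gaussian_window(wl) else hann_window(wl)
  nfft <- next_pow2(wl) * zp
  starts <- seq(1, max(1, length(x) - 1), by = hop)
  xp <- c(x, numeric(wl))
  idx <- outer(seq_len(wl) - 1L, starts, `+`)
  frames <- matrix(xp[idx], nrow = wl) * win
  fr <- rbind(frames, matrix(0, nfft - wl, ncol(frames)))
  sp <- mvfft(fr)
  nb <- nfft %/% 2 + 1
  sp <- sp[seq_len(nb), , drop = FALSE]
  list(
    mag = abs(sp), cspec = sp,
    freq = (seq_len(nb) - 1) * rate / nfft,
    times = (starts - 1 + wl / 2) / rate,
    wl = wl, hop = hop, nfft = nfft, rate = rate, win = win
  )
}

# Zero-phase frequency-domain filter with raised-cosine transitions.
# Response is 1 on [f_pass_lo, f_pass_hi], 0 outside [f_stop_lo, f_stop_hi],
# half-cosine in between. Pass f_stop_lo = NULL for a low-pass,
# f_stop_hi = NULL for a high-pass. The input is reflected at both ends to
# suppress edge transients; zero-phase by construction.
fft_filter <- function(x, fs, f_pass_lo = NULL, f_pass_hi = NULL,
                       f_stop_lo = NULL, f_stop_hi = NULL) {
  n <- length(x)
  if (n < 4) return(x)
  # detrend through the endpoints so the reflected extension is continuous;
  # the line is pure low-frequency content: re-added for a low-pass,
  # dropped when a lower band edge removes DC
  trend <- x[1] + (x[n] - x[1]) * (seq_len(n) - 1) / (n - 1)
  x <- x - trend
  pad <- min(n - 1, max(8, round(n / 2)))
  xp <- c(rev(x[seq_len(pad) + 1]), x, x[n - seq_len(pad)])
  np <- length(xp)
  f <- (seq_len(np) - 1) / np * fs
  f <- pmin(f, fs - f) # two-sided -> folded frequency
  resp <- rep(1, np)
  if (!is.null(f_pass_hi)) { # upper edge
    hi_stop <- if (is.null(f_stop_hi)) f_pass_hi else f_stop_hi
    up <- f > f_pass_hi & f < hi_stop
    resp[f >= hi_stop] <- 0
    resp[up] <- 0.5 + 0.5 * cos(pi * (f[up] - f_pass_hi) / (hi_stop - f_pass_hi))
  }
  if (!is.null(f_pass_lo) && f_pass_lo > 0) { # lower edge
    lo_stop <- if (is.null(f_stop_lo)) f_pass_lo else f_stop_lo
    dn <- f < f_pass_lo & f > lo_stop
    resp[f <= lo_stop] <- 0
    resp[dn] <- 0.5 + 0.5 * cos(pi * (f_pass_lo - f[dn]) / (f_pass_lo - lo_stop))
  }
  y <- Re(fft(fft(xp) * resp, inverse = TRUE)) / np
  y <- y[pad + seq_len(n)]
  if (is.null(f_pass_lo) || f_pass_lo <= 0) y <- y + trend
  y
}

# Second-order resonator (two-pole) filter, unit gain at the resonance.
resonator <- function(x, f, bw, fs) {
  r <- exp(-pi * bw / fs)
  theta <- 2 * pi * f / fs
  a1 <- 2 * r * cos(theta)
  a2 <- -r^2
  g <- (1 - r) * sqrt(1 - 2 * r * cos(2 * theta) + r^2) # approx unit peak gain
  y <- stats::filter(g * x, c(a1, a2), method = "recursive")
  as.numeric(y)
}

preemphasis <- function(x, fs, cutoff = 50) {
  a <- exp(-2 * pi * cutoff / fs)
  c(x[1], x[-1] - a * x[-length(x)])
}

# Windowed-sinc FIR low-pass + integer decimation.
decimate_fir <- function(x, fs, m, ntaps = 64) {
  if (m <= 1) return(list(x = x, fs = fs))
  fc <- 0.45 / m # normalized cutoff
  k <- seq(-ntaps, ntaps)
  h <- 2 * fc * sinc(2 * fc * k) * hann_window(2 * ntaps + 1)
  h <- h / sum(h)
  nx <- length(x)
  xp <- c(numeric(ntaps), x, numeric(ntaps))
  y <- stats::filter(xp, h, sides = 2)
  y <- y[ntaps + seq_len(nx)]
  y[is.na(y)] <- 0
  list(x = y[seq(1, nx, by = m)], fs = fs / m)
}

sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

# Band-limited (FFT zero-padding) upsampling by an integer factor m.
upsample_fft <- function(x, m) {
  n <- length(x)
  if (m <= 1 || n < 4) return(x)
  X <- fft(x)
  half <- n %/% 2
  Xp <- complex(real = numeric(n * m))
  Xp[seq_len(half + 1)] <- X[seq_len(half + 1)]
  Xp[n * m - seq_len(n - half - 1) + 1] <- X[n - seq_len(n - half - 1) + 1]
  Re(fft(Xp, inverse = TRUE)) * m / (n * m)
}

# Levinson-Durbin recursion: autocorrelation -> LPC coefficients a_1..a_p
# (prediction filter 1 - sum a_i z^-i).
levinson <- function(r, p) {
  a <- numeric(p)
  e <- r[1]
  if (e <= 0) return(NULL)
  for (i in seq_len(p)) {
    acc <- r[i + 1]
    if (i > 1) acc <- acc - sum(a[seq_len(i - 1)] * r[i:2])
    k <- acc / e
    a_new <- a
    a_new[i] <- k
    if (i > 1) a_new[seq_len(i - 1)] <- a[seq_len(i - 1)] - k * a[(i - 1):1]
    a <- a_new
    e <- e * (1 - k^2)
    if (e <= 0) return(NULL)
  }
  a
}

# Linear interpolation over NA runs; leading/trailing NAs filled with the
# nearest defined value. Returns all-NA input unchanged.
na_interp <- function(v) {
  ok <- !is.na(v)
  if (!any(ok) || all(ok)) return(v)
  approx(which(ok), v[ok], xout = seq_along(v), rule = 2)$y
}

# Evaluate an expression under a fixed seed without disturbing the
# caller's RNG state (expr is forced lazily, after set.seed).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Small integer hash for deriving substream seeds; stays below 2^31.
child_seed <- function(seed, ...) {
  parts <- unlist(list(seed, ...))
  h <- 0
  for (p in parts) {
    for (ch in utf8ToInt(paste0(p))) {
      h <- (h * 31 + ch) %% 2147483629
    }
  }
  as.integer(h + 1)
}
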