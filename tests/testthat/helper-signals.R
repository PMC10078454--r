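# Constructed signals used as oracles across test files.

FS <- 44100

tone <- function(freq, dur = 1, amp = 0.5, fs = FS) {
  waveform(amp * sin(2 * pi * freq * (seq_len(round(dur * fs)) - 1) / fs), fs)
}

# tone with sinusoidal frequency modulation (depth in semitones)
fm_tone <- function(carrier, rate_hz, depth_st, dur = 1, amp = 0.5, fs = FS) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  f0 <- carrier * 2^(depth_st * sin(2 * pi * rate_hz * t) / 12)
  waveform(amp * sin(2 * pi * cumsum(f0) / fs), fs)
}

# analytic pitch contour (25 ms frames) with sinusoidal FM
fm_contour <- function(carrier, rate_hz, depth_st, dur = 2, step = 0.025) {
  tt <- seq(step / 2, dur, by = step)
  pitch_contour(carrier * 2^(depth_st * sin(2 * pi * rate_hz * tt) / 12),
                step = step)
}

saw_frame <- function(f0, n_harm, dur = 0.04, fs = FS) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  rowSums(sapply(seq_len(n_harm), function(k) sin(2 * pi * k * f0 * t) / k))
}

# memoized small corpus shared across test files (8 speakers x 4 x 2)
small_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- corpus_config(n_female = 4, n_male = 4, takes = 2, seed = 42)
      corp <- generate_corpus(cfg)
      feats <- corpus_features(corp)
      cache <<- list(config = cfg, corpus = corp, features = feats)
    }
    cache
  }
})

# iid feature table (no audio) for statistical-layer tests
simulate_feature_table <- function(n_speakers = 33, takes = 3,
                                   effect = c(relaxed = 0, real = 0,
                                              concealed = 0, pretended = 0),
                                   feature = "f0_median_st") {
  grid <- expand.grid(speaker = sprintf("s%02d", seq_len(n_speakers)),
                      condition = conditions(), take = seq_len(takes))
  grid$sex <- ifelse(as.integer(factor(grid$speaker)) <= n_speakers / 2,
                     "female", "male")
  grid$channel <- sample(c("A", "B"), nrow(grid), replace = TRUE)
  spk_int <- rnorm(n_speakers)
  names(spk_int) <- sprintf("s%02d", seq_len(n_speakers))
  grid[[feature]] <- spk_int[grid$speaker] +
    effect[as.character(grid$condition)] + rnorm(nrow(grid), 0, 0.5)
  grid$condition <- factor(grid$condition, levels = conditions())
  grid
}
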