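---
title: "Methods: synthesizing and measuring vocal signatures of physical effort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthesizing and measuring vocal signatures of physical effort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices, and numerical
conventions behind `effortvoice`, in the spirit of a methods section: what
each stage assumes, which constants are free design choices, and what a
green test does and does not establish.

## The problem

Brief, intense physical effort (think of an isometric core hold) changes
the voice in characteristic ways: loudness and fundamental frequency rise,
phonation becomes pressed (energy shifts into higher harmonics), speech
accelerates, and the pitch contour acquires involuntary frequency
modulation around 10 Hz — vocal tremor, plausibly a mechanical side effect
of large motor units firing in heavily loaded muscles. Speakers can
exaggerate or conceal the deliberate components (pitch, loudness, voice
quality) but the tremor band is much harder to control, which makes it a
candidate *honest cue* of true exertion. The package operationalizes this
whole story on synthetic audio so that every estimator can be checked
against ground truth.

## Synthetic voices

`synth_utterance()` is a deliberately simple Klatt-style source-filter
synthesizer: a harmonic source with a spectral tilt of `source_tilt`
dB/octave (default −12, the textbook glottal rolloff), cycle-level jitter
(default 1%) and shimmer (3%), aspiration noise (−25 dB), filtered through
four second-order resonators (default 500/1500/2500/3500 Hz — the neutral
quarter-wave tube — scaled per speaker by an apparent-vocal-tract-length
factor). Utterances have six syllables (≈1.74 s, one unvoiced), with a
gentle declination (−1.5 st over the utterance), random accent wiggles,
and a phrase accent on the fifth syllable, mimicking a short question.
Harmonics are band-limited below 8 kHz so that descriptor values are
robust to resampling.

Speaker distributions are conventions, not published values (the study
reports no speaker-level acoustics): female/male mean f0 210/120 Hz with
between-speaker SD 2 st; formant scale factor 1.15 for females with 5%
scatter; tilt SD 2 dB/oct; habitual level SD 2 dB; speech-rate SD 8%.
The last two matter statistically: without between-speaker variance in
level and rate, the standardized scale of those features would consist
almost entirely of take-to-take noise and the mixed-model contrasts would
be much less stable than in real corpora, where speakers differ
substantially in rate and level.

Condition offsets (pitch in semitones, level in dB, tilt in dB/oct,
duration scale, injected tremor SD in semitones) are additive per
condition with an all-zero relaxed baseline. The defaults point in the
observed directions; `calibrate_offsets()` tunes them to standardized
targets (below). The two-microphone "recording channel" of the original
design is emulated as a random binary label whose only acoustic effect is
a +0.8 dB/oct tilt shift on channel B, so the statistical channel
covariate does real work.

## Pitch tracking and contour statistics

`track_pitch()` computes the unbiased normalized autocorrelation of 40 ms
frames every 25 ms, takes up to four candidate periods per frame (local
maxima over the 60–600 Hz search range, with a 0.07-per-octave penalty on
longer lags so the 2×-period subharmonic does not win on the unbiased
correction), marks frames unvoiced when the best normalized peak is below
0.45 or frame RMS is 45 dB below the loudest frame, and resolves octave
jumps with a Viterbi path (transition cost 0.35 per semitone). A final
despiking pass marks frames more than 4 st away from a 5-frame running
median (or more than 7 st from the utterance median) as unvoiced:
isolated octave glitches on high-pitched utterances otherwise leak large
excursions into the 8-14 Hz band and corrupt the tremor statistics.
Together these replace the interactive manual pitch correction used with
real recordings; with the clean synthetic source the tracker's median
error is a small fraction of a semitone.

With a 25 ms step the contour Nyquist is 20 Hz, so the 8–14 Hz tremor
band is analyzable but close to the limit; `fm_depth()` therefore
sinc-interpolates (FFT zero-padding) the band-passed contour before
locating extrema, otherwise a 10 Hz sinusoid sampled at 4 points/cycle
would systematically underestimate its own depth. FM depth is defined as:
bridge unvoiced gaps shorter than 0.25 s by linear interpolation on the
semitone scale, band-pass each voiced stretch of at least 0.3 s in
8–14 Hz (raised-cosine transitions one Hz wide), call each pair of
successive local extrema an event with depth half their absolute
difference, and report the upper quartile of the pooled event depths.
The quartile (rather than the median) is a deliberate choice: natural
tremor arrives in brief episodes, and the resynthesis manipulation
concentrates its modulation under a Gaussian envelope spanning half the
sound — a median over pooled events is mathematically unable to respond
more than marginally to an episode covering a minority of events,
whereas the validated behavior of the manipulation (a considerable FM
increase for tremor, a marginal one for the control) requires the
estimator to register exactly such episodes. For stationary FM the
quartile and median agree to within event-noise scatter, so the
constructed-signal oracles are unaffected. The
exact estimator used on the real data is not printed anywhere; this
operationalization is pinned down by its property tests (unit response to
in-band FM, rejection of 3 Hz FM, transposition invariance).

All contour filters are zero-phase frequency-domain filters with
raised-cosine transitions (low-pass: 0.9–1.1 × cutoff), applied after
detrending through the endpoints and reflecting at both edges; this keeps
a monotone contour monotone (no spurious inflections) while preserving a
0.5 Hz drift through the 1 Hz low-pass to within 5%. Inflections are sign
changes of the first difference of the low-passed voiced contour (10 Hz =
"fast", 1 Hz = "slow"), with differences below 1e−6 st treated as flat.

Semitones are always relative to 1 Hz. The even-count median of pitch
uses the midpoint convention **on the Hz scale** and is then converted
(so `median({200,200,300,300})` is the semitone value of 250 Hz); the IQR
and slope are computed on the semitone scale.

## Spectral descriptors

The 19-field profile (`acoustic_profile()`) shares one STFT (40 ms
Gaussian windows, sd = wl/6, 10 ms step). Voiced-frame measures: energy
in harmonics (energy proportion above 1.5·f0 — energy, not magnitude;
flagged as a sensitivity choice), harmonics height (highest multiple of
f0 whose mainlobe median stands 6 dB above both inter-harmonic side
medians, dominates its ±f0/2 neighborhood, and sits within the 60 dB
analysis dynamic range; scanning stops after two consecutive misses),
spectral quartile and centroid (energy distribution), cepstral peak
prominence (cepstral peak in the pitch quefrency band minus the
regression trend), and HNR (max normalized autocorrelation, clamped to
[0,1]). All-frame measures: loudness (per-frame RMS dB above a −45 dB
silence floor; mean and IQR), spectral novelty (Gaussian-tapered
checkerboard kernel, 200 ms span, on the cosine self-similarity matrix),
roughness (energy share of 30–150 Hz in the modulation spectrum of
8-bin band envelopes; both the band edges and the envelope parameters are
design constants, unprinted in the source study), and formants/VTL.

Formant analysis decimates to ≈11 kHz, pre-emphasizes twice (the −12
dB/oct source tilt otherwise starves the LPC of high-frequency
structure), fits order-(2 + fs/1000 + 2) LPC per voiced frame, pools root
candidates (bandwidth < 400 Hz) over frames, and picks density peaks
supported by a quarter-wave pattern search (formant spacing scanned over
VTL 12.5–23 cm). This pooled pattern-guided selection is markedly more
robust on tilted harmonic sources than per-frame slot medians, at the
cost of assuming roughly uniform-tube spacing — acceptable here because
the generator is a uniform-tube model and only F1 and VTL feed the
statistics. VTL comes from a regression through the origin of F1–F4 on
the odd multiples, speed of sound 35 000 cm/s, so 500/1500/2500/3500 Hz
gives exactly 17.5 cm.

Aggregation: mean over frames for energy-type measures, median for
f0-anchored ones (harmonics height), IQR where the descriptor itself is a
variability measure. Fully unvoiced input yields a profile with NA in the
pitch-dependent fields; NAs serialize as empty CSV cells, never sentinel
numbers.

## Tremor resynthesis

`tremor_factor_contour()` draws independent Gaussian deviates at 20
anchors/s (SD 1 st for tremor; 0.17 st = 1% for the control), connects
them with a monotone cubic spline, multiplies by the envelope — Gaussian
with sd = 0.5 × duration/4 centered on the loudest voiced stretch
(argmax of a 300 ms moving average of voiced RMS) for tremor, constant
for the control — and exponentiates to frequency factors. The spline
choice and the envelope width constant are design choices (the source
procedure's "rerun until natural" manual step is replaced by a fixed
seed per stimulus).

`shift_pitch()` is a bin-remapping phase vocoder: 2048-sample frames,
hop 512, Hann analysis/synthesis windows, per-bin instantaneous frequency
from phase differences, dominant-contributor phase locking, and formant
preservation by dividing each frame's magnitude by its 40-coefficient
cepstral envelope before remapping and re-imposing the envelope at the
target bin. Identity factors reconstruct the input (correlation > 0.99);
a factor of 1.06 moves F1 by < 5%. Output RMS is matched to the input.

A note on units: the source text equates 1 semitone with "~8.3%", but
2^(1/12) − 1 = 5.95%; 8.3% is 1/12 on the wrong (linear) scale. The
package defines the conversion as st = 12·log2(1 + p/100) throughout,
which reproduces the other printed conversion (1% = 0.17 st) exactly.

## Statistical layer

`standardize_features()` log-transforms the Hz-unit descriptors
(harmonics height, quartile, centroid, F1) and z-scores all 19 across the
corpus; the stored transform makes the operation reproducible and
invertible. `estimate_condition_effects()` fits, per standardized
feature, `y ~ condition + sex + channel + (1 | speaker)` by REML (lme4)
and reports each condition's contrast against relaxed with a 95% Wald
interval; the posterior-median-plus-CI contract of the original Bayesian
multivariate model is thus met with frequentist machinery, which the
coverage tests validate (nominal 95% ± 3% on null simulations). Singular
fits fall back to a fixed-effects model with speaker-cluster-robust
(CR1) intervals, flagged in the output. The "robust" flag marks
contrasts with a one-sided tail probability of at least 99%
(|z| > 2.326), mirroring the convention of graying out uncertain effects.

`rf_classify()` is a from-scratch random forest (Rcpp): bagged CART with
Gini splits, √p features per node, grown to purity, out-of-bag voting;
repetitions differ only by RNG stream and are summarized as cellwise
medians (row-renormalized) with 2.5/97.5 percentile coverage intervals.
No pre-installed RF implementation exists in the target environment,
which is why the package carries its own.

`simulate_ratings()` / `fit_rating_model()` close the perception loop
with simulated listeners: ratings are beta-distributed (precision 12)
around an inverse-logit linear predictor with random intercepts for
listener (SD 0.4), speaker (0.3), and sound (0.2) on the logit scale, and
fixed coefficients specified as **average marginal effects on the 0–1
rating scale** (defaults: pitch +0.16, energy in harmonics +0.05,
duration +0.04, FM depth +0.02 per SD). The simulator solves a small
fixed point so that the realized average marginal effect equals the
specified coefficient; the fitter (mgcv beta regression with
random-effect smooths) reports logit slopes mapped back through the mean
of μ(1−μ). This makes simulation and estimation commensurable without a
Bayesian backend (none with beta-mixed support is available in the
environment).

## Calibration and what the acceptance run shows

`calibrate_offsets()` tunes the generator's physical offsets so the
realized standardized contrasts match targets. Because every feature is
z-scored across the corpus, the offsets themselves inflate the
standardizing SD; each pilot round therefore solves the fixed point
SD² = Var_cond(target·SD) + σ²_other per feature, with the
physical-to-feature gain and σ_other estimated from the pilot corpus.
Gains that are physically exact are not estimated at all: a semitone
offset moves the tracked median by a semitone, a dB offset moves frame
RMS by a dB, and duration responds with gain equal to the mean relaxed
utterance duration. σ_other estimates are pooled across pilot rounds
(the binding uncertainty is the between-panel variability of the
standardizing SD, which is why the calibration runs several single-take
pilot panels rather than few multi-take ones), and features whose
targets all sit inside ¾ of the tolerance keep their offsets. The
injected-tremor knob is special twice over: its response runs through a
quadrature floor `r(s) = sqrt(b² + (a s)²) − b` (inverted analytically,
with the band gain `a` pooled across rounds) and its estimator noise
scales with the injection, so its σ comes from the current pilot only.

The acceptance run calibrates to the published standardized contrasts
(median pitch +0.25/+0.44/+0.72 SD for concealed/real/pretended; duration
−0.54/−0.42/+0.26 SD; FM depth +0.76/+0.54 SD), regenerates the default
33×4×3 corpus with a *fresh* seed, and requires the full pipeline —
synthesis, tracking, feature extraction, standardization, mixed model —
to recover the targets within ±0.15 SD (±0.2 for FM depth), plus recovery
of the +0.16 rating coefficient within ±0.05. The irreducible noise floor
here is the 33-speaker panel draw itself: the sample SD of a feature
across 33 speakers varies several percent between seeds, which
multiplies into every standardized contrast exactly as it would in a
real replication of the study design.

What a green run establishes: the measurement chain is unbiased enough,
and the statistical layer calibrated enough, to recover known effects of
the published size at the published corpus size. What it does not
establish: anything about real voices — the generator has no segmental
phonetics, no room acoustics, no microphone coloration beyond a token
tilt term, balanced cells instead of the real corpus's missingness, and
its tremor is stationary stochastic FM rather than biomechanical
shaking. Classification accuracy on this synthetic corpus is
correspondingly higher than on real recordings, which is why no
acceptance target is attached to it.

## Known limitations

* The pitch tracker is tuned for clean synthetic voices; creak,
  subharmonics, or heavy noise would require the interactive correction
  it replaces.
* The phase vocoder's formant preservation degrades above factors ≈1.12.
* Per-frame harmonics-height detection can be fooled by broadband-noise
  clusters in a single frame; the median over frames is robust, and that
  is the aggregated statistic the profile reports.
* The beta rating model approximates the original multilevel Bayesian
  fit; intervals are Wald-type on the logit scale.
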