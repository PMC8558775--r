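---
title: "pupvox: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pupvox: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

pupvox implements the measurement and inference chain of a noise-playback
experiment on harbour seal pup calls, together with a synthetic-session
generator that plays the role of the field recordings. This vignette is the
package's own account of what is modelled, which knobs matter, and where the
design was genuinely open.

## The digital SPL convention

All audio lives on a full-scale amplitude axis. A calibration object declares
the sound pressure level assigned to digital RMS 1.0; the default is
`cal_db = 100` dB SPL, so a 65 dB SPL noise bed has RMS `10^((65-100)/20)`.
The value is arbitrary in itself — every measurement in the package is a
*relative* level — but 100 dB leaves over 20 dB of headroom above the 75 dB
default call level, so mixed sessions never clip. `spl_to_rms()` refuses
levels above the calibration point rather than silently producing samples
beyond full scale.

## What the generator emulates

A session is nine blocks — three per condition (*no playback*, *low*, *high*),
drawn uniformly among the 174 orderings of that multiset with no two adjacent
blocks alike, which is the playback randomization rule. Defaults shorten
blocks to 30 s (the full 5-min design is `block_duration_s = 300`); all
block, call and noise seeds derive deterministically from one session seed.

**Noise beds.** Low and high beds are white Gaussian noise filtered to
250–500 Hz by a 4th-order Butterworth bandpass applied forward–backward
(zero phase; effective response `|H|^4`), then RMS-calibrated to 45 / 65 dB
SPL. The no-playback bed is broadband Gaussian noise at 25 dB SPL. The
original playbacks were filtered wind recordings; the stationary Gaussian
surrogate is a deliberate simplification — stationarity is what makes the
spectral-subtraction and gain-compensation properties provable, and the
within-band spectrum is flat by decision, not evidence.

**Calls.** A call is a sum of harmonics at multiples of a time-varying f0:
per-call base (lognormal across calls, so each condition attains its
population median and coefficient of variation exactly), a ±3% sinusoidal
drift at 2–4 Hz, and multiplicative cycle-level jitter (CV 0.02) — the
minimal structure that gives a pitch tracker realistic difficulty. Base-f0
draws outside the 200–800 Hz biological range are rejected and redrawn.
Durations are untruncated lognormal with `mu = log(0.729)` and
`sigma = sqrt(2 * log(0.785 / 0.729))`, the unique lognormal with median
0.729 s and mean 0.785 s — the printed duration statistics of the study
population (`duration_params_from_moments()` exposes the identity). Harmonic
amplitudes fall at the condition's source tilt in dB/octave; raised-cosine
ramps (20 ms) shape the edges; the rendered call is RMS-calibrated to the
condition's level.

Defaults encode the study conditions: condition f0 medians 403 / 374 / 324 Hz
(no playback / low / high), f0 CVs 0.08 / 0.08 / 0.05, call level 75 dB SPL
everywhere, source tilt −6 dB/octave everywhere. Three of these deserve a
word:

* **75 dB SPL in all conditions** means no intrinsic amplitude response to
  noise, and makes the high-condition SNR +10 dB — the average the study
  estimated for its pups. Per-condition overrides express Lombard scenarios
  (one individual with intensity gain and tilt flattening).
* **f0 CVs** are not printed anywhere in the source material; only their
  ordering (dispersion lower under high noise) is. 0.08 vs 0.05 is a
  moderate, realistic contrast that the CV analysis recovers at the default
  session count without being trivial.
* **Source tilt −6 dB/octave with 18 harmonics** keeps appreciable energy
  through the 1–4 kHz band, as the reported median call spectra show. The
  harmonic count matters more than it looks: the one-third-octave slope is
  fitted on bands up to ~6.3 kHz, and a source whose harmonics stop below
  the top bands leaves those bands holding only leakage and subtraction
  residue, which dilutes any true tilt difference. 18 harmonics (capped at
  0.45 × sample rate) cover the fit range at the default 16 kHz rate.

Sample rate defaults to 16 kHz — the R14 upper band (4 kHz) and the slope
bands (≤ 6.35 kHz) fit below Nyquist with margin.

**What the generator does not emulate:** vocal-tract formants beyond the
fixed tilt envelope, reverberation, non-stationary wind structure, bird or
airplane transients, or overlapping-call diarization errors. Tests passing
on synthetic data therefore certify the *estimators* (calibration, gain
handling, masking robustness, statistical calibration), not the package's
behaviour under every nuisance of real field audio.

## Screening

Four criteria gate the amplitude/f0 analyses (rate and duration analyses
keep every call):

1. *Clipped* — operationalized as ≥ 3 consecutive samples at ≥ 0.999 of full
   scale; the source material gives no numeric criterion, so the
   threshold/run pair is a documented choice.
2. *Overlapped* — half-open interval intersection with a call of a
   different seal in the same session.
3. *Extraneous noise* — an input flag, not a detector: on real data this was
   human judgement, and synthetic fixtures set it programmatically.
4. *Untrackable* — voiced fraction of pitch frames below 0.5. "Could be
   properly tracked" had no printed number; 0.5 is the documented surrogate.

## Pitch tracking

`track_pitch()` is a classical normalized-autocorrelation tracker: Hann
window of three floor-periods (15 ms at the 200 Hz floor), frame
autocorrelation divided by the window's own autocorrelation, candidate lags
between 1/ceiling and 1/floor with parabolic peak interpolation, an unvoiced
candidate competing through the voicing (0.45) and silence (0.03)
thresholds, and a Viterbi path with octave cost 0.01 and jump cost 0.35 per
octave. Step 0.01 s, floor 200 Hz, ceiling 800 Hz are the study's stated
extraction settings; the remaining knobs follow the classical design and are
all exposed in `pitch_settings()`.

The property that matters is masking robustness: with the fundamental buried
in the 250–500 Hz band at +10 dB overall SNR, the harmonics supply enough
autocorrelation evidence that per-call median f0 stays within ~2% of truth
(the tests check this, mirroring the manual spot-checks done on the original
recordings). Per-call location statistic is the median over voiced frames —
robust to occasional octave errors; the mean is reported alongside. Whether
condition medians should pool frames or per-call summaries was unstated in
the source; the pipeline computes per-call medians and takes condition
medians of those.

## Spectral features

Average spectra use 512-sample Hamming frames with 256 hop. The normalizer
makes the summed one-sided bin power equal the mean windowed-frame power, so
spectra integrate to RMS power and are directly comparable with intensities:
a sine of amplitude A integrates to A²/2.

*Gain compensation.* Sessions carry an unknown preamplifier factor. It is
estimated as the non-vocal RMS power per noisy condition divided by the
matching noise-only power, geometric-mean-combined over low and high; the
session is divided by the square root (gain is a power-domain factor). The
choice of geometric mean over the two conditions was open; it is exact when
both blocks share one true factor, which the tests verify.

*Spectral subtraction* is a signed bin-wise difference. Negative bins are
deliberately preserved: the difference is unbiased for the mean clean
spectrum under independence, and positivity is enforced only where a
consumer requires it (the slope fit keeps only positive band energies; R14
is undefined when either band sum is non-positive; both carry a
`discard_reason`). Low-SNR calls can likewise get negative compensated
*intensity*; comparisons are therefore done in the linear, non-decibel
domain, where the condition mean remains unbiased. SNR in dB is defined only
for positive intensities.

*Tilt.* The one-third-octave slope is OLS of 10·log10(band energy) on
octaves re 1 kHz, bands centered `1000·2^(k/3)` Hz with edges ±1/6 octave,
only centers above 400 Hz (the f0 region and the masking band corrupt lower
bands) and at most `min(8000, Nyquist·2^(-1/6))` Hz — the upper limit was an
open choice and is configurable. R14 is `10·log10(E(0.4–1 kHz)/E(1–4 kHz))`,
in dB (the source's unit was unstated). Sign conventions: tilt *flattening*
is a slope increase toward 0 and an R14 decrease.

*SNR estimation* is the linear intensity ratio in dB — a documented
surrogate, since the original estimation procedure sits in an unavailable
footnote.

## Statistics

`fit_random_intercept_model()` fits (via lme4, REML) the response against
condition and trial index with random intercepts for session and seal.
Pseudo-R² is the squared correlation between fitted (including predicted
intercepts) and observed values — the source never defines its pseudo-R², so
printed values of it are not comparison targets. Singular fits fall back to
dropping the zero-variance component; with no usable random factor the model
degrades to OLS, which is also its zero-variance limit.

*Permutation tests.* p-values come from Monte Carlo permutation of the
condition labels, `p = (1 + #{perm ≥ obs}) / (1 + n_perm)`, default 1000
permutations. Two design decisions deserve explanation:

* **Exchangeability unit.** Conditions were randomized as a block order per
  session, heard jointly by both housed pups. Call-level tables therefore
  permute the block→condition map within each session (calls in a block move
  together); per-group tables (counts, CVs) draw one condition relabelling
  per session applied to every seal in it. Permuting per seal independently
  would destroy the pups' shared design and miscalibrate the test for
  responses, like call counts, that correlate between cage-mates.
* **Statistic.** The default statistic is the Wald chi-square for condition
  under generalized least squares with variance components estimated *once*
  from the condition-free null model (evaluated per permutation via the
  Woodbury identity). Because the null fit never sees the labels, the
  statistic is label-symmetric and the permutation test is exact in
  distribution; holding the variance components fixed is what makes a
  500-replicate type-I calibration feasible, and that calibration (rejection
  rate within [0.03, 0.07] at nominal 0.05) is part of the test suite. A
  full-refit likelihood-ratio statistic (`statistic = "full_lr"`) is
  available when per-permutation refitting is affordable; which variant the
  original analysis used is not stated.

Pairwise condition comparisons refit on two-condition subsets at the
Bonferroni threshold 0.05/3 ≈ 0.0167. Intensity and both tilt measures are
strongly non-normal, so they are tested per seal with two-sided Mann–Whitney
U tests (exact when the smaller sample has ≤ 12 untied observations,
otherwise normal approximation with tie and continuity corrections) at
0.05/(3 × seals) — 0.05/24 ≈ 0.00208 in the eight-seal design.

*Coefficient of variation.* Dispersion of f0 and duration is sd/mean per
(session, seal, condition) group, sample sd (n−1). Groups under 3 calls are
dropped (the original grouping rule was unstated; its differing group counts
imply some dropping happened) and the CV table feeds the same
permutation-tested model, without the trial term, which does not exist at
group level.

## Pipeline and problem sizes

`run_end_to_end()` chains generate → features → stats → report through files
in one artifact directory, so each stage can be re-run from persisted
intermediates with identical output; a single seed fixes everything,
including per-session preamp gains (drawn uniformly in amplitude 0.7–1.4,
which the gain compensation must undo). Defaults — 14 sessions, 30 s blocks,
Poisson(4) calls per block, ~500 calls total — are desk-scale: they run the
full qualitative analysis in about a minute while leaving every condition
contrast overpowered or honestly null. The estimator-recovery studies in the
tests and the acceptance script use dedicated call ensembles (200–600 calls
per condition) rather than full sessions; those sizes keep the Monte-Carlo
error of a recovered median or mean several times smaller than the tolerance
being checked.

## Known limitations

* The slope estimator's *absolute* value on strongly tonal calls is biased
  by which third-octave bands harmonics happen to fill (near-empty bands
  between low harmonics carry leakage only); condition *differences* under
  matched f0 distributions are recovered accurately, which is what the
  analyses compare. With condition-dependent f0, tilt comparisons across
  conditions inherit some f0-driven bias — true of the method itself, not
  only of the implementation.
* Spectral subtraction corrects the mean but not the variance; per-call
  tilt and intensity values under heavy masking remain noisy and occasionally
  undefined (negative bands), and are discarded with a reason rather than
  imputed.
* The generator's stationary noise and additive mixing make gain estimation
  and subtraction easier than reverberant field recordings would; treat
  recovery numbers as upper bounds on real-data performance.
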