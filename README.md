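# pupvox

Simulation and analysis pipeline for noise-playback experiments on harbour
seal pup (*Phoca vitulina*) vocalizations.

## The problem

Playback studies of vocal plasticity expose animals to masking noise and ask
whether they shift their calls' fundamental frequency (f0), amplitude,
spectral tilt, rate or duration. Analysing such recordings is delicate: the
playback noise sits on top of every call, the recording gain drifts between
sessions, and the acoustic effects of interest are small relative to
between-individual variation. pupvox packages the full measurement and
inference chain for this design — and, because field recordings of this kind
are rarely shareable, a calibrated synthetic-session generator whose ground
truth can score every estimator in the chain.

The experimental design it models: pups housed in pairs hear nine randomized
blocks per session — three each of *high* noise (65 dB SPL), *low* noise
(45 dB SPL) and *no playback* (about 25 dB SPL ambient) — with no two
consecutive blocks sharing a condition. The playback noise is bandpass
filtered to 250–500 Hz, chosen to overlap the pups' f0 range. Spontaneous
calls are annotated, screened (no clipping, no overlap with the other pup,
no extraneous noise, trackable pitch), and measured.

## Methods in brief

- **Synthesis** — harmonic calls (lognormal durations; per-call base f0 drawn
  so each condition attains its population median and CV; slow drift + cycle
  jitter; source tilt in dB/octave) mixed additively over Butterworth
  bandpass noise beds, all on a declared digital SPL calibration
  (RMS 1.0 = 100 dB SPL).
- **Pitch** — normalized-autocorrelation tracking (Hann window of 3 floor
  periods, window-autocorrelation correction, parabolic peak interpolation,
  Viterbi path), time step 0.01 s, search range 200–800 Hz; per-call medians.
- **Spectral features** — per-session gain compensation from non-vocal
  segments against matched noise-only recordings; average power spectra
  (FFT 512, hop 256, Hamming); spectral subtraction (signed, unbiased for
  the mean); noise-compensated intensity in the linear domain with SNR in
  dB; two tilt measures: the one-third-octave log-energy slope above 400 Hz
  (dB/octave, 1 kHz reference, positive bands only) and the R14 band ratio
  (0.4–1 kHz over 1–4 kHz, dB).
- **Inference** — random-intercept models (session, seal) with condition and
  trial as fixed effects; p-values by Monte Carlo permutation of condition
  labels at the level the design randomized them (blocks within session);
  Bonferroni thresholds 0.05/3 for pairwise comparisons and 0.05/24 for
  per-seal Mann–Whitney tests of intensity and tilt; coefficient-of-variation
  analyses of f0 and duration dispersion.

## Worked example

```r
library(pupvox)

cfg <- run_config(out_dir = "pupvox_demo", seed = 1)
run_end_to_end(cfg)
cat(readLines("pupvox_demo/report.txt"), sep = "\n")
```

The default configuration simulates 14 sessions (two housed pups each, 30 s
blocks) with condition f0 medians of 403/374/324 Hz, equal call levels of
75 dB SPL, and lower f0 dispersion under high noise. The report it prints
(abridged):

```
sessions: 14; valid sessions (>= 2 calls per pup): 14

f0 recovery (clean calls):
  no_playback  est median  398.7 Hz | true median  398.5 Hz | n = 188
  low          est median  374.8 Hz | true median  375.0 Hz | n = 165
  high         est median  326.2 Hz | true median  326.0 Hz | n = 164

intensity / SNR (clean calls with positive intensity):
  high         mean snr  10.0 dB | mean intensity 3.170e-03 | n = 164

statistics:
  n_calls [main]: pseudoR2 = 0.010; p = 0.097; N = 168
  duration_s [main]: pseudoR2 = 0.058; p = 0.824; N = 517
  f0_median_hz [main]: pseudoR2 = 0.570; p < 0.001; N = 517 (*)
  f0_median_hz [low_vs_high]: pseudoR2 = 0.519; p < 0.001; N = 329 (*)
  cv_f0_median_hz [main]: pseudoR2 = 0.234; p < 0.001; N = 82 (*)
```

Reading it: the pitch tracker recovers the per-condition f0 medians within a
fraction of a percent even though the high-noise band masks the fundamental
(harmonics carry the autocorrelation evidence); the compensated SNR in high
noise is +10 dB (75 dB calls over 65 dB noise); the permutation-tested
models find the planted downward f0 shift (main effect and all three pairs)
and the reduced f0 dispersion under high noise, while call rate and duration
— generated condition-independent — stay null.

A command-line driver wraps the same stages:

```sh
Rscript inst/cli/pupvox.R all --seed 1 --out pupvox_demo
```

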