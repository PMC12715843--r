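---
title: "Predicting cortical spiking envelopes from scalp EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cortical spiking envelopes from scalp EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegMUAe)
```

This vignette documents the scientific model the package implements,
the assumptions behind it, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where several reasonable options
existed.

## The problem and the signals

During a steady-state visual stimulation paradigm a screen flickers
sinusoidally at one of several temporal frequencies (0, 5, 10, 20,
40 Hz; 0 Hz means a static stimulus, i.e. open-eye spontaneous
activity). Two signals are recorded simultaneously: a wideband
intracranial signal (30 kHz) from a cortical microelectrode array, and
scalp EEG (1 kHz). Trials last 3400 ms: 800 ms pre-stimulus fixation,
2000 ms stimulation, 600 ms post-stimulus. All analyses use the
400–1800 ms window after stimulus onset (1400 samples at 1 kHz),
avoiding onset and offset transients.

The **multi-unit activity envelope (MUAe)** summarizes aggregate local
spiking: the wideband signal is band-passed to 500–5000 Hz, full-wave
rectified, enveloped with the Hilbert transform, and downsampled to
1 kHz (`extractMuae`). The envelope is a magnitude, so the output is
clipped at zero after the anti-alias filter (a low-pass at 0.4 × the
output rate, applied before decimation so that high-frequency envelope
fluctuations do not alias).

EEG is cleaned of line noise (60/120/180 Hz) and decomposed into seven
canonical bands — delta 2–4, theta 4–8, alpha 8–15, beta 15–30,
low-gamma 30–60, gamma 60–120 and high-gamma 120–200 Hz — by
bidirectional FIR filters of order 1000. The printed band edges are
kept exactly as stated, including the shared edges at 4, 8, 15, 30, 60
and 120 Hz; half-power points sit at the edges.

## The prediction model

For band $k$, the analytic signal of the band-limited EEG yields the
instantaneous amplitude $A_k(t)$ and phase $\phi_k(t)$. The model of
the instantaneous MUAe $y(t)$ is linear in 45 predictors:

$$y(t) = \beta_0 + \sum_{k=1}^{7} \beta_{A,k} A_k(t)
 + \sum_{k=1}^{7} \left[\beta_{s,k}\sin\phi_k(t) +
   \beta_{c,k}\cos\phi_k(t)\right]
 + \sum_{i=4}^{7}\sum_{j=1}^{3} A_i(t)\left[\beta_{s,i,j}\sin\phi_j(t)
 + \beta_{c,i,j}\cos\phi_j(t)\right] + \varepsilon(t)$$

Circular phases are linearized into sin/cos pairs. The interaction
block crosses the four high-frequency amplitude bands (beta through
high-gamma) with the three low-frequency phase bands (delta, theta,
alpha) — the pairs where cross-frequency phase-amplitude coupling is
expected — giving 12 pairs, 24 columns. An extended variant appends
$\sin\phi_{\mathrm{stim}}(t)$ and $\cos\phi_{\mathrm{stim}}(t)$, the
phase of the sinusoidal flicker itself (zero at stimulus onset). The
0 Hz condition has no defined stimulus phase and is never fit with the
extended model. Phase-pair coefficients are reported as Euclidean
norms, e.g. $|\beta_{\mathrm{phase},k}| = \sqrt{\beta_{s,k}^2 +
\beta_{c,k}^2}$ (`summarizeCoefficients`).

### Fitting and evaluation

`fitLassoNestedCv` estimates the model by LASSO with nested
cross-validation:

* **Outer loop**: 5 folds of *contiguous* time blocks. The series are
  strongly autocorrelated; randomly interleaved folds would place
  near-duplicate samples on both sides of the train/test split and
  inflate performance. Contiguous blocks are the conservative choice.
* **Inner loop**: the training block is split into 5 contiguous folds;
  a grid of 50 penalties, log-spaced from $\lambda_{\max}$ (smallest
  penalty yielding the all-zero model on the training split) down to
  $10^{-4}\lambda_{\max}$, is evaluated, and the penalty minimizing
  the mean inner-fold squared error is selected (no one-standard-error
  rule).
* **Standardization**: predictors are z-scored with statistics from
  the training rows only, inside both loops, so no held-out sample
  influences any fitted quantity. Columns constant on a training split
  are mapped to zero with a warning. The response stays on its native
  scale — Pearson *r* is scale-free, so reported metrics are
  unaffected.
* **Metrics**: per-fold held-out Pearson *r* and their average; a
  fully sparse model predicts a constant and scores *r* = 0 by
  convention. Adjusted R² is computed on the concatenated held-out
  predictions with *p* = the number of predictors retained in any
  fold.

Fits are performed separately per (session, EEG electrode,
intracranial electrode, condition, granularity), where granularity is
either the trial-averaged series or single trials concatenated along
the sample axis — matching per-pair, per-condition reporting.

## Quality control

**Electrode retention.** Power spectra are computed by FFT over the
500–1500 ms post-onset window (1 Hz bins), averaged across trials of a
condition. The SSVEP SNR is the power at the stimulus frequency over
the mean power of the two neighboring bins; an EEG electrode is
retained if SNR > 1.5 (strict) for at least one condition in the
session.

**Trial rejection.** From the LFP (wideband low-passed at 250 Hz and
downsampled to 1 kHz): (1) synchronization z > 4 across more than 25%
of electrodes, (2) outlier z > 4 on at least two electrodes,
(3) magnitude above 500 µV on more than two electrodes. From the EEG:
(1) outlier z > 4 at any electrode, (2) magnitude above 100 µV
sustained for more than 10 ms (a strictly contiguous run) at any
electrode. The excluded set is the union. Two statistics are not fully
specified by convention and are implemented as the simplest scale-free
choices: "synchronization" is the Pearson correlation of an
electrode's trial trace with the simultaneous mean of the other
electrodes, z-scored across trials; "outlier signal" is the per-trial
RMS, z-scored across trials. Note that a z threshold of 4 is
unreachable when few trials exist (the maximum attainable z among $n$
values is $(n-1)/\sqrt{n}$), so at small trial counts rejection is
driven by the absolute-amplitude rules — which is also what the
injected-artifact recovery tests exercise.

## Phase-amplitude coupling

The Modulation Index bins phases into 18 intervals of 20° over
(−180°, 180°], averages the amplitude per bin, normalizes the means to
a distribution $P$, and reports the Kullback–Leibler divergence of $P$
from uniform, divided by $\log 18$ so that MI ∈ [0, 1]. Numerically
the KL term is evaluated as $\sum_j p_j \log(N p_j)$ via the ratio of
un-normalized bin means, which makes the flat case exactly 0 and the
single-occupied-bin case exactly 1 in floating point. Empty bins
receive probability 0 and contribute 0 (0·log 0 := 0), with a warning
flagging undersampling. The surrogate null applies a random circular
shift of the phase series — uniform between 10% and 90% of the series
length — and recomputes MI; a circular shift preserves both series'
autocorrelation, making it the more conservative null compared with a
full permutation (which was the main alternative reading of "shuffled
phase"). `pacGrid` assembles the 7×7 EEG phase × EEG amplitude matrix
or the 7-vector against MUAe amplitude.

Trial-averaged features are computed by band-filtering each trial,
averaging the band-limited series across trials, and then taking the
analytic signal of the average. The alternative ordering (Hilbert per
trial, then averaging amplitude/phase) discards the phase alignment
that trial-averaging is meant to exploit, so the filter-then-average
ordering was chosen.

## Numerical choices in the filtering

* FIR design is a windowed-sinc (Hamming) prototype at order 1000,
  `signal::fir1`, which normalizes the gain to exactly 1 at the
  passband's arithmetic center. This matters for the 2 Hz-wide delta
  band, where an order-1000 filter at 1 kHz is at its resolution
  limit: gain at the band center is exact by construction, while the
  band edges roll off.
* Zero-phase application runs the filter forward and backward via FFT
  convolution with odd-reflection padding of one filter length —
  O(n log n), numerically equivalent to `filtfilt`, and it squares the
  magnitude response. Inputs shorter than three filter lengths are
  rejected (edge-effect hazard).
* Line-noise removal is implemented as band-**stop** (notch) filters:
  removing noise requires rejection, and the notch reading is taken as
  the intended operation. The notch half-width is 2 Hz: a 1 Hz
  half-width at order 1000 leaves the 60 Hz rejection at barely 20 dB
  after the bidirectional pass, whereas 2 Hz achieves around 65 dB
  while leaving 55 Hz and 10 Hz within 0.5% of unit gain.
* On continuous recordings, filtering precedes segmentation (avoids
  trial-edge transients). The synthetic generator emits
  trial-segmented data directly; trials (3400 samples) exceed three
  filter lengths, so per-trial filtering remains well-posed.

## The synthetic-data generator

`generateDataset` emulates the paired-recording structure so that
every downstream stage is verifiable by parameter recovery:

* Per session, trial conditions are a pseudorandom permutation of the
  configured flicker frequencies × trials-per-condition.
* A per-trial "source" EEG is the sum of seven narrowband components
  (white noise filtered into each band, scaled to configured RMS),
  optional cross-frequency coupling (amplitude of one band modulated
  by $(1+\kappa\cos\phi)$ of another's phase; default delta→gamma,
  κ = 0.3), and — in flicker trials, during the stimulus window only —
  sinusoidal SSVEP components at the stimulus frequency and its
  harmonics (phase zero at onset, harmonic weights 1 and 0.5 by
  default). Pre- and post-stimulus epochs contain band oscillations
  but no stimulus-locked components.
* Each EEG electrode observes the source through a random contact
  gain (0.8–1.2) plus white observation noise (default 2 µV).
* The MUAe rate of each intracranial electrode is
  $r(t) = \max(0,\; r_0 + g\,[X(t)\beta + s(t)])$, where $X(t)$ are
  the source's analytic band features *in exactly the model's
  45-column basis*, $\beta$ the configured true coefficients, $s(t)$
  the stimulus-locked modulation (amplitude `stimulusPhaseGain`,
  flicker trials only), $g$ the electrode's laminar gain
  (shallow/deep), and $r_0 = 50$ spikes/s the baseline. Building the
  rate from the EEG's own features keeps the ground truth in the
  estimator's basis, making recovery well-posed; the rectified-linear
  link is the simplest one preserving nonnegative rates.
* Spikes are drawn by Bernoulli thinning at the wideband rate and
  rendered as 1 ms biphasic waveforms (80 µV) over white background
  noise (5 µV) — the spike energy lies inside the 500–5000 Hz MUAe
  band.
* Artifact injection (off by default) contaminates a configured
  fraction of trials with a 150 µV / 30 ms EEG plateau and, when at
  least three intracranial electrodes exist, a 600 µV low-frequency
  excursion on three electrodes — each designed to trip exactly the
  corresponding QC rule.

Defaults (µV band RMS: delta 4, theta 3, alpha 3, beta 2, low-gamma
1.5, gamma 1, high-gamma 0.8; SSVEP gain 3 µV) follow typical scalp
EEG magnitudes with the usual 1/f-like decline across bands.

**What the generator does not emulate**: volume conduction and head
geometry (all EEG electrodes see one source), eye movements, non-
stationarities within sessions, spike waveform diversity, and any
nonlinearity in the EEG→spiking relationship beyond rate
rectification. Passing recovery tests therefore demonstrates
correctness of the estimation machinery under the model's own
assumptions — not that real cortical data satisfy those assumptions.

## Verification strategy and problem sizes

The test suite verifies each stage against independent oracles:
brute-force binned KL for the MI; FFT amplitude ratios for spectra;
Poisson counts for spike generation; hand-computed masks for QC; and
planted-coefficient recovery for the full model (5 active predictors,
n = 1400, true R² = 0.5: all signs recovered, median relative
magnitude error ≈ 15%, well under the 30% bound; null responses give
|r| < 0.06 in ≥ 95% of runs). Directional findings are reproduced on
20 simulated sessions each: flicker conditions are predicted far
better than 0 Hz when the stimulus drives the rate, the
stimulus-phase extension raises adjusted R² only when the truth
contains stimulus-locked modulation, and shallow electrodes beat deep
ones exactly when their coupling gain is larger. Simulated sessions in
the tests use 1–2 EEG and 1–4 intracranial electrodes and 3–8 trials
per condition — sizes chosen so the full suite verifies every property
in minutes on a single core while leaving all scientific constants
(trial layout, sampling rates, band edges, thresholds, fold counts)
at their stated values.

## Known limitations

* The z-scored QC criteria assume enough trials for the z threshold to
  be meaningful (see above); with very few trials only the absolute
  rules act.
* The LASSO's penalty biases retained coefficients toward zero;
  recovered magnitudes are systematically conservative (the ~15%
  median relative error above is mostly shrinkage).
* Single-trial fits at realistic noise levels yield small *r* by
  nature; the package reports them per pair and condition and leaves
  population-level inference (e.g. mixed-effects modeling across
  electrode pairs and sessions) to dedicated tools.
* EDF ingestion is not provided; continuous recordings enter through
  `segmentTrials` on numeric arrays, and sessions round-trip through
  the documented directory container (`writeContainer` /
  `readContainer`).
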