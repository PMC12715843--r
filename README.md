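# eegMUAe

Can millisecond-scale spiking dynamics in primary visual cortex be read
out from the scalp? `eegMUAe` is an R package for relating
non-invasive EEG to intracortical **multi-unit activity envelopes
(MUAe)** recorded simultaneously during steady-state visually evoked
potential (SSVEP) paradigms, in which a stimulus flickers at a fixed
frequency (here 0, 5, 10, 20 or 40 Hz; 0 Hz = open-eye spontaneous).
It is aimed at electrophysiologists and computational neuroscientists
who have paired wideband intracranial + scalp recordings (or want to
prototype such analyses on simulated data) and need a tested,
reproducible implementation of the full chain: preprocessing, quality
control, spectral feature extraction, phase-amplitude coupling, and a
cross-validated linear readout.

## The model

EEG is decomposed into seven canonical bands (delta 2–4, theta 4–8,
alpha 8–15, beta 15–30, low-gamma 30–60, gamma 60–120, high-gamma
120–200 Hz) with zero-phase order-1000 FIR filters. For each band *k*
the analytic signal provides the instantaneous amplitude *A_k(t)* and
phase *φ_k(t)*. The instantaneous MUAe *y(t)* is predicted by an
L1-regularized linear model

y(t) = β₀ + Σₖ β_{A,k} A_k(t)
     + Σₖ [ β_{s,k} sin φ_k(t) + β_{c,k} cos φ_k(t) ]
     + Σᵢ Σⱼ A_i(t) [ β_{s,i,j} sin φ_j(t) + β_{c,i,j} cos φ_j(t) ] + ε(t)

with amplitude bands *i* ∈ {beta, low-gamma, gamma, high-gamma} crossed
with phase bands *j* ∈ {delta, theta, alpha} (12 interaction pairs),
45 predictors in total; an extended variant appends sin/cos of the
stimulus phase (47 predictors). Every circular phase enters as a
sin/cos pair, and phase coefficients are reported as the Euclidean norm
of the pair. Fitting uses LASSO with 5-fold cross-validation over
contiguous time blocks and a nested 5-fold inner loop that selects the
penalty minimizing mean squared error; predictors are z-scored with
training-split statistics only. Performance is the fold-averaged
held-out Pearson *r* and the adjusted R² of concatenated held-out
predictions.

Around the model, the package provides:

* **MUAe extraction** — band-pass 500–5000 Hz, rectify, Hilbert
  envelope, anti-aliased downsampling to 1 kHz (`extractMuae`);
* **quality control** — SSVEP SNR electrode retention (power at the
  stimulus frequency over its two spectral neighbors, threshold 1.5)
  and artifact-trial rejection from LFP (z > 4 synchronization /
  outlier rules, 500 µV magnitude) and EEG (z > 4 outlier, 100 µV for
  over 10 ms) (`snrTable`, `flagArtifactTrialsLfp`,
  `flagArtifactTrialsEeg`);
* **phase-amplitude coupling** — the Kullback–Leibler Modulation Index
  on 18 phase bins with circular-shift surrogate nulls
  (`modulationIndex`, `miShuffleNull`, `pacGrid`);
* **a synthetic-data generator** (`generateDataset`) producing paired
  EEG/wideband sessions whose MUAe rate is a *known* linear function of
  the EEG's own band features — so every stage is testable by
  parameter recovery against recorded ground truth.

## Worked example

Simulate a small paired session (one EEG electrode, one shallow and one
deep intracranial electrode, five trials each of the 0 Hz and 10 Hz
conditions) and run the full pipeline:

```r
library(eegMUAe)
cfg <- runConfig(
  simulation = simulationConfig(nEegElectrodes = 1,
                                nIntracranialElectrodes = 2,
                                trialsPerCondition = 5,
                                conditions = c(0, 10), seed = 3),
  seed = 3)
rep <- runPipeline(cfg)
rep$metrics
```

```
  session  eeg electrode condition    granularity variant       meanR   adjustedR2 nRetained
1       1 EEG1       IC1         0 trial-averaged    base  0.00000000 -0.007422125         2
2       1 EEG1       IC2         0 trial-averaged    base -0.02645755 -0.056666896        17
3       1 EEG1       IC1        10 trial-averaged    base  0.15725899 -0.019267352        20
4       1 EEG1       IC2        10 trial-averaged    base  0.06987007 -0.012042815         6
```

Each row is one EEG–MUAe electrode pair in one stimulus condition:
`meanR` is the fold-averaged held-out correlation between predicted and
observed MUAe, `adjustedR2` the adjusted R² of the concatenated
held-out predictions, and `nRetained` the number of predictors the
LASSO kept in any fold. Even at this toy scale the flicker condition
(10 Hz) is predicted clearly better than the spontaneous condition
(0 Hz), the qualitative signature the model is built to expose; with
more trials and sessions the contrast sharpens (see the acceptance
script below). `rep$snr` holds the SSVEP SNR table used for electrode
retention and `rep$qc` the trial-exclusion summary.

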