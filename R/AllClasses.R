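#' @import methods
NULL

#' Canonical EEG frequency bands
#'
#' The seven bands used throughout the package: delta 2-4, theta 4-8,
#' alpha 8-15, beta 15-30, low-gamma 30-60, gamma 60-120 and high-gamma
#' 120-200 Hz. Adjacent bands share their printed edge frequency.
#'
#' @return A data.frame with columns \code{name}, \code{f_low}, \code{f_high}
#'   (Hz), one row per band, ordered low to high.
#' @examples
#' defaultBands()
#' @export
defaultBands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta",
             "low_gamma", "gamma", "high_gamma"),
    f_low = c(2, 4, 8, 15, 30, 60, 120),
    f_high = c(4, 8, 15, 30, 60, 120, 200),
    stringsAsFactors = FALSE
  )
}

.validBandTable <- function(bands) {
  is.data.frame(bands) &&
    all(c("name", "f_low", "f_high") %in% names(bands)) &&
    all(bands$f_low > 0) && all(bands$f_low < bands$f_high)
}

# ---------------------------------------------------------------------------
# TrialSet
# ---------------------------------------------------------------------------

#' Trial-segmented multi-electrode time series
#'
#' Container for trial-aligned recordings: a 3-D numeric array indexed
#' (electrode, trial, time), the sampling rate, the position of stimulus
#' onset within the trial, one condition label (flicker frequency, Hz)
#' per trial, and per-electrode metadata.
#'
#' @slot signal numeric array, dim = c(n_electrodes, n_trials, n_timepoints).
#' @slot fs sampling rate in Hz.
#' @slot alignment time of stimulus onset within each trial, in ms from
#'   trial start (800 under the default layout).
#' @slot condition numeric vector, flicker frequency (Hz) per trial; 0
#'   denotes the non-flicker (spontaneous) condition.
#' @slot electrodeInfo data.frame with one row per electrode: \code{name},
#'   \code{kind} ("eeg" or "intracranial"), and \code{depth} ("shallow",
#'   "deep", or NA for EEG electrodes).
#' @exportClass TrialSet
setClass("TrialSet",
  representation(
    signal = "array",
    fs = "numeric",
    alignment = "numeric",
    condition = "numeric",
    electrodeInfo = "data.frame"
  )
)

setValidity("TrialSet", function(object) {
  d <- dim(object@signal)
  msg <- character()
  if (length(d) != 3L)
    msg <- c(msg, "signal must be a 3-D array (electrode, trial, time)")
  else {
    if (nrow(object@electrodeInfo) != d[1L])
      msg <- c(msg, "electrodeInfo rows must match dim(signal)[1]")
    if (length(object@condition) != d[2L])
      msg <- c(msg, "condition labels must match dim(signal)[2]")
  }
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@alignment) != 1L || object@alignment < 0)
    msg <- c(msg, "alignment must be a single nonnegative time (ms)")
  if (length(d) == 3L &&
      object@alignment > 1000 * d[3L] / object@fs)
    msg <- c(msg, "alignment lies outside the trial span")
  if (!all(c("name", "kind") %in% names(object@electrodeInfo)))
    msg <- c(msg, "electrodeInfo needs 'name' and 'kind' columns")
  else {
    if (!all(object@electrodeInfo$kind %in% c("eeg", "intracranial")))
      msg <- c(msg, "electrode kind must be 'eeg' or 'intracranial'")
    ic <- object@electrodeInfo$kind == "intracranial"
    if (any(ic)) {
      if (!"depth" %in% names(object@electrodeInfo) ||
          !all(object@electrodeInfo$depth[ic] %in% c("shallow", "deep")))
        msg <- c(msg,
          "intracranial electrodes need depth labels 'shallow' or 'deep'")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TrialSet
#'
#' @param signal 3-D numeric array (electrode, trial, time).
#' @param fs sampling rate, Hz.
#' @param alignment stimulus onset within the trial, ms (default 800).
#' @param condition flicker frequency per trial, Hz.
#' @param electrodeInfo data.frame with columns \code{name}, \code{kind}
#'   and, for intracranial electrodes, \code{depth}.
#' @return A \linkS4class{TrialSet}.
#' @examples
#' sig <- array(rnorm(2 * 3 * 100), dim = c(2, 3, 100))
#' info <- data.frame(name = c("O1", "O2"), kind = "eeg", depth = NA)
#' ts <- TrialSet(sig, fs = 1000, alignment = 20, condition = c(0, 10, 10),
#'                electrodeInfo = info)
#' nTrials(ts)
#' @export
TrialSet <- function(signal, fs, alignment = 800, condition,
                     electrodeInfo) {
  if (!"depth" %in% names(electrodeInfo)) electrodeInfo$depth <- NA
  new("TrialSet", signal = signal, fs = fs, alignment = alignment,
      condition = as.numeric(condition), electrodeInfo = electrodeInfo)
}

# ---------------------------------------------------------------------------
# SimulationConfig
# ---------------------------------------------------------------------------

#' Configuration of the synthetic paired-recording generator
#'
#' Describes a simulated experiment: session/electrode/trial counts, the
#' flicker conditions, sampling rates, the trial layout, per-band EEG
#' oscillation strengths, SSVEP response gain and harmonic weights,
#' phase-amplitude coupling pairs, the true linear mapping from EEG
#' spectrotemporal features to the MUAe rate, stimulus-locked rate
#' modulation, laminar gain factors, noise levels, and the seed.
#'
#' @slot nSessions,nEegElectrodes,nIntracranialElectrodes,trialsPerCondition
#'   counts (>= 1).
#' @slot conditions flicker frequencies in Hz; 0 = no flicker.
#' @slot fsWideband,fsEeg sampling rates (Hz); fsWideband must be a
#'   multiple of fsEeg.
#' @slot trialLayout named numeric: pre/stim/post durations in ms.
#' @slot bandAmplitudes named numeric(7), per-band oscillation RMS (uV).
#' @slot ssvepGain amplitude (uV) of the stimulus-frequency response.
#' @slot ssvepHarmonics relative weights of harmonics 1..H.
#' @slot pacPairs data.frame(phase_band, amp_band, kappa), kappa in [0,1].
#' @slot couplingCoefficients numeric(45): true weights from the
#'   feature basis (7 amplitudes, 14 phase sin/cos, 24 interactions) to
#'   the MUAe rate, spikes/s per feature unit.
#' @slot stimulusPhaseGain spikes/s amplitude of stimulus-locked rate
#'   modulation (flicker conditions only).
#' @slot depthGainShallow,depthGainDeep multiplicative gain on the coupled
#'   rate component for shallow / deep electrodes.
#' @slot baselineRate baseline MUAe rate, spikes/s.
#' @slot noiseSd EEG observation noise SD (uV).
#' @slot spikeAmplitude spike waveform amplitude (uV).
#' @slot widebandNoiseSd wideband background noise SD (uV).
#' @slot artifactRate fraction of trials receiving injected artifacts.
#' @slot seed integer random seed.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nSessions = "numeric",
    nEegElectrodes = "numeric",
    nIntracranialElectrodes = "numeric",
    trialsPerCondition = "numeric",
    conditions = "numeric",
    fsWideband = "numeric",
    fsEeg = "numeric",
    trialLayout = "numeric",
    bandAmplitudes = "numeric",
    ssvepGain = "numeric",
    ssvepHarmonics = "numeric",
    pacPairs = "data.frame",
    couplingCoefficients = "numeric",
    stimulusPhaseGain = "numeric",
    depthGainShallow = "numeric",
    depthGainDeep = "numeric",
    baselineRate = "numeric",
    noiseSd = "numeric",
    spikeAmplitude = "numeric",
    widebandNoiseSd = "numeric",
    artifactRate = "numeric",
    seed = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  counts <- c(nSessions = object@nSessions,
              nEegElectrodes = object@nEegElectrodes,
              nIntracranialElectrodes = object@nIntracranialElectrodes,
              trialsPerCondition = object@trialsPerCondition)
  bad <- counts < 1 | counts != round(counts)
  if (any(bad))
    msg <- c(msg, paste0("counts must be integers >= 1: ",
                         paste(names(counts)[bad], collapse = ", ")))
  if (length(object@conditions) == 0)
    msg <- c(msg, "conditions must be a non-empty list of frequencies")
  if (object@fsWideband %% object@fsEeg != 0)
    msg <- c(msg, "fsWideband must be an integer multiple of fsEeg")
  if (length(object@trialLayout) != 3L || any(object@trialLayout <= 0))
    msg <- c(msg, "trialLayout needs positive pre/stim/post durations (ms)")
  if (length(object@bandAmplitudes) != 7L || any(object@bandAmplitudes < 0))
    msg <- c(msg, "bandAmplitudes must be 7 nonnegative values")
  if (nrow(object@pacPairs) > 0) {
    if (!all(c("phase_band", "amp_band", "kappa") %in% names(object@pacPairs)))
      msg <- c(msg, "pacPairs needs phase_band, amp_band, kappa columns")
    else if (any(object@pacPairs$kappa < 0 | object@pacPairs$kappa > 1))
      msg <- c(msg, "pacPairs kappa must lie in [0, 1]")
  }
  if (length(object@couplingCoefficients) != 45L)
    msg <- c(msg, "couplingCoefficients must have length 45 (feature basis)")
  if (object@artifactRate < 0 || object@artifactRate > 1)
    msg <- c(msg, "artifactRate must lie in [0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Zero coupling-coefficient template
#'
#' A named all-zero vector over the 45-column feature basis (7 band
#' amplitudes, 7 sin/cos phase pairs, 12 sin/cos interaction pairs), for
#' building ground-truth coupling vectors by name.
#'
#' @return Named numeric(45) of zeros; names match the design-matrix
#'   columns of \code{\link{buildDesignMatrix}} (without stimulus phase).
#' @examples
#' beta <- zeroCouplingTemplate()
#' beta["amp_alpha"] <- 2
#' @export
zeroCouplingTemplate <- function() {
  stats::setNames(numeric(45), designColumnNames(FALSE))
}

#' Default true coupling vector for simulations
#'
#' A sparse, physiologically plausible mapping: positive weights on alpha
#' and gamma amplitudes, delta and alpha phase terms, and one
#' delta-phase-by-gamma-amplitude interaction.
#'
#' @return Named numeric(45).
#' @export
defaultCouplingCoefficients <- function() {
  beta <- zeroCouplingTemplate()
  beta["amp_alpha"] <- 2
  beta["amp_gamma"] <- 4
  beta["phase_sin_delta"] <- 4
  beta["phase_cos_alpha"] <- 3
  beta["int_sin_gamma_delta"] <- 2
  beta
}

#' Construct a SimulationConfig
#'
#' Defaults encode the emulated study conditions: 3400 ms trials
#' (800 pre / 2000 stim / 600 post), flicker conditions {0, 5, 10, 20,
#' 40} Hz, 30 kHz wideband and 1 kHz EEG sampling.
#'
#' @param nSessions,nEegElectrodes,nIntracranialElectrodes,trialsPerCondition
#'   counts.
#' @param conditions flicker frequencies (Hz).
#' @param fsWideband,fsEeg sampling rates (Hz).
#' @param trialLayout pre/stim/post durations (ms).
#' @param bandAmplitudes per-band RMS amplitudes (uV), named by band.
#' @param ssvepGain SSVEP fundamental amplitude (uV).
#' @param ssvepHarmonics relative harmonic weights.
#' @param pacPairs data.frame(phase_band, amp_band, kappa).
#' @param couplingCoefficients named numeric(45) true feature weights.
#' @param stimulusPhaseGain stimulus-locked rate modulation (spikes/s).
#' @param depthGainShallow,depthGainDeep laminar gain factors.
#' @param baselineRate baseline MUAe rate (spikes/s).
#' @param noiseSd EEG observation noise SD (uV).
#' @param spikeAmplitude spike waveform amplitude (uV).
#' @param widebandNoiseSd wideband background noise SD (uV).
#' @param artifactRate fraction of trials with injected artifacts.
#' @param seed integer seed.
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(trialsPerCondition = 2, seed = 1)
#' @export
simulationConfig <- function(nSessions = 1,
                             nEegElectrodes = 3,
                             nIntracranialElectrodes = 4,
                             trialsPerCondition = 10,
                             conditions = c(0, 5, 10, 20, 40),
                             fsWideband = 30000,
                             fsEeg = 1000,
                             trialLayout = c(pre = 800, stim = 2000,
                                             post = 600),
                             bandAmplitudes = c(delta = 4, theta = 3,
                                                alpha = 3, beta = 2,
                                                low_gamma = 1.5, gamma = 1,
                                                high_gamma = 0.8),
                             ssvepGain = 3,
                             ssvepHarmonics = c(1, 0.5),
                             pacPairs = data.frame(phase_band = "delta",
                                                   amp_band = "gamma",
                                                   kappa = 0.3),
                             couplingCoefficients =
                               defaultCouplingCoefficients(),
                             stimulusPhaseGain = 10,
                             depthGainShallow = 1,
                             depthGainDeep = 1,
                             baselineRate = 50,
                             noiseSd = 2,
                             spikeAmplitude = 80,
                             widebandNoiseSd = 5,
                             artifactRate = 0,
                             seed = 1) {
  new("SimulationConfig",
      nSessions = nSessions, nEegElectrodes = nEegElectrodes,
      nIntracranialElectrodes = nIntracranialElectrodes,
      trialsPerCondition = trialsPerCondition,
      conditions = as.numeric(conditions),
      fsWideband = fsWideband, fsEeg = fsEeg,
      trialLayout = trialLayout, bandAmplitudes = bandAmplitudes,
      ssvepGain = ssvepGain, ssvepHarmonics = ssvepHarmonics,
      pacPairs = pacPairs,
      couplingCoefficients = couplingCoefficients,
      stimulusPhaseGain = stimulusPhaseGain,
      depthGainShallow = depthGainShallow,
      depthGainDeep = depthGainDeep,
      baselineRate = baselineRate, noiseSd = noiseSd,
      spikeAmplitude = spikeAmplitude,
      widebandNoiseSd = widebandNoiseSd,
      artifactRate = artifactRate, seed = seed)
}

# ---------------------------------------------------------------------------
# GroundTruth
# ---------------------------------------------------------------------------

#' Ground truth recorded by the synthetic generator
#'
#' @slot coefficients named numeric(45): true feature weights (raw scale).
#' @slot stimulusPhaseGain spikes/s stimulus-locked modulation amplitude.
#' @slot depthLabels character per intracranial electrode.
#' @slot depthGains numeric per intracranial electrode.
#' @slot artifactTrials list (one element per session) of injected trial
#'   indices.
#' @slot rateEnvelopes list per session: array (ic electrode, trial, time)
#'   of realized MUAe rates (spikes/s) at the EEG sampling rate.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    coefficients = "numeric",
    stimulusPhaseGain = "numeric",
    depthLabels = "character",
    depthGains = "numeric",
    artifactTrials = "list",
    rateEnvelopes = "list"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (length(object@coefficients) != 45L)
    msg <- c(msg, "coefficients must have length 45")
  if (length(object@depthLabels) != length(object@depthGains))
    msg <- c(msg, "depthLabels and depthGains must align")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# AnalyticFeatures
# ---------------------------------------------------------------------------

#' Per-band analytic amplitude and phase over an analysis window
#'
#' @slot amplitude numeric matrix (samples x 7 bands), >= 0.
#' @slot phase numeric matrix (samples x 7 bands), radians in (-pi, pi].
#' @slot fs sampling rate (Hz).
#' @slot windowMs analysis window, ms relative to stimulus onset.
#' @slot granularity "single-trial" (rows concatenate trials) or
#'   "trial-averaged".
#' @slot trialIndex integer per row: source trial (0 for trial-averaged).
#' @slot degenerate logical(7): TRUE where the band input was identically
#'   zero and phase is reported as 0 by convention.
#' @slot bands the band table the columns refer to.
#' @exportClass AnalyticFeatures
setClass("AnalyticFeatures",
  representation(
    amplitude = "matrix",
    phase = "matrix",
    fs = "numeric",
    windowMs = "numeric",
    granularity = "character",
    trialIndex = "integer",
    degenerate = "logical",
    bands = "data.frame"
  )
)

setValidity("AnalyticFeatures", function(object) {
  msg <- character()
  if (!identical(dim(object@amplitude), dim(object@phase)))
    msg <- c(msg, "amplitude and phase must have identical dimensions")
  if (any(object@amplitude < 0))
    msg <- c(msg, "amplitude must be nonnegative")
  if (any(object@phase <= -pi - 1e-9 | object@phase > pi + 1e-9))
    msg <- c(msg, "phase must lie in (-pi, pi]")
  if (nrow(object@amplitude) != length(object@trialIndex))
    msg <- c(msg, "trialIndex must have one entry per row")
  if (!object@granularity %in% c("single-trial", "trial-averaged"))
    msg <- c(msg, "granularity must be 'single-trial' or 'trial-averaged'")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# MIResult
# ---------------------------------------------------------------------------

#' Modulation Index with a circular-shift surrogate null
#'
#' @slot observed observed MI in [0, 1].
#' @slot null numeric vector of surrogate MI values.
#' @slot percentile percentile (0-100) of the observed MI within the null.
#' @slot nBins number of phase bins (18).
#' @exportClass MIResult
setClass("MIResult",
  representation(
    observed = "numeric",
    null = "numeric",
    percentile = "numeric",
    nBins = "numeric"
  )
)

setValidity("MIResult", function(object) {
  msg <- character()
  if (object@observed < 0 || object@observed > 1 + 1e-12)
    msg <- c(msg, "observed MI must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# ModelSpec / ModelFit
# ---------------------------------------------------------------------------

#' Specification of the MUAe prediction model and its cross-validation
#'
#' @slot bands band table (7 rows).
#' @slot interactionAmpBands amplitude bands entering interactions
#'   (beta, low_gamma, gamma, high_gamma).
#' @slot interactionPhaseBands phase bands entering interactions
#'   (delta, theta, alpha).
#' @slot includeStimulusPhase add sin/cos of the stimulus phase.
#' @slot outerFolds,innerFolds fold counts (5/5).
#' @slot nLambda number of penalty values on the grid.
#' @slot lambdaMinRatio smallest lambda as a fraction of lambda_max.
#' @slot seed integer seed (folds are deterministic; kept for provenance).
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(
    bands = "data.frame",
    interactionAmpBands = "character",
    interactionPhaseBands = "character",
    includeStimulusPhase = "logical",
    outerFolds = "numeric",
    innerFolds = "numeric",
    nLambda = "numeric",
    lambdaMinRatio = "numeric",
    seed = "numeric"
  )
)

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (nrow(object@bands) != 7L)
    msg <- c(msg, "bands must list the seven canonical bands")
  np <- length(object@interactionAmpBands) *
    length(object@interactionPhaseBands)
  if (np != 12L)
    msg <- c(msg, "interaction structure must yield 12 pairs")
  if (object@outerFolds < 2 || object@innerFolds < 2)
    msg <- c(msg, "outerFolds and innerFolds must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Construct a ModelSpec
#'
#' @param includeStimulusPhase logical; add the two stimulus-phase columns.
#' @param bands band table (default \code{\link{defaultBands}}).
#' @param outerFolds,innerFolds cross-validation folds (default 5/5).
#' @param nLambda,lambdaMinRatio penalty grid: \code{nLambda} values
#'   log-spaced from lambda_max down to
#'   \code{lambdaMinRatio * lambda_max}.
#' @param seed integer seed recorded with fits.
#' @return A \linkS4class{ModelSpec}.
#' @examples
#' modelSpec()
#' @export
modelSpec <- function(includeStimulusPhase = FALSE,
                      bands = defaultBands(),
                      outerFolds = 5, innerFolds = 5,
                      nLambda = 50, lambdaMinRatio = 1e-4,
                      seed = 1) {
  new("ModelSpec", bands = bands,
      interactionAmpBands = c("beta", "low_gamma", "gamma", "high_gamma"),
      interactionPhaseBands = c("delta", "theta", "alpha"),
      includeStimulusPhase = includeStimulusPhase,
      outerFolds = outerFolds, innerFolds = innerFolds,
      nLambda = nLambda, lambdaMinRatio = lambdaMinRatio, seed = seed)
}

#' Fitted MUAe prediction model
#'
#' Result of \code{\link{fitLassoNestedCv}}: per-outer-fold coefficients
#' refit at the inner-CV-selected penalty, held-out predictions covering
#' every analysis sample exactly once, and performance metrics.
#'
#' @slot coefficients named numeric: mean over outer folds of the
#'   standardized-scale coefficients.
#' @slot rawCoefficients coefficients mapped back to the raw predictor
#'   scale (divided by per-fold training SDs, averaged over folds).
#' @slot foldCoefficients matrix (predictors x outer folds), standardized
#'   scale.
#' @slot annotation data.frame describing each design column (category,
#'   band, phase_band, role).
#' @slot intercepts numeric per outer fold.
#' @slot foldLambda selected penalty per outer fold.
#' @slot foldR held-out Pearson r per outer fold (0 where the prediction
#'   was constant).
#' @slot meanR fold-averaged r.
#' @slot adjustedR2 adjusted R-squared on concatenated held-out
#'   predictions, with p = number of predictors retained in any fold.
#' @slot predictions held-out predictions (original sample order).
#' @slot foldId outer-fold assignment per sample.
#' @slot y the response, for fold-compatibility checks.
#' @slot foldScaling list per fold: center and scale used for z-scoring
#'   (train statistics only).
#' @slot includeStimulusPhase logical.
#' @exportClass ModelFit
setClass("ModelFit",
  representation(
    coefficients = "numeric",
    rawCoefficients = "numeric",
    foldCoefficients = "matrix",
    annotation = "data.frame",
    intercepts = "numeric",
    foldLambda = "numeric",
    foldR = "numeric",
    meanR = "numeric",
    adjustedR2 = "numeric",
    predictions = "numeric",
    foldId = "integer",
    y = "numeric",
    foldScaling = "list",
    includeStimulusPhase = "logical"
  )
)

setValidity("ModelFit", function(object) {
  msg <- character()
  if (length(object@coefficients) != nrow(object@annotation))
    msg <- c(msg, "coefficient length must match the design width")
  if (length(object@predictions) != length(object@foldId))
    msg <- c(msg, "predictions and foldId must align")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# RunConfig
# ---------------------------------------------------------------------------

#' End-to-end pipeline configuration
#'
#' Bundles the simulation (or input container path), QC thresholds, the
#' analysis window, and the model specification. Every default equals
#' the analysis constant used throughout the package: SNR threshold 1.5,
#' z threshold 4, 500 uV LFP and 100 uV / 10 ms EEG amplitude rules, and
#' the 400-1800 ms analysis window.
#'
#' @slot simulation SimulationConfig (or NULL slot via empty list) driving
#'   the simulate stage.
#' @slot inputPath optional container directory to read instead of
#'   simulating ("" = simulate).
#' @slot bands band table.
#' @slot snrThreshold SSVEP SNR retention threshold.
#' @slot zThreshold z-score threshold for artifact criteria.
#' @slot lfpMagnitudeUv LFP absolute-amplitude rule (uV).
#' @slot eegMagnitudeUv,eegDurationMs EEG amplitude-duration rule.
#' @slot analysisWindowMs analysis window, ms after stimulus onset.
#' @slot model ModelSpec.
#' @slot fitStimulusPhaseModel also fit the stimulus-phase-extended model
#'   for flicker conditions.
#' @slot granularity "trial-averaged", "single-trial", or both.
#' @slot seed top-level seed; stage seeds derive from it.
#' @exportClass RunConfig
setClass("RunConfig",
  representation(
    simulation = "SimulationConfig",
    inputPath = "character",
    bands = "data.frame",
    snrThreshold = "numeric",
    zThreshold = "numeric",
    lfpMagnitudeUv = "numeric",
    eegMagnitudeUv = "numeric",
    eegDurationMs = "numeric",
    analysisWindowMs = "numeric",
    model = "ModelSpec",
    fitStimulusPhaseModel = "logical",
    granularity = "character",
    seed = "numeric"
  )
)

setValidity("RunConfig", function(object) {
  msg <- character()
  if (!.validBandTable(object@bands))
    msg <- c(msg, "bands: invalid band definition table")
  for (fld in c("snrThreshold", "zThreshold", "lfpMagnitudeUv",
                "eegMagnitudeUv", "eegDurationMs")) {
    v <- slot(object, fld)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, paste0(fld, ": must be a single positive number"))
  }
  if (length(object@analysisWindowMs) != 2L ||
      diff(object@analysisWindowMs) <= 0)
    msg <- c(msg, "analysisWindowMs: must be an increasing [start, end]")
  lay <- object@simulation@trialLayout
  if (length(lay) == 3L &&
      object@analysisWindowMs[2L] > lay[2L] + lay[3L])
    msg <- c(msg, "analysisWindowMs: window extends beyond the trial span")
  if (!all(object@granularity %in% c("trial-averaged", "single-trial")))
    msg <- c(msg, "granularity: must be 'trial-averaged' or 'single-trial'")
  if (length(msg)) msg else TRUE
})

#' Construct a RunConfig
#'
#' @param simulation a \linkS4class{SimulationConfig}.
#' @param inputPath container directory to read instead of simulating.
#' @param bands band table.
#' @param snrThreshold,zThreshold,lfpMagnitudeUv,eegMagnitudeUv,eegDurationMs
#'   QC thresholds.
#' @param analysisWindowMs analysis window (ms post-onset).
#' @param model a \linkS4class{ModelSpec}.
#' @param fitStimulusPhaseModel also fit the stimulus-phase model.
#' @param granularity which granularities to fit.
#' @param seed top-level seed.
#' @return A \linkS4class{RunConfig}.
#' @export
runConfig <- function(simulation = simulationConfig(),
                      inputPath = "",
                      bands = defaultBands(),
                      snrThreshold = 1.5,
                      zThreshold = 4,
                      lfpMagnitudeUv = 500,
                      eegMagnitudeUv = 100,
                      eegDurationMs = 10,
                      analysisWindowMs = c(400, 1800),
                      model = modelSpec(),
                      fitStimulusPhaseModel = FALSE,
                      granularity = "trial-averaged",
                      seed = 1) {
  new("RunConfig", simulation = simulation, inputPath = inputPath,
      bands = bands, snrThreshold = snrThreshold, zThreshold = zThreshold,
      lfpMagnitudeUv = lfpMagnitudeUv, eegMagnitudeUv = eegMagnitudeUv,
      eegDurationMs = eegDurationMs, analysisWindowMs = analysisWindowMs,
      model = model, fitStimulusPhaseModel = fitStimulusPhaseModel,
      granularity = granularity, seed = seed)
}
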