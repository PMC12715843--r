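# Shared fixtures, built in code and cached per test run.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, expr, envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# Small paired dataset: 1 EEG + 2 intracranial electrodes, 4 trials
# each of 0 and 10 Hz.
smallDataset <- function() cached("smallDataset", {
  generateDataset(simulationConfig(
    nEegElectrodes = 1, nIntracranialElectrodes = 2,
    trialsPerCondition = 4, conditions = c(0, 10), seed = 42))
})

smallMuae <- function() cached("smallMuae", {
  extractMuaeTrials(smallDataset()$sessions[[1]]$wideband)
})

smallFeatures10 <- function() cached("smallFeatures10", {
  computeBandFeatures(smallDataset()$sessions[[1]]$eeg,
                      electrode = 1, condition = 10)
})

# A toy TrialSet built directly from an array.
toyTrialSet <- function(signal, fs = 1000, alignment = 800,
                        condition = NULL, kind = "eeg",
                        depth = NULL) {
  nE <- dim(signal)[1]
  if (is.null(condition)) condition <- rep(0, dim(signal)[2])
  info <- data.frame(name = paste0("E", seq_len(nE)), kind = kind,
                     depth = if (is.null(depth)) NA else depth)
  TrialSet(signal, fs = fs, alignment = alignment,
           condition = condition, electrodeInfo = info)
}

# Independent brute-force Modulation Index oracle: explicit loop over
# bins, direct KL divergence formula. Kept deliberately separate from
# the package implementation.
bruteForceMI <- function(phase, amplitude, nBins = 18) {
  edges <- seq(-pi, pi, length.out = nBins + 1)
  ph <- (phase + pi) %% (2 * pi) - pi
  ph[ph == -pi] <- pi
  m <- numeric(nBins)
  for (j in seq_len(nBins)) {
    inBin <- ph > edges[j] & ph <= edges[j + 1]
    m[j] <- if (any(inBin)) mean(amplitude[inBin]) else 0
  }
  p <- m / sum(m)
  kl <- 0
  for (j in seq_len(nBins))
    if (p[j] > 0) kl <- kl + p[j] * log(p[j] / (1 / nBins))
  kl / log(nBins)
}
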