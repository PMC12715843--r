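# Synthetic paired EEG / wideband-intracranial generator with recorded
# ground truth. Every downstream stage of the package can be verified
# by parameter recovery against the truth this module records.

# One trial of clean source EEG: per-band narrowband noise at the
# configured RMS, optional phase-amplitude coupling between configured
# band pairs, and (flicker trials, stimulus window only) SSVEP
# components at the stimulus frequency and harmonics. Returns the band
# components (time x 7) plus the stimulus-locked waveform separately.
.simTrialComponents <- function(config, cond, bands) {
  fs <- config@fsEeg
  lay <- config@trialLayout
  nSamp <- round(sum(lay) * fs / 1000)
  onset <- round(lay[1L] * fs / 1000)
  stimIdx <- (onset + 1L):(onset + round(lay[2L] * fs / 1000))
  comp <- matrix(0, nSamp, 7L)
  for (k in seq_len(7L)) {
    w <- stats::rnorm(nSamp)
    nb <- filterBand(w, fs, bands[k, ])
    s <- stats::sd(nb)
    if (s > 0) nb <- nb * (config@bandAmplitudes[k] / s)
    comp[, k] <- nb
  }
  # cross-frequency coupling: modulate the amplitude-band component by
  # the phase of the phase-band component
  if (nrow(config@pacPairs) > 0) {
    for (r in seq_len(nrow(config@pacPairs))) {
      jp <- match(config@pacPairs$phase_band[r], bands$name)
      ia <- match(config@pacPairs$amp_band[r], bands$name)
      kap <- config@pacPairs$kappa[r]
      phi <- Arg(analyticSignal(comp[, jp]))
      comp[, ia] <- comp[, ia] * (1 + kap * cos(phi)) / (1 + kap)
    }
  }
  stimWave <- numeric(nSamp)
  if (cond > 0 && config@ssvepGain > 0) {
    tRel <- (seq_along(stimIdx) - 1L) / fs
    for (h in seq_along(config@ssvepHarmonics)) {
      stimWave[stimIdx] <- stimWave[stimIdx] +
        config@ssvepGain * config@ssvepHarmonics[h] *
        cos(2 * pi * h * cond * tRel)
    }
  }
  list(components = comp, stimWave = stimWave,
       stimIdx = stimIdx, onset = onset)
}

#' Render a spike rate envelope as a wideband extracellular trace
#'
#' Inhomogeneous point-process spikes (Bernoulli thinning at the
#' wideband rate) convolved with a 1 ms biphasic waveform, plus white
#' Gaussian background noise. The spike energy lies in the 500-5000 Hz
#' band the MUAe extraction targets.
#'
#' @param rateEnvelope nonnegative rate (spikes/s) sampled at
#'   \code{fsRate}.
#' @param fs output wideband sampling rate, Hz.
#' @param fsRate sampling rate of the envelope (default 1000 Hz); must
#'   divide \code{fs}.
#' @param spikeAmplitude waveform peak, uV.
#' @param noiseSd background noise SD, uV (0 = none).
#' @param seed optional seed; NULL uses the current RNG stream.
#' @return Numeric wideband trace of length
#'   \code{length(rateEnvelope) * fs / fsRate}.
#' @examples
#' x <- generateSpikeWideband(rep(100, 200), fs = 30000, seed = 1)
#' @export
generateSpikeWideband <- function(rateEnvelope, fs, fsRate = 1000,
                                  spikeAmplitude = 80, noiseSd = 5,
                                  seed = NULL) {
  if (any(rateEnvelope < 0)) stop("spike rates must be nonnegative")
  if (fs %% fsRate != 0) stop("fsRate must divide fs")
  if (!is.null(seed)) set.seed(as.integer(seed))
  up <- rep(rateEnvelope, each = fs / fsRate)
  n <- length(up)
  spikes <- stats::rbinom(n, 1L, pmin(up / fs, 1))
  out <- numeric(n)
  if (any(spikes > 0)) {
    kt <- seq_len(round(fs / 1000))  # 1 ms biphasic kernel
    kernel <- spikeAmplitude * sin(2 * pi * (kt - 0.5) / length(kt))
    idx <- which(spikes == 1L)
    for (o in seq_along(kernel)) {
      at <- idx + o - 1L
      ok <- at <= n
      out[at[ok]] <- out[at[ok]] + kernel[o]
    }
  }
  if (noiseSd > 0) out <- out + stats::rnorm(n, sd = noiseSd)
  out
}

#' Inject artifact contamination into a session
#'
#' A configurable fraction of trials receives (a) an EEG plateau of
#' +/-150 uV lasting 30 ms on one electrode — tripping the 100 uV /
#' 10 ms amplitude-duration rule — and, when at least three
#' intracranial electrodes exist, (b) a 600 uV low-frequency excursion
#' (100 ms half-sine) on three electrodes — tripping the 500 uV LFP
#' magnitude rule.
#'
#' @param session list with elements \code{eeg} and \code{wideband}
#'   (\linkS4class{TrialSet}s with equal trial counts).
#' @param artifactRate fraction of trials to contaminate, in [0, 1];
#'   the injected count is \code{round(artifactRate * nTrials)}.
#' @param seed integer seed.
#' @return List: \code{session} (modified copy), \code{injected}
#'   (sorted trial indices).
#' @export
injectArtifacts <- function(session, artifactRate, seed = 1) {
  if (artifactRate < 0 || artifactRate > 1)
    stop("artifactRate must lie in [0, 1]")
  nT <- nTrials(session$eeg)
  k <- round(artifactRate * nT)
  if (k == 0L) return(list(session = session, injected = integer(0)))
  set.seed(as.integer(seed))
  injected <- sort(sample.int(nT, k))
  eeg <- session$eeg@signal
  wb <- session$wideband@signal
  fsE <- samplingRate(session$eeg)
  fsW <- samplingRate(session$wideband)
  nE <- dim(eeg)[1L]; nSE <- dim(eeg)[3L]
  nI <- dim(wb)[1L]; nSW <- dim(wb)[3L]
  durE <- round(0.030 * fsE)
  durW <- round(0.100 * fsW)
  for (tr in injected) {
    e <- sample.int(nE, 1L)
    at <- sample.int(nSE - durE, 1L)
    eeg[e, tr, at:(at + durE - 1L)] <-
      eeg[e, tr, at:(at + durE - 1L)] + sample(c(-150, 150), 1L)
    if (nI >= 3L) {
      els <- sample.int(nI, 3L)
      atW <- sample.int(nSW - durW, 1L)
      bump <- 600 * sin(pi * seq_len(durW) / durW)
      for (ie in els)
        wb[ie, tr, atW:(atW + durW - 1L)] <-
          wb[ie, tr, atW:(atW + durW - 1L)] + bump
    }
  }
  session$eeg@signal <- eeg
  session$wideband@signal <- wb
  list(session = session, injected = injected)
}

#' Generate a paired EEG / wideband dataset with ground truth
#'
#' Each session draws a pseudorandom trial order over the configured
#' flicker conditions. Per trial, a clean "source" EEG is built from
#' seven narrowband components (with configured cross-frequency
#' coupling and, under flicker, SSVEP components during the stimulus
#' window). The MUAe rate envelope of every intracranial electrode is
#' the configured linear combination of the source's analytic band
#' features (exactly the model's 45-column basis) plus stimulus-locked
#' modulation, scaled by the electrode's laminar gain, offset by the
#' baseline rate, and rectified at zero. Spikes are drawn from that
#' rate and rendered as a wideband trace; EEG electrodes observe the
#' source plus white observation noise. The full ground truth —
#' coefficients, depth labels and gains, injected artifact trials, and
#' realized rate envelopes — is recorded.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return List: \code{sessions} (list of lists with \code{eeg} and
#'   \code{wideband} \linkS4class{TrialSet}s), \code{truth}
#'   (\linkS4class{GroundTruth}).
#' @examples
#' \donttest{
#' ds <- generateDataset(simulationConfig(trialsPerCondition = 1,
#'                                        conditions = c(0, 10),
#'                                        seed = 7))
#' }
#' @export
generateDataset <- function(config) {
  validObject(config)
  set.seed(as.integer(config@seed))
  bands <- defaultBands()
  fsE <- config@fsEeg; fsW <- config@fsWideband
  lay <- config@trialLayout
  nSamp <- round(sum(lay) * fsE / 1000)
  nSampW <- round(sum(lay) * fsW / 1000)
  nIc <- config@nIntracranialElectrodes
  nEe <- config@nEegElectrodes
  depthLabels <- rep(c("shallow", "deep"), length.out = nIc)
  depthGains <- ifelse(depthLabels == "shallow",
                       config@depthGainShallow, config@depthGainDeep)
  beta <- config@couplingCoefficients

  eegInfo <- data.frame(name = paste0("EEG", seq_len(nEe)),
                        kind = "eeg", depth = NA)
  icInfo <- data.frame(name = paste0("IC", seq_len(nIc)),
                       kind = "intracranial", depth = depthLabels)

  sessions <- vector("list", config@nSessions)
  artifactTrials <- vector("list", config@nSessions)
  rateEnvelopes <- vector("list", config@nSessions)

  for (s in seq_len(config@nSessions)) {
    conds <- sample(rep(config@conditions,
                        each = config@trialsPerCondition))
    nT <- length(conds)
    eegSig <- array(0, dim = c(nEe, nT, nSamp))
    wbSig <- array(0, dim = c(nIc, nT, nSampW))
    rates <- array(0, dim = c(nIc, nT, nSamp))
    mix <- stats::runif(nEe, 0.8, 1.2)  # electrode contact gains

    for (tr in seq_len(nT)) {
      parts <- .simTrialComponents(config, conds[tr], bands)
      source <- rowSums(parts$components) + parts$stimWave
      for (e in seq_len(nEe))
        eegSig[e, tr, ] <- mix[e] * source +
          stats::rnorm(nSamp, sd = config@noiseSd)
      # ground-truth features of the source, in the model basis
      A <- P <- matrix(0, nSamp, 7L)
      for (k in seq_len(7L)) {
        z <- analyticSignal(parts$components[, k] +
                              if (conds[tr] > 0) parts$stimWave *
                                .bandContains(bands[k, ], conds[tr]) else 0)
        A[, k] <- Mod(z)
        P[, k] <- .wrapPhase(Arg(z))
      }
      X <- .rawDesign(A, P, bands)
      coupled <- drop(X %*% beta)
      if (conds[tr] > 0 && config@stimulusPhaseGain != 0) {
        tRel <- (parts$stimIdx - parts$stimIdx[1L]) / fsE
        coupled[parts$stimIdx] <- coupled[parts$stimIdx] +
          config@stimulusPhaseGain * cos(2 * pi * conds[tr] * tRel)
      }
      for (ic in seq_len(nIc)) {
        rate <- pmax(0, config@baselineRate + depthGains[ic] * coupled)
        rates[ic, tr, ] <- rate
        wbSig[ic, tr, ] <- generateSpikeWideband(
          rate, fs = fsW, fsRate = fsE,
          spikeAmplitude = config@spikeAmplitude,
          noiseSd = config@widebandNoiseSd)
      }
    }
    sess <- list(
      eeg = TrialSet(eegSig, fs = fsE, alignment = lay[1L],
                     condition = conds, electrodeInfo = eegInfo),
      wideband = TrialSet(wbSig, fs = fsW, alignment = lay[1L],
                          condition = conds, electrodeInfo = icInfo))
    injected <- integer(0)
    if (config@artifactRate > 0) {
      inj <- injectArtifacts(sess, config@artifactRate,
                             seed = config@seed + 131 * s)
      sess <- inj$session
      injected <- inj$injected
    }
    sessions[[s]] <- sess
    artifactTrials[[s]] <- injected
    rateEnvelopes[[s]] <- rates
  }

  truth <- new("GroundTruth", coefficients = beta,
               stimulusPhaseGain = config@stimulusPhaseGain,
               depthLabels = depthLabels, depthGains = depthGains,
               artifactTrials = artifactTrials,
               rateEnvelopes = rateEnvelopes)
  list(sessions = sessions, truth = truth)
}

# Does a band contain frequency f (used to place the SSVEP component in
# the ground-truth features of the band it falls into)?
.bandContains <- function(band, f) {
  as.numeric(f >= band$f_low[1L] && f <= band$f_high[1L])
}
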