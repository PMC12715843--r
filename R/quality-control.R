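# Electrode selection (SSVEP SNR) and artifact-trial rejection.

#' Trial-averaged power spectrum over the evoked window
#'
#' FFT power over a window after stimulus onset (default 500-1500 ms,
#' giving 1 Hz bins at 1 kHz), averaged over the trials of one
#' condition, per electrode. One-sided power normalized so a unit-
#' amplitude sinusoid contributes power 0.5 at its bin.
#'
#' @param ts a \linkS4class{TrialSet}.
#' @param condition flicker frequency selecting trials; NULL = all.
#' @param windowMs window, ms post-onset (default c(500, 1500)).
#' @return Matrix (electrode x frequency bin) with a
#'   \code{"frequencies"} attribute (Hz).
#' @export
powerSpectrum <- function(ts, condition = NULL, windowMs = c(500, 1500)) {
  fs <- samplingRate(ts)
  idx <- .windowIndex(windowMs, stimulusOnset(ts), fs, nTimepoints(ts))
  sel <- if (is.null(condition)) seq_len(nTrials(ts)) else
    which(trialConditions(ts) == condition)
  if (!length(sel)) stop("no trials of condition ", condition)
  n <- length(idx)
  nF <- floor(n / 2) + 1L
  freqs <- (seq_len(nF) - 1L) * fs / n
  out <- matrix(0, nElectrodes(ts), nF)
  for (e in seq_len(nElectrodes(ts))) {
    acc <- numeric(nF)
    for (tr in sel) {
      X <- stats::fft(ts@signal[e, tr, idx])[seq_len(nF)]
      pw <- (Mod(X) / n)^2
      # fold two-sided power into one side (not DC/Nyquist)
      dbl <- 2:(nF - if (n %% 2 == 0) 1L else 0L)
      pw[dbl] <- 2 * pw[dbl]
      acc <- acc + pw
    }
    out[e, ] <- acc / length(sel)
  }
  rownames(out) <- electrodeInfo(ts)$name
  colnames(out) <- freqs
  attr(out, "frequencies") <- freqs
  out
}

#' Steady-state SNR at the stimulus frequency
#'
#' The ratio of evoked power at the stimulus frequency to the average
#' power at the two neighboring frequency bins. A zero denominator is
#' reported as \code{Inf} with a \code{"degenerate"} attribute.
#'
#' @param spectrum power vector with a \code{"frequencies"} attribute,
#'   or one row of \code{\link{powerSpectrum}} plus \code{freqs}.
#' @param fStim stimulus frequency, Hz.
#' @param freqs frequency axis (Hz) if not carried as an attribute.
#' @return SNR (dimensionless, >= 0).
#' @examples
#' p <- c(1, 1, 3, 1, 1)
#' computeSnr(p, fStim = 2, freqs = 0:4) # 3
#' @export
computeSnr <- function(spectrum, fStim, freqs = attr(spectrum,
                                                     "frequencies")) {
  if (is.null(freqs)) stop("frequency axis required")
  i <- which.min(abs(freqs - fStim))
  if (abs(freqs[i] - fStim) > diff(freqs[1:2]) / 2)
    stop("stimulus frequency not on the spectral grid")
  if (i <= 1L || i >= length(freqs))
    stop("both neighboring bins must exist")
  denom <- mean(c(spectrum[i - 1L], spectrum[i + 1L]))
  if (denom == 0) {
    out <- Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  as.numeric(spectrum[i] / denom)
}

#' SNR table over electrodes and conditions
#'
#' @param ts an EEG \linkS4class{TrialSet}.
#' @param conditions flicker conditions to evaluate (default the
#'   nonzero conditions present).
#' @param session session identifier recorded in the table.
#' @param windowMs evoked window for \code{\link{powerSpectrum}}.
#' @return data.frame: session, electrode, condition, snr.
#' @export
snrTable <- function(ts, conditions = NULL, session = 1L,
                     windowMs = c(500, 1500)) {
  if (is.null(conditions))
    conditions <- setdiff(sort(unique(trialConditions(ts))), 0)
  rows <- list()
  for (cc in conditions) {
    sp <- powerSpectrum(ts, condition = cc, windowMs = windowMs)
    freqs <- attr(sp, "frequencies")
    for (e in seq_len(nrow(sp))) {
      rows[[length(rows) + 1L]] <- data.frame(
        session = session,
        electrode = rownames(sp)[e],
        condition = cc,
        snr = suppressWarnings(computeSnr(sp[e, ], cc, freqs)))
    }
  }
  do.call(rbind, rows)
}

#' Retain EEG electrodes by SSVEP SNR
#'
#' An electrode is retained when its SNR strictly exceeds the threshold
#' for at least one stimulus condition in the session.
#'
#' @param snr data.frame from \code{\link{snrTable}}.
#' @param threshold retention threshold (default 1.5, strict
#'   inequality).
#' @return Named list per session of retained electrode names.
#' @export
selectEegElectrodes <- function(snr, threshold = 1.5) {
  if (!nrow(snr)) stop("empty SNR table")
  out <- lapply(split(snr, snr$session), function(tab) {
    keep <- tapply(tab$snr, tab$electrode, function(v)
      any(v > threshold))
    names(keep)[keep]
  })
  out
}

# Per-trial, per-electrode RMS, z-scored across trials (per electrode).
.rmsZ <- function(sig) {
  rms <- sqrt(apply(sig^2, c(1L, 2L), mean))
  t(scale(t(rms)))  # z across trials within electrode
}

#' Derive the LFP from wideband trials
#'
#' Zero-phase low-pass at 250 Hz and decimation to \code{fsOut}.
#'
#' @param ts wideband \linkS4class{TrialSet}.
#' @param fsOut output rate (default 1000 Hz).
#' @param cutoffHz low-pass edge (default 250 Hz).
#' @param order FIR order.
#' @return A \linkS4class{TrialSet} of LFP at \code{fsOut}.
#' @export
deriveLfp <- function(ts, fsOut = 1000, cutoffHz = 250, order = 1000) {
  fs <- samplingRate(ts)
  dec <- fs / fsOut
  if (dec != round(dec)) stop("fsOut must divide the wideband rate")
  b <- .firDesign(cutoffHz, fs, order, "low")
  d <- dim(ts@signal)
  nOut <- length(seq.int(1L, d[3L], by = dec))
  out <- array(0, dim = c(d[1L], d[2L], nOut))
  for (e in seq_len(d[1L])) for (tr in seq_len(d[2L])) {
    y <- .zeroPhaseFilter(b, ts@signal[e, tr, ])
    out[e, tr, ] <- y[seq.int(1L, d[3L], by = dec)]
  }
  TrialSet(out, fs = fsOut, alignment = ts@alignment,
           condition = ts@condition, electrodeInfo = ts@electrodeInfo)
}

#' Flag artifact trials from the LFP
#'
#' Three criteria, each evaluated per trial: (1) synchronization —
#' per electrode, the Pearson correlation of the trial trace with the
#' simultaneous mean of the other electrodes, z-scored across trials;
#' a trial is flagged when z > \code{zThreshold} on more than 25% of
#' electrodes. (2) outlier — per-electrode trial RMS z-scored across
#' trials; flagged when z > \code{zThreshold} on at least two
#' electrodes. (3) magnitude — absolute LFP exceeding
#' \code{magnitudeUv} on more than two electrodes.
#'
#' @param lfp LFP \linkS4class{TrialSet} (from \code{\link{deriveLfp}}).
#' @param zThreshold z-score threshold (default 4).
#' @param magnitudeUv absolute amplitude rule, uV (default 500).
#' @return data.frame (one row per trial): trial, flagged, plus logical
#'   provenance columns sync, outlier, magnitude.
#' @export
flagArtifactTrialsLfp <- function(lfp, zThreshold = 4,
                                  magnitudeUv = 500) {
  sig <- lfp@signal
  d <- dim(sig)
  if (d[2L] < 3L) stop("need at least 3 trials for z-scored criteria")
  nE <- d[1L]; nT <- d[2L]
  # (1) synchronization
  syncFlag <- rep(FALSE, nT)
  if (nE >= 2L) {
    corMat <- matrix(NA_real_, nE, nT)
    for (tr in seq_len(nT)) {
      m <- sig[, tr, , drop = FALSE][, 1L, ]
      if (nE == 1L) m <- matrix(m, nrow = 1L)
      tot <- colSums(m)
      for (e in seq_len(nE)) {
        others <- (tot - m[e, ]) / (nE - 1L)
        corMat[e, tr] <- if (stats::sd(m[e, ]) == 0 ||
                             stats::sd(others) == 0) 0 else
          stats::cor(m[e, ], others)
      }
    }
    zSync <- t(scale(t(corMat)))
    syncFlag <- colSums(zSync > zThreshold, na.rm = TRUE) > 0.25 * nE
  }
  # (2) outlier RMS
  zRms <- .rmsZ(sig)
  outlierFlag <- colSums(zRms > zThreshold, na.rm = TRUE) >= 2L
  # (3) magnitude
  maxAbs <- apply(abs(sig), c(1L, 2L), max)
  magFlag <- colSums(maxAbs > magnitudeUv) > 2L
  data.frame(trial = seq_len(nT),
             flagged = syncFlag | outlierFlag | magFlag,
             sync = syncFlag, outlier = outlierFlag,
             magnitude = magFlag)
}

#' Flag artifact trials from the EEG
#'
#' Two criteria: (1) outlier — per-electrode trial RMS z-scored across
#' trials, flagged when z > \code{zThreshold} at any electrode;
#' (2) amplitude-duration — a contiguous run of samples with absolute
#' amplitude above \code{magnitudeUv} lasting longer than
#' \code{durationMs} at any electrode.
#'
#' @param eeg EEG \linkS4class{TrialSet}.
#' @param zThreshold z-score threshold (default 4).
#' @param magnitudeUv amplitude rule, uV (default 100).
#' @param durationMs duration rule, ms (default 10; strictly longer
#'   runs flag).
#' @return data.frame: trial, flagged, outlier, magnitude.
#' @export
flagArtifactTrialsEeg <- function(eeg, zThreshold = 4,
                                  magnitudeUv = 100, durationMs = 10) {
  sig <- eeg@signal
  d <- dim(sig)
  if (d[2L] < 3L) stop("need at least 3 trials for z-scored criteria")
  zRms <- .rmsZ(sig)
  outlierFlag <- colSums(zRms > zThreshold, na.rm = TRUE) >= 1L
  minRun <- durationMs * samplingRate(eeg) / 1000
  magFlag <- vapply(seq_len(d[2L]), function(tr) {
    any(vapply(seq_len(d[1L]), function(e) {
      r <- rle(abs(sig[e, tr, ]) > magnitudeUv)
      any(r$values & r$lengths > minRun)
    }, logical(1)))
  }, logical(1))
  data.frame(trial = seq_len(d[2L]),
             flagged = outlierFlag | magFlag,
             outlier = outlierFlag, magnitude = magFlag)
}

#' Combine LFP and EEG artifact masks
#'
#' The excluded set is the union of trials flagged by either method.
#'
#' @param lfpMask,eegMask data.frames from the two flagging functions.
#' @return data.frame: trial, excluded, lfp, eeg.
#' @export
combineArtifactMasks <- function(lfpMask, eegMask) {
  stopifnot(nrow(lfpMask) == nrow(eegMask))
  data.frame(trial = lfpMask$trial,
             excluded = lfpMask$flagged | eegMask$flagged,
             lfp = lfpMask$flagged, eeg = eegMask$flagged)
}
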