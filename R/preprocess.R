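# Signal preprocessing: MUAe extraction, line-noise removal, band
# filtering, and trial segmentation.

#' Extract the multi-unit activity envelope (MUAe) from a wideband signal
#'
#' Four sequential steps: (1) zero-phase band-pass of the wideband trace
#' to 500-5000 Hz, (2) full-wave rectification, (3) analytic-signal
#' (Hilbert) envelope of the rectified trace, (4) anti-alias low-pass at
#' 0.4 * \code{fsOut} followed by decimation to \code{fsOut}. The result
#' is clipped at zero: the envelope is a magnitude and the anti-alias
#' filter may undershoot by a numerical hair.
#'
#' @param x wideband numeric vector.
#' @param fsIn input sampling rate, Hz; must be at least 10 kHz so the
#'   5000 Hz band edge exists.
#' @param fsOut output rate, Hz; must divide \code{fsIn}.
#' @param bandHz the spiking band (default c(500, 5000) Hz).
#' @param order FIR order for both filters.
#' @return Nonnegative envelope sampled at \code{fsOut}.
#' @examples
#' \donttest{
#' fs <- 30000
#' x <- rnorm(fs) # 1 s of noise
#' env <- extractMuae(x, fsIn = fs, fsOut = 1000)
#' }
#' @export
extractMuae <- function(x, fsIn, fsOut = 1000, bandHz = c(500, 5000),
                        order = 1000) {
  if (fsIn < 2 * bandHz[2L])
    stop("fsIn = ", fsIn, " Hz is too low for the ", bandHz[2L],
         " Hz band edge")
  if (fsIn %% fsOut != 0)
    stop("fsOut must divide fsIn (got ", fsIn, " / ", fsOut, ")")
  b <- .firDesign(bandHz, fsIn, order, "pass")
  spk <- .zeroPhaseFilter(b, x)
  rect <- abs(spk)
  env <- Mod(analyticSignal(rect))
  dec <- fsIn / fsOut
  if (dec > 1L) {
    lp <- .firDesign(0.4 * fsOut, fsIn, order, "low")
    env <- .zeroPhaseFilter(lp, env)
    env <- env[seq.int(1L, length(env), by = dec)]
  }
  pmax(env, 0)
}

#' Remove power-line noise with zero-phase FIR notch filters
#'
#' Sequential narrow band-stop filters at each listed harmonic, applied
#' forward and backward. The notch half-width is 2 Hz, wide enough for
#' an order-1000 windowed-sinc design to reject the harmonic by far more
#' than 20 dB while leaving the passband within a fraction of a percent.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param harmonics line frequencies to notch, Hz (default 60/120/180).
#' @param halfWidthHz notch half-width, Hz.
#' @param order FIR order.
#' @return Filtered series, same length.
#' @examples
#' t <- seq(0, 4, by = 1e-3)
#' x <- sin(2 * pi * 10 * t) + sin(2 * pi * 60 * t)
#' y <- removeLineNoise(x, fs = 1000)
#' @export
removeLineNoise <- function(x, fs, harmonics = c(60, 120, 180),
                            halfWidthHz = 2, order = 1000) {
  if (any(harmonics >= fs / 2))
    stop("line harmonic at or above the Nyquist frequency")
  for (f0 in harmonics) {
    b <- .firDesign(c(f0 - halfWidthHz, f0 + halfWidthHz), fs, order,
                    "stop")
    x <- .zeroPhaseFilter(b, x)
  }
  x
}

#' Zero-phase FIR band-pass filtering
#'
#' Windowed-sinc FIR of the given order applied bidirectionally, so the
#' net phase response is zero. \code{band} is either a row of the band
#' table (list/data.frame with \code{f_low}, \code{f_high}) or a numeric
#' pair of edges in Hz; the default filters to the 1-250 Hz full band.
#'
#' @param x numeric series, longer than 3x the filter length.
#' @param fs sampling rate, Hz.
#' @param band band edges; default \code{c(1, 250)} (full-band EEG).
#' @param order FIR order (default 1000).
#' @return Band-limited series, same length as \code{x}.
#' @examples
#' t <- seq(0, 5, by = 1e-3)
#' alpha <- filterBand(sin(2 * pi * 10 * t), fs = 1000,
#'                     band = c(8, 15))
#' @export
filterBand <- function(x, fs, band = c(1, 250), order = 1000) {
  if (is.list(band) || is.data.frame(band))
    band <- c(band$f_low[1L], band$f_high[1L])
  stopifnot(length(band) == 2L, band[1L] > 0, band[1L] < band[2L])
  b <- .firDesign(band, fs, order, "pass")
  .zeroPhaseFilter(b, x)
}

#' Segment a continuous recording into stimulus-aligned trials
#'
#' Cuts one window per stimulus onset: \code{windowMs[1]} ms before the
#' onset through \code{windowMs[2]} ms after (default -800 to +2600 ms,
#' a 3400 ms trial aligned at 800 ms).
#'
#' @param x continuous signal: numeric vector (one electrode) or matrix
#'   (electrode x time).
#' @param fs sampling rate, Hz.
#' @param onsetsMs stimulus-onset times, ms from recording start.
#' @param condition flicker frequency per onset, Hz.
#' @param windowMs window around onset, ms (negative = pre-stimulus).
#' @param electrodeInfo electrode metadata; default one generic EEG row
#'   per electrode.
#' @return A \linkS4class{TrialSet} aligned at \code{-windowMs[1]} ms.
#' @examples
#' x <- rnorm(10000)
#' ts <- segmentTrials(x, fs = 1000, onsetsMs = c(2000, 6000),
#'                     condition = c(0, 10), windowMs = c(-800, 2600))
#' nTrials(ts)
#' @export
segmentTrials <- function(x, fs, onsetsMs, condition,
                          windowMs = c(-800, 2600),
                          electrodeInfo = NULL) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  nE <- nrow(x); nS <- ncol(x)
  if (length(condition) != length(onsetsMs))
    stop("one condition label per onset is required")
  nPer <- round(diff(windowMs) * fs / 1000)
  sig <- array(NA_real_, dim = c(nE, length(onsetsMs), nPer))
  for (k in seq_along(onsetsMs)) {
    i0 <- round((onsetsMs[k] + windowMs[1L]) * fs / 1000) + 1L
    i1 <- i0 + nPer - 1L
    if (i0 < 1L || i1 > nS)
      stop("trial window for onset at ", onsetsMs[k],
           " ms exceeds the recording bounds")
    sig[, k, ] <- x[, i0:i1]
  }
  if (is.null(electrodeInfo))
    electrodeInfo <- data.frame(name = paste0("E", seq_len(nE)),
                                kind = "eeg", depth = NA)
  TrialSet(sig, fs = fs, alignment = -windowMs[1L],
           condition = condition, electrodeInfo = electrodeInfo)
}

#' Band-decompose every trial of an EEG TrialSet
#'
#' Applies \code{\link{removeLineNoise}} then \code{\link{filterBand}}
#' per electrode and trial, returning one TrialSet per band (plus the
#' 1-250 Hz full band).
#'
#' @param ts an EEG \linkS4class{TrialSet}.
#' @param bands band table (default \code{\link{defaultBands}}).
#' @param lineNoise remove 60/120/180 Hz first (default TRUE).
#' @param order FIR order.
#' @return Named list of TrialSets: one per band name plus "full_band".
#' @export
bandDecompose <- function(ts, bands = defaultBands(), lineNoise = TRUE,
                          order = 1000) {
  sig <- ts@signal
  if (lineNoise)
    sig <- .overTime(sig, function(x)
      removeLineNoise(x, samplingRate(ts), order = order))
  mk <- function(arr) TrialSet(arr, fs = ts@fs, alignment = ts@alignment,
                               condition = ts@condition,
                               electrodeInfo = ts@electrodeInfo)
  out <- list()
  out[["full_band"]] <- mk(.overTime(sig, function(x)
    filterBand(x, samplingRate(ts), c(1, 250), order = order)))
  for (k in seq_len(nrow(bands))) {
    out[[bands$name[k]]] <- mk(.overTime(sig, function(x)
      filterBand(x, samplingRate(ts), bands[k, ], order = order)))
  }
  out
}

#' Extract MUAe for every trial of a wideband TrialSet
#'
#' @param ts wideband intracranial \linkS4class{TrialSet}.
#' @param fsOut output rate, Hz (default 1000).
#' @param ... passed to \code{\link{extractMuae}}.
#' @return A \linkS4class{TrialSet} of MUAe at \code{fsOut}.
#' @export
extractMuaeTrials <- function(ts, fsOut = 1000, ...) {
  d <- dim(ts@signal)
  dec <- samplingRate(ts) / fsOut
  nOut <- floor((d[3L] - 1) / dec) + 1
  out <- array(0, dim = c(d[1L], d[2L], nOut))
  for (e in seq_len(d[1L])) for (tr in seq_len(d[2L]))
    out[e, tr, ] <- extractMuae(ts@signal[e, tr, ], fsIn = samplingRate(ts),
                                fsOut = fsOut, ...)
  TrialSet(out, fs = fsOut, alignment = ts@alignment,
           condition = ts@condition, electrodeInfo = ts@electrodeInfo)
}
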