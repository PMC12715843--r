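# Analytic amplitude/phase features, time-series correlation,
# phase-amplitude coupling (Modulation Index) and its surrogate null.

#' Instantaneous amplitude and phase of a band-limited series
#'
#' The analytic signal is computed on the full series and then cropped
#' to the analysis window, so Hilbert edge effects stay outside the
#' window. An identically-zero input yields amplitude 0 and phase 0
#' with the degeneracy flag set.
#'
#' @param x band-limited numeric series (one trial).
#' @param fs sampling rate, Hz.
#' @param windowMs optional analysis window in ms relative to stimulus
#'   onset; requires \code{alignmentMs}. NULL keeps the full series.
#' @param alignmentMs stimulus onset within the series, ms.
#' @return List: \code{amplitude} (>= 0), \code{phase} (radians,
#'   (-pi, pi]), \code{degenerate} (logical).
#' @examples
#' t <- seq(0, 2, by = 1e-3)
#' f <- analyticFeatures(3 * sin(2 * pi * 10 * t), fs = 1000)
#' mean(f$amplitude[500:1500]) # ~3
#' @export
analyticFeatures <- function(x, fs, windowMs = NULL, alignmentMs = 0) {
  if (all(x == 0)) {
    keep <- if (is.null(windowMs)) seq_along(x) else
      .windowIndex(windowMs, alignmentMs, fs, length(x))
    return(list(amplitude = numeric(length(keep)),
                phase = numeric(length(keep)), degenerate = TRUE))
  }
  z <- analyticSignal(x)
  keep <- if (is.null(windowMs)) seq_along(x) else
    .windowIndex(windowMs, alignmentMs, fs, length(x))
  list(amplitude = Mod(z)[keep], phase = .wrapPhase(Arg(z)[keep]),
       degenerate = FALSE)
}

#' Per-band analytic features of an EEG electrode
#'
#' Band-filters every trial of the given condition, then either
#' concatenates single-trial features or averages the band-limited
#' series across trials before taking the analytic signal
#' (trial-averaged), and crops to the analysis window.
#'
#' @param ts an EEG \linkS4class{TrialSet} (raw; filtering is applied
#'   here) or a named list of band-filtered TrialSets from
#'   \code{\link{bandDecompose}}.
#' @param electrode electrode index.
#' @param condition flicker frequency selecting the trials.
#' @param bands band table.
#' @param windowMs analysis window, ms post-onset (default 400-1800).
#' @param granularity "trial-averaged" or "single-trial".
#' @param lineNoise when \code{ts} is a raw TrialSet, notch line noise
#'   before band filtering.
#' @return An \linkS4class{AnalyticFeatures}.
#' @export
computeBandFeatures <- function(ts, electrode = 1, condition,
                                bands = defaultBands(),
                                windowMs = c(400, 1800),
                                granularity = c("trial-averaged",
                                                "single-trial"),
                                lineNoise = TRUE) {
  granularity <- match.arg(granularity)
  if (is(ts, "TrialSet")) {
    fs <- samplingRate(ts); align <- stimulusOnset(ts)
    trials <- which(trialConditions(ts) == condition)
    if (!length(trials)) stop("no trials of condition ", condition)
    raw <- lapply(trials, function(tr) {
      x <- trialSignal(ts, electrode, tr)
      if (lineNoise) x <- removeLineNoise(x, fs)
      x
    })
    bandSeries <- lapply(seq_len(nrow(bands)), function(k)
      lapply(raw, function(x) filterBand(x, fs, bands[k, ])))
  } else {
    stopifnot(all(bands$name %in% names(ts)))
    fs <- samplingRate(ts[[bands$name[1L]]])
    align <- stimulusOnset(ts[[bands$name[1L]]])
    trials <- which(trialConditions(ts[[bands$name[1L]]]) == condition)
    if (!length(trials)) stop("no trials of condition ", condition)
    bandSeries <- lapply(bands$name, function(bname)
      lapply(trials, function(tr) trialSignal(ts[[bname]], electrode, tr)))
  }
  nBands <- nrow(bands)
  if (granularity == "trial-averaged") {
    amp <- phs <- NULL
    degen <- logical(nBands)
    for (k in seq_len(nBands)) {
      avg <- Reduce(`+`, bandSeries[[k]]) / length(trials)
      f <- analyticFeatures(avg, fs, windowMs, align)
      degen[k] <- f$degenerate
      amp <- cbind(amp, f$amplitude)
      phs <- cbind(phs, f$phase)
    }
    trialIndex <- rep.int(0L, nrow(amp))
  } else {
    degen <- logical(nBands)
    perTrial <- lapply(seq_along(trials), function(it) {
      a <- p <- NULL
      for (k in seq_len(nBands)) {
        f <- analyticFeatures(bandSeries[[k]][[it]], fs, windowMs, align)
        degen[k] <<- degen[k] || f$degenerate
        a <- cbind(a, f$amplitude)
        p <- cbind(p, f$phase)
      }
      list(a = a, p = p)
    })
    amp <- do.call(rbind, lapply(perTrial, `[[`, "a"))
    phs <- do.call(rbind, lapply(perTrial, `[[`, "p"))
    nWin <- nrow(perTrial[[1L]]$a)
    trialIndex <- rep(trials, each = nWin)
  }
  colnames(amp) <- colnames(phs) <- bands$name
  new("AnalyticFeatures", amplitude = amp, phase = phs, fs = fs,
      windowMs = windowMs, granularity = granularity,
      trialIndex = as.integer(trialIndex), degenerate = degen,
      bands = bands)
}

#' Pearson correlation between two time series
#'
#' @param x,y equal-length numeric series (length >= 3, finite).
#' @return Pearson r in [-1, 1].
#' @examples
#' correlateSeries(1:10, (1:10)^2)
#' @export
correlateSeries <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 3L) stop("need at least 3 samples")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("series must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: a series has zero variance")
  stats::cor(x, y)
}

#' Modulation Index of phase-amplitude coupling
#'
#' Phases are binned into \code{nBins} equal intervals covering
#' (-180, 180] degrees; the mean amplitude per bin, normalized to sum
#' one, forms the phase-amplitude distribution P. The MI is the
#' Kullback-Leibler divergence of P from the uniform distribution,
#' normalized by log(nBins): MI = (log N - H(P)) / log N, in [0, 1].
#' Empty bins get probability 0 and contribute 0 to the entropy
#' (0 log 0 := 0); a warning reports undersampled bins.
#'
#' @param phase radians, any real values (wrapped internally).
#' @param amplitude nonnegative series, same length.
#' @param nBins number of phase bins (default 18, i.e. 20 degrees).
#' @return MI in [0, 1].
#' @examples
#' ph <- runif(1e4, -pi, pi)
#' modulationIndex(ph, 1 + 0.5 * cos(ph))
#' @export
modulationIndex <- function(phase, amplitude, nBins = 18) {
  if (length(phase) != length(amplitude))
    stop("phase and amplitude must have equal length")
  if (length(phase) < 1L) stop("need at least one sample")
  if (any(amplitude < 0)) stop("amplitude must be nonnegative")
  if (all(amplitude == 0))
    stop("undefined MI: amplitude is identically zero")
  bin <- .phaseBins(phase, nBins)
  sums <- tabulate(bin, nBins)
  if (any(sums == 0L))
    warning(sum(sums == 0L), " empty phase bin(s); MI computed with ",
            "0 log 0 := 0")
  m <- numeric(nBins)
  tot <- rowsum(amplitude, bin)
  m[as.integer(rownames(tot))] <-
    tot / pmax(sums[as.integer(rownames(tot))], 1L)
  .miFromBinMeans(m, nBins)
}

# MI from per-bin mean amplitudes. KL is evaluated as
# sum p * log(N * m / S): for a flat distribution N*m/S is exactly 1,
# so MI is exactly 0; for a single occupied bin p = 1 and the ratio is
# exactly N, so MI is exactly 1.
.miFromBinMeans <- function(m, nBins) {
  S <- sum(m)
  occ <- m > 0
  sum((m[occ] / S) * log(nBins * m[occ] / S)) / log(nBins)
}

# Bin wrapped phases into 1..nBins over (-pi, pi].
.phaseBins <- function(phase, nBins) {
  ph <- .wrapPhase(phase)
  bin <- ceiling((ph + pi) / (2 * pi) * nBins)
  bin[bin < 1L] <- 1L
  bin[bin > nBins] <- nBins
  as.integer(bin)
}

#' Surrogate null distribution of the Modulation Index
#'
#' Each iteration applies a random circular shift (uniform between 10%
#' and 90% of the series length, preserving the amplitude
#' autocorrelation) to the phase series and recomputes the MI. The
#' percentile of the observed MI within the null is reported.
#'
#' @param phase,amplitude the coupled pair (see
#'   \code{\link{modulationIndex}}).
#' @param nIter number of surrogates (default 1000).
#' @param nBins phase bins.
#' @param seed integer seed for the shift draws.
#' @return An \linkS4class{MIResult}.
#' @export
miShuffleNull <- function(phase, amplitude, nIter = 1000, nBins = 18,
                          seed = 1) {
  if (nIter < 1) stop("nIter must be at least 1")
  n <- length(phase)
  obs <- modulationIndex(phase, amplitude, nBins)
  bin <- .phaseBins(phase, nBins)
  set.seed(as.integer(seed))
  shifts <- sample(floor(0.1 * n):ceiling(0.9 * n), nIter, replace = TRUE)
  null <- vapply(shifts, function(s) {
    sb <- c(bin[(s + 1L):n], bin[1L:s])
    sums <- tabulate(sb, nBins)
    m <- numeric(nBins)
    tot <- rowsum(amplitude, sb)
    m[as.integer(rownames(tot))] <-
      tot / pmax(sums[as.integer(rownames(tot))], 1L)
    .miFromBinMeans(m, nBins)
  }, numeric(1))
  new("MIResult", observed = obs, null = null,
      percentile = 100 * mean(null < obs) , nBins = nBins)
}

#' Phase-amplitude coupling grid across bands
#'
#' MI between the phase of every band and either the amplitude of every
#' band (7 x 7 matrix, rows = phase band, columns = amplitude band) or
#' an external amplitude series such as the MUAe (length-7 vector).
#' Band pairs whose amplitude is constant (no modulation possible)
#' score 0.
#'
#' @param features an \linkS4class{AnalyticFeatures}.
#' @param amplitude optional external amplitude series aligned with the
#'   feature rows (e.g. MUAe over the same window); NULL couples EEG
#'   bands among themselves.
#' @param nBins phase bins.
#' @return Matrix (phase band x amplitude band) or named vector.
#' @export
pacGrid <- function(features, amplitude = NULL, nBins = 18) {
  bn <- features@bands$name
  ph <- features@phase
  am <- features@amplitude
  miOrZero <- function(p, a) {
    if (stats::sd(a) < .Machine$double.eps^0.5) return(0)
    suppressWarnings(modulationIndex(p, a, nBins))
  }
  if (is.null(amplitude)) {
    out <- matrix(0, 7L, 7L, dimnames = list(phase = bn, amplitude = bn))
    for (j in seq_len(7L)) for (i in seq_len(7L))
      out[j, i] <- miOrZero(ph[, j], am[, i])
    out
  } else {
    if (length(amplitude) != nrow(ph))
      stop("amplitude series does not match the feature window")
    stats::setNames(vapply(seq_len(7L), function(j)
      miOrZero(ph[, j], amplitude), numeric(1)), bn)
  }
}

#' Trial-averaged series per electrode
#'
#' Pointwise mean across the trials of one condition.
#'
#' @param ts a \linkS4class{TrialSet}.
#' @param condition flicker frequency selecting trials.
#' @return Matrix (electrode x time).
#' @export
trialAverage <- function(ts, condition) {
  sel <- which(trialConditions(ts) == condition)
  if (!length(sel)) stop("no trials of condition ", condition)
  apply(ts@signal[, sel, , drop = FALSE], c(1L, 3L), mean)
}
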