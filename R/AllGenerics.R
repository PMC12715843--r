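#' @include AllClasses.R
NULL

#' Accessors for TrialSet objects
#'
#' \code{nTrials}, \code{nElectrodes}, \code{nTimepoints} return counts;
#' \code{samplingRate} the sampling rate in Hz; \code{stimulusOnset} the
#' onset alignment in ms; \code{trialConditions} the per-trial flicker
#' frequency; \code{electrodeInfo} the electrode metadata table;
#' \code{trialSignal} the signal array (optionally sliced).
#'
#' @param x a \linkS4class{TrialSet}.
#' @param electrode,trial optional integer indices to slice.
#' @return See individual descriptions.
#' @name TrialSet-accessors
#' @aliases nTrials nElectrodes nTimepoints samplingRate stimulusOnset
#'   trialConditions electrodeInfo trialSignal
#' @examples
#' sig <- array(0, dim = c(1, 2, 50))
#' info <- data.frame(name = "E1", kind = "eeg", depth = NA)
#' ts <- TrialSet(sig, fs = 1000, alignment = 10, condition = c(0, 10),
#'                electrodeInfo = info)
#' nTrials(ts); samplingRate(ts)
NULL

#' @rdname TrialSet-accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname TrialSet-accessors
#' @export
setGeneric("nElectrodes", function(x) standardGeneric("nElectrodes"))
#' @rdname TrialSet-accessors
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))
#' @rdname TrialSet-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname TrialSet-accessors
#' @export
setGeneric("stimulusOnset", function(x) standardGeneric("stimulusOnset"))
#' @rdname TrialSet-accessors
#' @export
setGeneric("trialConditions", function(x) standardGeneric("trialConditions"))
#' @rdname TrialSet-accessors
#' @export
setGeneric("electrodeInfo", function(x) standardGeneric("electrodeInfo"))
#' @rdname TrialSet-accessors
#' @export
setGeneric("trialSignal",
           function(x, electrode = NULL, trial = NULL)
             standardGeneric("trialSignal"))

#' @rdname TrialSet-accessors
setMethod("nTrials", "TrialSet", function(x) dim(x@signal)[2L])
#' @rdname TrialSet-accessors
setMethod("nElectrodes", "TrialSet", function(x) dim(x@signal)[1L])
#' @rdname TrialSet-accessors
setMethod("nTimepoints", "TrialSet", function(x) dim(x@signal)[3L])
#' @rdname TrialSet-accessors
setMethod("samplingRate", "TrialSet", function(x) x@fs)
#' @rdname TrialSet-accessors
setMethod("stimulusOnset", "TrialSet", function(x) x@alignment)
#' @rdname TrialSet-accessors
setMethod("trialConditions", "TrialSet", function(x) x@condition)
#' @rdname TrialSet-accessors
setMethod("electrodeInfo", "TrialSet", function(x) x@electrodeInfo)
#' @rdname TrialSet-accessors
setMethod("trialSignal", "TrialSet", function(x, electrode = NULL,
                                              trial = NULL) {
  if (is.null(electrode) && is.null(trial)) return(x@signal)
  if (is.null(electrode)) electrode <- seq_len(dim(x@signal)[1L])
  if (is.null(trial)) trial <- seq_len(dim(x@signal)[2L])
  out <- x@signal[electrode, trial, , drop = FALSE]
  if (length(electrode) == 1L && length(trial) == 1L) drop(out) else out
})

#' Subset a TrialSet by trials
#'
#' \code{x[i]} keeps trials \code{i} (with their condition labels).
#'
#' @param x a \linkS4class{TrialSet}.
#' @param i trial indices or a logical mask over trials.
#' @param j,...,drop ignored.
#' @return A \linkS4class{TrialSet}.
#' @export
setMethod("[", "TrialSet", function(x, i, j, ..., drop = FALSE) {
  if (is.logical(i)) i <- which(i)
  TrialSet(x@signal[, i, , drop = FALSE], fs = x@fs,
           alignment = x@alignment, condition = x@condition[i],
           electrodeInfo = x@electrodeInfo)
})

setMethod("show", "TrialSet", function(object) {
  d <- dim(object@signal)
  cat(sprintf(
    "TrialSet: %d electrode(s) x %d trial(s) x %d samples @ %g Hz\n",
    d[1L], d[2L], d[3L], object@fs))
  cat(sprintf("  stimulus onset at %g ms; conditions: %s Hz\n",
              object@alignment,
              paste(sort(unique(object@condition)), collapse = ", ")))
  kinds <- table(object@electrodeInfo$kind)
  cat("  electrodes:",
      paste(sprintf("%s (%d)", names(kinds), kinds), collapse = ", "), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    paste0("SimulationConfig: %d session(s), %d EEG + %d intracranial ",
           "electrodes\n"),
    object@nSessions, object@nEegElectrodes,
    object@nIntracranialElectrodes))
  cat(sprintf("  %d trials/condition at %s Hz; EEG %g Hz, wideband %g Hz\n",
              object@trialsPerCondition,
              paste(object@conditions, collapse = "/"),
              object@fsEeg, object@fsWideband))
  cat(sprintf("  trial layout %s ms; seed %d\n",
              paste(object@trialLayout, collapse = "+"),
              as.integer(object@seed)))
})

setMethod("show", "MIResult", function(object) {
  cat(sprintf(
    "MIResult: observed MI = %.4g (%d-bin), percentile %.1f of %d nulls\n",
    object@observed, as.integer(object@nBins), object@percentile,
    length(object@null)))
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf(
    "ModelFit: %d predictors (%d retained), %d outer folds\n",
    length(object@coefficients),
    sum(rowSums(object@foldCoefficients != 0) > 0),
    length(object@foldR)))
  cat(sprintf("  fold-averaged r = %.4f; adjusted R^2 = %.4f\n",
              object@meanR, object@adjustedR2))
})

setMethod("show", "AnalyticFeatures", function(object) {
  cat(sprintf(
    "AnalyticFeatures: %d samples x %d bands (%s), window [%g, %g] ms\n",
    nrow(object@amplitude), ncol(object@amplitude), object@granularity,
    object@windowMs[1L], object@windowMs[2L]))
})

#' Extract ModelFit metrics
#'
#' @param fit a \linkS4class{ModelFit}.
#' @return \code{foldAveragedR}: the mean held-out Pearson r across outer
#'   folds. \code{modelCoefficients}: named coefficient vector
#'   (standardized scale unless \code{raw = TRUE}).
#' @param raw return coefficients on the raw predictor scale.
#' @name ModelFit-accessors
#' @export
foldAveragedR <- function(fit) fit@meanR

#' @rdname ModelFit-accessors
#' @export
modelCoefficients <- function(fit, raw = FALSE) {
  if (raw) fit@rawCoefficients else fit@coefficients
}
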