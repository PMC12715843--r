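# The MUAe prediction model: design-matrix construction from band
# features, leakage-free z-scoring, L1-regularized fitting with nested
# cross-validation, and the reported metrics and contrasts.

#' Names of the design-matrix columns
#'
#' Column order is fixed: 7 band amplitudes, then sin/cos of the 7 band
#' phases, then sin/cos of the 12 amplitude-phase interactions
#' (amplitude bands beta..high-gamma crossed with phase bands
#' delta..alpha), and optionally the stimulus-phase sin/cos pair.
#'
#' @param includeStimulusPhase append the two stimulus-phase columns.
#' @param bands band table.
#' @return Character vector of length 45 (or 47).
#' @examples
#' length(designColumnNames())
#' @export
designColumnNames <- function(includeStimulusPhase = FALSE,
                              bands = defaultBands()) {
  bn <- bands$name
  ampB <- bn[4:7]
  phB <- bn[1:3]
  nm <- c(paste0("amp_", bn),
          as.vector(t(cbind(paste0("phase_sin_", bn),
                            paste0("phase_cos_", bn)))),
          unlist(lapply(ampB, function(i)
            unlist(lapply(phB, function(j)
              c(paste0("int_sin_", i, "_", j),
                paste0("int_cos_", i, "_", j)))))))
  if (includeStimulusPhase) nm <- c(nm, "stim_sin", "stim_cos")
  nm
}

# The 45-column feature basis shared by the model and the generator's
# ground truth: 7 amplitudes, 14 phase sin/cos, 24 interaction sin/cos.
.rawDesign <- function(A, P, bands = defaultBands()) {
  bn <- bands$name
  X <- matrix(0, nrow(A), 45L)
  X[, 1:7] <- A
  sinP <- sin(P); cosP <- cos(P)
  X[, seq(8L, 20L, by = 2L)] <- sinP
  X[, seq(9L, 21L, by = 2L)] <- cosP
  k <- 22L
  for (i in 4:7) {
    for (j in 1:3) {
      X[, k] <- A[, i] * sinP[, j]
      X[, k + 1L] <- A[, i] * cosP[, j]
      k <- k + 2L
    }
  }
  colnames(X) <- designColumnNames(FALSE, bands)
  X
}

# Per-column annotation matching designColumnNames().
.designAnnotation <- function(includeStimulusPhase = FALSE,
                              bands = defaultBands()) {
  bn <- bands$name
  ampB <- bn[4:7]; phB <- bn[1:3]
  ann <- data.frame(
    column = designColumnNames(includeStimulusPhase, bands),
    category = c(rep("amplitude", 7L), rep("phase", 14L),
                 rep("coupling", 24L),
                 if (includeStimulusPhase) rep("stimulus_phase", 2L)),
    band = c(bn, rep(bn, each = 2L),
             rep(ampB, each = 6L),
             if (includeStimulusPhase) rep(NA_character_, 2L)),
    phase_band = c(rep(NA_character_, 7L), rep(bn, each = 2L),
                   rep(rep(phB, each = 2L), times = 4L),
                   if (includeStimulusPhase) rep("stimulus", 2L)),
    role = c(rep(NA_character_, 7L), rep(c("sin", "cos"), 7L),
             rep(c("sin", "cos"), 12L),
             if (includeStimulusPhase) c("sin", "cos")),
    stringsAsFactors = FALSE
  )
  ann
}

#' Phase of a sinusoidally flickering stimulus
#'
#' The screen luminance is modeled as sinusoidal with phase zero at
#' stimulus onset, so the phase at time \code{t} seconds after onset is
#' \code{2 * pi * fStim * t}, wrapped to (-pi, pi].
#'
#' @param tSec time since stimulus onset, seconds (vectorized).
#' @param fStim flicker frequency, Hz; must be positive — the 0 Hz
#'   (non-flicker) condition has no defined stimulus phase.
#' @return Phase in radians, (-pi, pi].
#' @examples
#' stimulusPhase(0.05, 10) # half a cycle: pi
#' @export
stimulusPhase <- function(tSec, fStim) {
  if (length(fStim) != 1L || fStim <= 0)
    stop("stimulus phase is undefined for fStim = 0 ",
         "(non-flicker condition)")
  .wrapPhase(2 * pi * fStim * tSec)
}

#' Build the predictor matrix from analytic band features
#'
#' Columns, in order: the 7 band amplitudes A_k(t); sin and cos of each
#' band phase (the circular phase linearized into two components); the
#' 12 amplitude-phase interactions A_i(t) sin(phi_j(t)) and
#' A_i(t) cos(phi_j(t)) for amplitude bands i in {beta, low-gamma,
#' gamma, high-gamma} and phase bands j in {delta, theta, alpha}; and,
#' if requested, sin and cos of the stimulus phase.
#'
#' @param features an \linkS4class{AnalyticFeatures} object.
#' @param spec a \linkS4class{ModelSpec}.
#' @param fStim stimulus frequency, Hz; required (positive) when
#'   \code{spec} includes the stimulus phase.
#' @param tSec time since stimulus onset per row, seconds; defaults to
#'   the feature window grid (recycled over trials for single-trial
#'   features).
#' @return Numeric matrix (samples x 45 or 47) with an \code{annotation}
#'   attribute (data.frame: column, category, band, phase_band, role).
#' @export
buildDesignMatrix <- function(features, spec = modelSpec(), fStim = NULL) {
  A <- features@amplitude
  P <- features@phase
  bn <- spec@bands$name
  if (ncol(A) != 7L)
    stop("features must cover the seven canonical bands")
  colnames(A) <- colnames(P) <- bn
  n <- nrow(A)
  X <- .rawDesign(A, P, spec@bands)
  if (spec@includeStimulusPhase) {
    if (is.null(fStim) || fStim <= 0)
      stop("stimulus-phase predictors requested but fStim is 0 or missing")
    nWin <- round(diff(features@windowMs) * features@fs / 1000)
    tWin <- features@windowMs[1L] / 1000 + (seq_len(nWin) - 1L) / features@fs
    tSec <- rep(tWin, length.out = n)
    phi <- stimulusPhase(tSec, fStim)
    X <- cbind(X, sin(phi), cos(phi))
  }
  colnames(X) <- designColumnNames(spec@includeStimulusPhase, spec@bands)
  attr(X, "annotation") <-
    .designAnnotation(spec@includeStimulusPhase, spec@bands)
  X
}

#' z-score design columns using training-split statistics
#'
#' Centers and scales every column by the mean and SD computed on the
#' training rows only; test rows are transformed with the same
#' statistics, so no held-out sample influences the standardization.
#' Columns constant on the training split are mapped to all zeros with
#' a warning.
#'
#' @param X numeric matrix.
#' @param trainIdx integer rows defining the statistics source; default
#'   all rows.
#' @return List: \code{X} (standardized matrix), \code{center},
#'   \code{scale} (per-column statistics).
#' @examples
#' z <- zscoreColumns(matrix(rnorm(40), 10, 4))
#' colMeans(z$X)
#' @export
zscoreColumns <- function(X, trainIdx = seq_len(nrow(X))) {
  if (length(trainIdx) < 2L)
    stop("at least 2 training samples are required for z-scoring")
  ctr <- colMeans(X[trainIdx, , drop = FALSE])
  scl <- apply(X[trainIdx, , drop = FALSE], 2L, stats::sd)
  const <- !is.finite(scl) | scl < .Machine$double.eps^0.5
  if (any(const)) {
    warning("constant column(s) mapped to zero: ",
            paste(colnames(X)[const], collapse = ", "))
    scl[const] <- 1
  }
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  Xs[, const] <- 0
  list(X = Xs, center = ctr, scale = scl)
}

# Contiguous-block fold assignment over n samples (autocorrelated
# series: interleaved folds would leak between train and test).
.contiguousFolds <- function(n, k) {
  bounds <- floor(seq(0, n, length.out = k + 1))
  rep(seq_len(k), times = diff(bounds))
}

# Lambda grid on a standardized training design (glmnet convention:
# objective RSS/(2n) + lambda * |beta|_1).
.lambdaGrid <- function(Xs, y, nLambda, minRatio) {
  n <- nrow(Xs)
  lmax <- max(abs(crossprod(Xs, y - mean(y)))) / n
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * minRatio), length.out = nLambda))
}

#' Fit the L1-regularized MUAe model with nested cross-validation
#'
#' Outer loop: the samples are split into \code{outerFolds} contiguous
#' blocks; each block is held out in turn. Inner loop: the training
#' block is itself split into \code{innerFolds} contiguous blocks, a
#' shared log-spaced penalty grid (from lambda_max down to
#' \code{lambdaMinRatio * lambda_max}) is evaluated on every inner
#' split, and the penalty minimizing the mean inner-fold squared error
#' is selected. The model is then refit on the full training block at
#' that penalty and applied to the held-out block. Predictors are
#' z-scored with training statistics only, inside every loop. Held-out
#' Pearson r per fold and its average are reported; a constant held-out
#' prediction (fully sparse model) scores r = 0.
#'
#' @param X design matrix from \code{\link{buildDesignMatrix}}.
#' @param y MUAe response, same length as \code{nrow(X)} (native scale).
#' @param spec a \linkS4class{ModelSpec}.
#' @return A \linkS4class{ModelFit}.
#' @export
fitLassoNestedCv <- function(X, y, spec = modelSpec()) {
  n <- nrow(X)
  if (length(y) != n) stop("X and y must be aligned")
  if (stats::sd(y) == 0)
    stop("degenerate response: y has zero variance")
  if (n < 10 * spec@outerFolds)
    stop("need at least 10 samples per outer fold")
  ann <- attr(X, "annotation")
  if (is.null(ann)) ann <- .designAnnotation(ncol(X) == 47L, spec@bands)
  p <- ncol(X)
  foldId <- .contiguousFolds(n, spec@outerFolds)
  preds <- numeric(n)
  foldR <- foldLambda <- intercepts <- numeric(spec@outerFolds)
  foldCoef <- matrix(0, p, spec@outerFolds,
                     dimnames = list(colnames(X), NULL))
  rawCoef <- matrix(0, p, spec@outerFolds)
  foldScaling <- vector("list", spec@outerFolds)

  for (f in seq_len(spec@outerFolds)) {
    trainIdx <- which(foldId != f)
    testIdx <- which(foldId == f)
    zs <- suppressWarnings(zscoreColumns(X, trainIdx))
    Xtr <- zs$X[trainIdx, , drop = FALSE]
    ytr <- y[trainIdx]
    lambdas <- .lambdaGrid(Xtr, ytr, spec@nLambda, spec@lambdaMinRatio)

    # inner CV over the shared grid
    innerId <- .contiguousFolds(length(trainIdx), spec@innerFolds)
    mse <- matrix(NA_real_, spec@innerFolds, length(lambdas))
    for (g in seq_len(spec@innerFolds)) {
      itr <- which(innerId != g)
      ite <- which(innerId == g)
      # standardize inside the inner split as well (leakage-free)
      izs <- suppressWarnings(zscoreColumns(X[trainIdx, , drop = FALSE],
                                            itr))
      fitI <- glmnet::glmnet(izs$X[itr, , drop = FALSE], ytr[itr],
                             lambda = lambdas, standardize = FALSE,
                             family = "gaussian")
      pr <- stats::predict(fitI, izs$X[ite, , drop = FALSE])
      # glmnet may drop grid points; align by nearest penalty value
      got <- vapply(fitI$lambda, function(l)
        which.min(abs(lambdas - l)), integer(1))
      mse[g, got] <- colMeans((pr - ytr[ite])^2)
    }
    meanMse <- colMeans(mse, na.rm = TRUE)
    best <- which.min(meanMse)
    lamStar <- lambdas[best]

    fitO <- glmnet::glmnet(Xtr, ytr, lambda = lambdas,
                           standardize = FALSE, family = "gaussian")
    beta <- as.numeric(stats::predict(fitO, type = "coefficients",
                                      s = lamStar, exact = FALSE))
    b0 <- beta[1L]; bz <- beta[-1L]
    yhat <- drop(zs$X[testIdx, , drop = FALSE] %*% bz) + b0
    preds[testIdx] <- yhat
    foldLambda[f] <- lamStar
    intercepts[f] <- b0
    foldCoef[, f] <- bz
    rawCoef[, f] <- bz / zs$scale
    foldScaling[[f]] <- list(center = zs$center, scale = zs$scale)
    foldR[f] <- if (stats::sd(yhat) < .Machine$double.eps^0.5) 0 else
      stats::cor(yhat, y[testIdx])
  }

  retained <- sum(rowSums(foldCoef != 0) > 0)
  adjR2 <- evaluateAdjustedR2(y, preds, retained)
  new("ModelFit",
      coefficients = stats::setNames(rowMeans(foldCoef), colnames(X)),
      rawCoefficients = stats::setNames(rowMeans(rawCoef), colnames(X)),
      foldCoefficients = foldCoef, annotation = ann,
      intercepts = intercepts, foldLambda = foldLambda,
      foldR = foldR, meanR = mean(foldR), adjustedR2 = adjR2,
      predictions = preds, foldId = as.integer(foldId), y = y,
      foldScaling = foldScaling,
      includeStimulusPhase = isTRUE(spec@includeStimulusPhase))
}

#' Adjusted R-squared of held-out predictions
#'
#' \code{1 - (1 - R2) * (n - 1) / (n - p - 1)}, where R2 is computed on
#' the concatenated held-out predictions and \code{p} is the number of
#' retained (nonzero) predictors.
#'
#' @param y observed response.
#' @param predictions held-out predictions, aligned with \code{y}.
#' @param nPredictors number of retained predictors.
#' @return Adjusted R-squared (can be negative).
#' @examples
#' evaluateAdjustedR2(1:10, 1:10, 1) # exact predictions: 1
#' @export
evaluateAdjustedR2 <- function(y, predictions, nPredictors) {
  n <- length(y)
  if (length(predictions) != n) stop("y and predictions must align")
  if (n <= nPredictors + 1)
    stop("need n > nPredictors + 1 for the adjustment")
  ssRes <- sum((y - predictions)^2)
  ssTot <- sum((y - mean(y))^2)
  r2 <- 1 - ssRes / ssTot
  1 - (1 - r2) * (n - 1) / (n - nPredictors - 1)
}

#' Summarize fitted coefficients by category
#'
#' Amplitude coefficients are reported as absolute values; each sin/cos
#' pair (band phases, interactions, stimulus phase) as the Euclidean
#' norm of the pair. Category means average over the 7 amplitude, 7
#' phase-norm, and 12 coupling-norm entries.
#'
#' @param fit a \linkS4class{ModelFit}.
#' @return List with \code{perPredictor} (data.frame: category, band,
#'   phase_band, norm) and \code{categoryMeans} (named numeric).
#' @export
summarizeCoefficients <- function(fit) {
  beta <- fit@coefficients
  ann <- fit@annotation
  rows <- list()
  amp <- ann$category == "amplitude"
  rows$amplitude <- data.frame(category = "amplitude",
                               band = ann$band[amp],
                               phase_band = NA_character_,
                               norm = abs(beta[amp]))
  pairNorm <- function(cat) {
    idx <- which(ann$category == cat & ann$role == "sin")
    data.frame(category = cat,
               band = ann$band[idx],
               phase_band = ann$phase_band[idx],
               norm = sqrt(beta[idx]^2 + beta[idx + 1L]^2))
  }
  rows$phase <- pairNorm("phase")
  rows$coupling <- pairNorm("coupling")
  if (any(ann$category == "stimulus_phase"))
    rows$stimulus_phase <- pairNorm("stimulus_phase")
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  means <- tapply(per$norm, per$category, mean)
  list(perPredictor = per,
       categoryMeans = means[unique(per$category)])
}

#' Compare a base and an extended model fit
#'
#' Both fits must share the response and the outer-fold partition.
#'
#' @param fitBase,fitExtended \linkS4class{ModelFit} objects on the same
#'   response and folds.
#' @return List: \code{deltaMeanR} and \code{deltaAdjustedR2}
#'   (extended - base).
#' @export
compareModels <- function(fitBase, fitExtended) {
  if (!isTRUE(all.equal(fitBase@y, fitExtended@y)) ||
      !identical(fitBase@foldId, fitExtended@foldId))
    stop("fits must share the response and the fold partition")
  list(deltaMeanR = fitExtended@meanR - fitBase@meanR,
       deltaAdjustedR2 = fitExtended@adjustedR2 - fitBase@adjustedR2)
}

#' Shallow vs deep laminar contrast of model performance
#'
#' Groups per-fit performance by electrode depth and reports, per
#' condition, the shallow mean, deep mean, and their difference.
#'
#' @param metrics data.frame with columns \code{electrode},
#'   \code{condition}, and \code{meanR} (one row per fit).
#' @param depthLabels named character vector mapping electrode name to
#'   "shallow" or "deep".
#' @return data.frame: condition, shallowR, deepR, deltaR
#'   (shallow - deep).
#' @export
layerContrast <- function(metrics, depthLabels) {
  depth <- depthLabels[as.character(metrics$electrode)]
  if (!any(depth == "shallow", na.rm = TRUE) ||
      !any(depth == "deep", na.rm = TRUE))
    stop("both shallow and deep electrode groups must be present")
  conds <- sort(unique(metrics$condition))
  out <- do.call(rbind, lapply(conds, function(cc) {
    sel <- metrics$condition == cc
    s <- mean(metrics$meanR[sel & depth == "shallow"])
    d <- mean(metrics$meanR[sel & depth == "deep"])
    data.frame(condition = cc, shallowR = s, deepR = d, deltaR = s - d)
  }))
  rownames(out) <- NULL
  out
}
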