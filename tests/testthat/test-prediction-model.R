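test_that("design matrix has the specified structure", {
  fe <- smallFeatures10()
  X <- buildDesignMatrix(fe)
  expect_identical(ncol(X), 45L)
  X2 <- buildDesignMatrix(fe, modelSpec(includeStimulusPhase = TRUE),
                          fStim = 10)
  expect_identical(ncol(X2), 47L)
  ann <- attr(X, "annotation")
  expect_identical(sum(ann$category == "amplitude"), 7L)
  expect_identical(sum(ann$category == "phase"), 14L)
  expect_identical(sum(ann$category == "coupling"), 24L)
  # exactly the 12 amplitude x phase interaction pairs
  pairs <- unique(ann[ann$category == "coupling", c("band", "phase_band")])
  expect_identical(nrow(pairs), 12L)
  expect_setequal(unique(pairs$band),
                  c("beta", "low_gamma", "gamma", "high_gamma"))
  expect_setequal(unique(pairs$phase_band), c("delta", "theta", "alpha"))
  # sin^2 + cos^2 = 1 for every phase pair before scaling
  for (b in defaultBands()$name)
    expect_equal(X[, paste0("phase_sin_", b)]^2 +
                   X[, paste0("phase_cos_", b)]^2,
                 rep(1, nrow(X)), tolerance = 1e-12)
  expect_equal(X2[, "stim_sin"]^2 + X2[, "stim_cos"]^2, rep(1, nrow(X2)))
  expect_error(buildDesignMatrix(fe, modelSpec(includeStimulusPhase = TRUE),
                                 fStim = 0), "fStim")
})

test_that("stimulus phase wraps a sinusoidal flicker from onset", {
  expect_equal(stimulusPhase(0, 10), 0)
  expect_equal(stimulusPhase(0.05, 10), pi)  # half a cycle at 10 Hz
  expect_equal(stimulusPhase(0.1, 10), 0)    # full cycle wraps to 0
  expect_error(stimulusPhase(0.1, 0), "undefined")
})

test_that("z-scoring standardizes on training statistics only", {
  set.seed(13)
  X <- cbind(a = rnorm(100, 5, 2), b = runif(100), c = rep(3, 100))
  expect_warning(z <- zscoreColumns(X, trainIdx = 1:60), "constant")
  expect_equal(unname(colMeans(z$X[1:60, 1:2])), c(0, 0),
               tolerance = 1e-10)
  expect_equal(unname(apply(z$X[1:60, 1:2], 2, sd)), c(1, 1),
               tolerance = 1e-10)
  expect_true(all(z$X[, "c"] == 0))
  # affine invariance: z(a x + b) = z(x) for a > 0
  z1 <- zscoreColumns(cbind(x = X[, 1]))$X
  z2 <- zscoreColumns(cbind(x = 4 * X[, 1] + 7))$X
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("noise-free linear responses are recovered near-perfectly", {
  fe <- smallFeatures10()
  X <- buildDesignMatrix(fe)
  y <- 2 * X[, "amp_alpha"] - 3 * X[, "phase_sin_delta"] +
    1.5 * X[, "amp_gamma"]
  fit <- fitLassoNestedCv(X, y)
  expect_gt(foldAveragedR(fit), 0.99)
  support <- names(which(abs(modelCoefficients(fit)) > 1e-8))
  expect_true(all(c("amp_alpha", "phase_sin_delta", "amp_gamma")
                  %in% support))
})

test_that("an all-penalty grid yields the null model", {
  fe <- smallFeatures10()
  X <- buildDesignMatrix(fe)
  set.seed(14)
  y <- rnorm(nrow(X))
  spec <- modelSpec(nLambda = 1, lambdaMinRatio = 1)  # grid = lambda_max
  fit <- fitLassoNestedCv(X, y, spec)
  expect_true(all(fit@foldCoefficients == 0))
  expect_equal(foldAveragedR(fit), 0)  # constant predictions score 0
  # each fold predicts its training mean
  for (f in 1:5) {
    tr <- fit@foldId != f
    expect_equal(unique(round(fit@predictions[!tr], 10)),
                 round(mean(y[tr]), 10))
  }
})

test_that("cross-validation partitions samples without leakage", {
  fe <- smallFeatures10()
  X <- buildDesignMatrix(fe)
  set.seed(15)
  y <- X[, "amp_gamma"] + rnorm(nrow(X))
  fit <- fitLassoNestedCv(X, y)
  # outer-fold test sets partition the window
  expect_identical(sort(unique(fit@foldId)), 1:5)
  expect_identical(length(fit@foldId), nrow(X))
  # contiguous blocks
  expect_true(all(diff(fit@foldId) >= 0))
  # scaling statistics come from training rows only
  for (f in 1:5) {
    tr <- which(fit@foldId != f)
    expect_equal(unname(fit@foldScaling[[f]]$center),
                 unname(colMeans(X[tr, ])), tolerance = 1e-12)
  }
  expect_error(fitLassoNestedCv(X, rep(1, nrow(X))), "zero variance")
  expect_error(fitLassoNestedCv(X[1:20, ], y[1:20]), "10 samples")
})

test_that("the retained-predictor count shrinks as the penalty grows", {
  fe <- smallFeatures10()
  X <- buildDesignMatrix(fe)
  set.seed(16)
  y <- X[, "amp_gamma"] + 0.5 * X[, "phase_cos_alpha"] + rnorm(nrow(X))
  zs <- zscoreColumns(X)
  lambdas <- eegMUAe:::.lambdaGrid(zs$X, y, 20, 1e-4)
  fitPath <- glmnet::glmnet(zs$X, y, lambda = lambdas,
                            standardize = FALSE)
  nnz <- colSums(as.matrix(fitPath$beta) != 0)
  # lambda_max leaves at most a boundary coefficient; as the penalty
  # shrinks the support grows (allowing the solver's occasional
  # drop-and-re-enter wiggle of a coefficient or two)
  expect_lte(nnz[1], 1)
  expect_true(all(nnz - cummax(nnz) >= -2))
  expect_gt(nnz[length(nnz)], 30)
})

test_that("adjusted R-squared follows its definition", {
  set.seed(17)
  y <- rnorm(50)
  expect_equal(evaluateAdjustedR2(y, y, 3), 1)
  expect_lte(evaluateAdjustedR2(y, rep(mean(y), 50), 3), 0)
  pred <- y + rnorm(50, sd = 0.5)
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_equal(evaluateAdjustedR2(y, pred, 7),
               1 - (1 - r2) * 49 / (50 - 7 - 1))
  expect_error(evaluateAdjustedR2(y[1:5], pred[1:5], 6), "nPredictors")
})

test_that("coefficient summaries report Euclidean pair norms", {
  fe <- smallFeatures10()
  X <- buildDesignMatrix(fe)
  set.seed(18)
  fit <- fitLassoNestedCv(X, X[, "amp_gamma"] + rnorm(nrow(X), sd = 2))
  # overwrite with hand values to pin the norm arithmetic
  fit@coefficients[] <- 0
  fit@coefficients["phase_sin_theta"] <- 3
  fit@coefficients["phase_cos_theta"] <- 4
  fit@coefficients["amp_delta"] <- -2
  s <- summarizeCoefficients(fit)
  expect_equal(s$perPredictor$norm[s$perPredictor$band == "theta" &
                                     s$perPredictor$category == "phase"],
               5)
  expect_equal(s$perPredictor$norm[s$perPredictor$band == "delta" &
                                     s$perPredictor$category ==
                                     "amplitude"], 2)
  expect_identical(sum(s$perPredictor$category == "amplitude"), 7L)
  expect_identical(sum(s$perPredictor$category == "phase"), 7L)
  expect_identical(sum(s$perPredictor$category == "coupling"), 12L)
  fit@coefficients[] <- 0
  expect_true(all(summarizeCoefficients(fit)$perPredictor$norm == 0))
})

test_that("model comparison requires a shared fold partition", {
  fe <- smallFeatures10()
  X <- buildDesignMatrix(fe)
  set.seed(19)
  y <- X[, "amp_gamma"] + rnorm(nrow(X))
  fit <- fitLassoNestedCv(X, y)
  d <- compareModels(fit, fit)
  expect_equal(d$deltaMeanR, 0)
  expect_equal(d$deltaAdjustedR2, 0)
  other <- fitLassoNestedCv(X[1:700, ], y[1:700])
  expect_error(compareModels(fit, other), "fold partition")
})

test_that("layer contrast groups by depth and rejects missing groups", {
  metrics <- data.frame(
    electrode = c("IC1", "IC2", "IC1", "IC2"),
    condition = c(10, 10, 0, 0),
    meanR = c(0.5, 0.2, 0.1, 0.05))
  depth <- c(IC1 = "shallow", IC2 = "deep")
  lc <- layerContrast(metrics, depth)
  expect_equal(lc$deltaR[lc$condition == 10], 0.3)
  expect_equal(lc$deltaR[lc$condition == 0], 0.05)
  expect_error(layerContrast(metrics, c(IC1 = "shallow", IC2 = "shallow")),
               "deep")
})
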