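test_that("identical configs yield identical datasets", {
  cfg <- simulationConfig(nEegElectrodes = 1, nIntracranialElectrodes = 1,
                          trialsPerCondition = 1, conditions = c(0, 10),
                          seed = 7)
  a <- generateDataset(cfg)
  b <- generateDataset(cfg)
  expect_identical(a$sessions[[1]]$eeg@signal, b$sessions[[1]]$eeg@signal)
  expect_identical(a$sessions[[1]]$wideband@signal,
                   b$sessions[[1]]$wideband@signal)
  expect_identical(a$truth@coefficients, b$truth@coefficients)
})

test_that("flicker trials carry SSVEP power at the stimulus frequency", {
  eeg <- smallDataset()$sessions[[1]]$eeg
  sp <- powerSpectrum(eeg, condition = 10, windowMs = c(500, 1500))
  freqs <- attr(sp, "frequencies")
  i10 <- which(freqs == 10)
  # local maximum at the 10 Hz bin, and SNR > 1 against neighbors
  expect_gt(sp[1, i10], sp[1, i10 - 1])
  expect_gt(sp[1, i10], sp[1, i10 + 1])
  expect_gt(computeSnr(sp[1, ], 10, freqs), 1)
})

test_that("config invariants are enforced", {
  expect_error(simulationConfig(conditions = numeric(0)), "conditions")
  expect_error(simulationConfig(fsWideband = 2500, fsEeg = 1000),
               "multiple")
  expect_error(simulationConfig(trialsPerCondition = 0), "counts")
  expect_error(simulationConfig(artifactRate = 1.5), "artifactRate")
  expect_error(
    simulationConfig(pacPairs = data.frame(phase_band = "delta",
                                           amp_band = "gamma",
                                           kappa = 2)),
    "kappa")
})

test_that("spike rendering is a rate-faithful point process", {
  # rate 0, no noise: silent trace
  expect_identical(generateSpikeWideband(rep(0, 100), fs = 30000,
                                         noiseSd = 0, seed = 1),
                   rep(0, 3000))
  expect_error(generateSpikeWideband(c(1, -1), fs = 30000), "nonnegative")
  # 100 spikes/s over 2 s: ~200 spikes; count waveform onsets over seeds
  counts <- vapply(1:20, function(s) {
    x <- generateSpikeWideband(rep(100, 2000), fs = 30000, noiseSd = 0,
                               seed = s)
    r <- rle(x != 0)
    sum(r$values)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 200), 3 * sqrt(200))
})

test_that("step in the spike rate is visible in the extracted MUAe", {
  x <- generateSpikeWideband(c(rep(10, 1000), rep(100, 1000)),
                             fs = 30000, seed = 3)
  env <- extractMuae(x, fsIn = 30000, fsOut = 1000)
  expect_gt(mean(env[1001:2000]), mean(env[1:1000]))
})

test_that("artifact injection respects the configured rate", {
  sess <- smallDataset()$sessions[[1]]
  none <- injectArtifacts(sess, 0, seed = 1)
  expect_identical(none$injected, integer(0))
  expect_identical(none$session$eeg@signal, sess$eeg@signal)

  half <- injectArtifacts(sess, 0.5, seed = 1)
  expect_length(half$injected, round(0.5 * nTrials(sess$eeg)))

  all_ <- injectArtifacts(sess, 1, seed = 1)
  expect_identical(all_$injected, seq_len(nTrials(sess$eeg)))
  # injected EEG trials now exceed 100 uV somewhere
  mx <- apply(abs(all_$session$eeg@signal), 2, max)
  expect_true(all(mx > 100))
})

test_that("ground-truth bookkeeping matches the generated data", {
  ds <- smallDataset()
  truth <- ds$truth
  expect_length(truth@coefficients, 45)
  expect_identical(truth@depthLabels, c("shallow", "deep"))
  rates <- truth@rateEnvelopes[[1]]
  expect_identical(dim(rates)[1:2],
                   c(2L, nTrials(ds$sessions[[1]]$eeg)))
  expect_true(all(rates >= 0))
})
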