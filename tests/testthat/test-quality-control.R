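test_that("power spectrum localizes tones with Parseval-consistent power", {
  n <- 3400
  tt <- (seq_len(n) - 1) / 1000
  mk <- function(f, a) a * sin(2 * pi * f * tt)
  sig <- array(0, dim = c(1, 2, n))
  sig[1, 1, ] <- mk(10, 2) + mk(20, 1)
  sig[1, 2, ] <- mk(10, 2) + mk(20, 1)
  ts <- toyTrialSet(sig, condition = c(10, 10))
  sp <- powerSpectrum(ts, condition = 10)
  freqs <- attr(sp, "frequencies")
  expect_identical(freqs[which.max(sp[1, ])], 10)
  ratio <- sp[1, freqs == 10] / sp[1, freqs == 20]
  expect_lt(abs(ratio - 4), 0.2)  # amplitude 2:1 -> power 4:1 within 5%
  zero <- toyTrialSet(array(0, dim = c(1, 2, n)), condition = c(0, 0))
  expect_true(all(powerSpectrum(zero) == 0))
})

test_that("SNR follows the neighbor-bin definition", {
  flat <- rep(2, 11)
  expect_equal(computeSnr(flat, 5, freqs = 0:10), 1)
  pk <- c(1, 1, 1, 1, 1, 3, 1, 1, 1, 1, 1)
  expect_equal(computeSnr(pk, 5, freqs = 0:10), 3)
  degen <- c(0, 0, 0, 2, 0, 0)
  out <- computeSnr(degen, 3, freqs = 0:5)
  expect_true(is.infinite(out))
  expect_true(isTRUE(attr(out, "degenerate")))
  expect_error(computeSnr(pk, 0, freqs = 0:10), "neighboring")
})

test_that("electrode retention uses a strict SNR threshold", {
  tab <- data.frame(session = 1,
                    electrode = rep(c("A", "B", "C"), each = 2),
                    condition = rep(c(10, 20), 3),
                    snr = c(1.6, 1.2, 1.0, 1.0, 1.5, 1.5))
  kept <- selectEegElectrodes(tab, threshold = 1.5)
  expect_identical(kept[["1"]], "A")  # B below, C exactly at threshold
  expect_error(selectEegElectrodes(tab[0, ]), "empty")
})

test_that("raising the SNR threshold never enlarges the retained set", {
  set.seed(4)
  tab <- data.frame(session = 1,
                    electrode = rep(letters[1:8], each = 4),
                    condition = rep(c(5, 10, 20, 40), 8),
                    snr = rexp(32, rate = 0.5))
  prev <- selectEegElectrodes(tab, threshold = 0.1)[["1"]]
  for (thr in c(0.5, 1, 1.5, 2, 4)) {
    cur <- selectEegElectrodes(tab, thr)[["1"]]
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("LFP criteria flag magnitude violations but not lone outliers", {
  set.seed(5)
  nE <- 8; nT <- 6; n <- 1000
  sig <- array(rnorm(nE * nT * n, sd = 10), dim = c(nE, nT, n))
  # 600 uV excursion on 3 electrodes in trial 2
  sig[1:3, 2, 400:500] <- sig[1:3, 2, 400:500] + 600
  lfp <- toyTrialSet(sig, kind = "intracranial",
                     depth = rep(c("shallow", "deep"), 4),
                     condition = rep(0, nT), alignment = 100)
  mask <- flagArtifactTrialsLfp(lfp)
  expect_true(mask$magnitude[2])
  expect_true(mask$flagged[2])
  expect_false(any(mask$magnitude[-2]))

  # single-electrode RMS outlier: z > 4 on exactly one electrode must
  # not trip the two-electrode outlier criterion (30 trials so z > 4
  # is attainable; with a handful of trials the z-score is bounded
  # below the threshold by construction)
  nT2 <- 30
  sig2 <- array(rnorm(nE * nT2 * 200, sd = 10), dim = c(nE, nT2, 200))
  sig2[1, 3, ] <- sig2[1, 3, ] * 30
  lfp2 <- toyTrialSet(sig2, kind = "intracranial",
                      depth = rep(c("shallow", "deep"), 4),
                      condition = rep(0, nT2), alignment = 100)
  mask2 <- flagArtifactTrialsLfp(lfp2, magnitudeUv = 1e6)
  expect_false(any(mask2$flagged))
  # the same outlier on two electrodes does trip criterion (2)
  sig3 <- sig2
  sig3[2, 3, ] <- sig3[2, 3, ] * 30
  lfp3 <- toyTrialSet(sig3, kind = "intracranial",
                      depth = rep(c("shallow", "deep"), 4),
                      condition = rep(0, nT2), alignment = 100)
  mask3 <- flagArtifactTrialsLfp(lfp3, magnitudeUv = 1e6)
  expect_true(mask3$outlier[3])
  expect_false(any(mask3$outlier[-3]))

  quiet <- toyTrialSet(array(rnorm(nE * nT * n, sd = 10),
                             dim = c(nE, nT, n)),
                       kind = "intracranial",
                       depth = rep(c("shallow", "deep"), 4),
                       condition = rep(0, nT), alignment = 100)
  expect_false(any(flagArtifactTrialsLfp(quiet)$flagged))
  expect_error(flagArtifactTrialsLfp(quiet[1:2]), "3 trials")
})

test_that("EEG amplitude-duration rule needs both amplitude and duration", {
  set.seed(6)
  nT <- 6; n <- 3400
  sig <- array(rnorm(2 * nT * n, sd = 8), dim = c(2, nT, n))
  sig[1, 2, 1000:1020] <- 150   # 150 uV for 20 ms -> flagged
  sig[2, 4, 2000:2004] <- 150   # 150 uV for 5 ms -> duration rule spares
  eeg <- toyTrialSet(sig, condition = rep(0, nT))
  mask <- flagArtifactTrialsEeg(eeg)
  expect_true(mask$magnitude[2])
  expect_false(mask$magnitude[4])
  quiet <- toyTrialSet(array(rnorm(2 * nT * n, sd = 8),
                             dim = c(2, nT, n)),
                       condition = rep(0, nT))
  expect_false(any(flagArtifactTrialsEeg(quiet)$flagged))
  # an RMS outlier at a single EEG electrode is enough (criterion 1)
  nT2 <- 30
  sigO <- array(rnorm(2 * nT2 * 200, sd = 8), dim = c(2, nT2, 200))
  sigO[2, 7, ] <- sigO[2, 7, ] * 8  # below 100 uV plateau, big RMS
  eegO <- toyTrialSet(sigO, condition = rep(0, nT2), alignment = 100)
  maskO <- flagArtifactTrialsEeg(eegO, magnitudeUv = 1e6)
  expect_true(maskO$outlier[7])
  expect_false(any(maskO$outlier[-7]))
})

test_that("exclusion set is the union of LFP and EEG masks", {
  lfpMask <- data.frame(trial = 1:4,
                        flagged = c(TRUE, FALSE, FALSE, FALSE),
                        sync = FALSE, outlier = FALSE,
                        magnitude = c(TRUE, FALSE, FALSE, FALSE))
  eegMask <- data.frame(trial = 1:4,
                        flagged = c(FALSE, FALSE, TRUE, FALSE),
                        outlier = FALSE,
                        magnitude = c(FALSE, FALSE, TRUE, FALSE))
  comb <- combineArtifactMasks(lfpMask, eegMask)
  expect_identical(comb$excluded, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("injected artifacts are recovered by the QC rules", {
  cfg <- simulationConfig(nEegElectrodes = 2, nIntracranialElectrodes = 4,
                          trialsPerCondition = 4, conditions = c(0, 10),
                          artifactRate = 0.25, seed = 9)
  ds <- generateDataset(cfg)
  sess <- ds$sessions[[1]]
  injected <- ds$truth@artifactTrials[[1]]
  expect_length(injected, 2)
  eegMask <- flagArtifactTrialsEeg(sess$eeg)
  lfpMask <- flagArtifactTrialsLfp(deriveLfp(sess$wideband))
  comb <- combineArtifactMasks(lfpMask, eegMask)
  expect_true(all(comb$excluded[injected]))
})
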