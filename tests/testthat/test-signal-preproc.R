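t5 <- seq(0, 4.999, by = 1e-3)  # 5 s at 1 kHz
central <- 1000:4000

test_that("band filters pass in-band tones at unit gain with zero lag", {
  bands <- defaultBands()
  for (k in seq_len(nrow(bands))) {
    fc <- mean(c(bands$f_low[k], bands$f_high[k]))
    x <- sin(2 * pi * fc * t5)
    y <- filterBand(x, 1000, bands[k, ])
    gain <- sd(y[central]) / sd(x[central])
    expect_gt(gain, 0.9)
    expect_lt(gain, 1.1)
    # zero-phase: cross-correlation peak at lag 0 (+/- 1 sample)
    cc <- stats::ccf(y[central], x[central], lag.max = 20, plot = FALSE)
    expect_lte(abs(cc$lag[which.max(cc$acf)]), 1)
  }
})

test_that("band filters attenuate out-of-band tones by over 20 dB", {
  x <- sin(2 * pi * 40 * t5)
  y <- filterBand(x, 1000, c(8, 15))
  expect_lt(sd(y[central]) / sd(x[central]), 10^(-20 / 20))
})

test_that("filtering is linear and maps zero to zero", {
  expect_equal(filterBand(rep(0, 5000), 1000, c(8, 15)), rep(0, 5000))
  set.seed(1)
  x <- rnorm(5000); y <- rnorm(5000)
  lhs <- filterBand(2 * x + 3 * y, 1000, c(8, 15))
  rhs <- 2 * filterBand(x, 1000, c(8, 15)) +
    3 * filterBand(y, 1000, c(8, 15))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("short series are rejected for bidirectional filtering", {
  expect_error(filterBand(rnorm(2000), 1000, c(8, 15)), "too short")
})

test_that("line-noise removal notches harmonics and spares the passband", {
  for (f0 in c(60, 120, 180)) {
    x <- sin(2 * pi * f0 * t5)
    y <- removeLineNoise(x, 1000)
    expect_lt(sd(y[central]) / sd(x[central]), 0.1)
  }
  x10 <- sin(2 * pi * 10 * t5)
  y10 <- removeLineNoise(x10, 1000)
  expect_lt(abs(sd(y10[central]) / sd(x10[central]) - 1), 0.1)
  expect_equal(removeLineNoise(rep(0, 5000), 1000), rep(0, 5000))
  expect_error(removeLineNoise(rnorm(5000), 1000, harmonics = 600),
               "Nyquist")
})

test_that("MUAe extraction is nonnegative and tracks envelope structure", {
  expect_equal(extractMuae(rep(0, 60000), 30000, 1000), rep(0, 2000))
  set.seed(2)
  env <- extractMuae(rnorm(60000, sd = 20), 30000, 1000)
  expect_true(all(env >= 0))
  # stationary 2 kHz tone: near-constant envelope in the central window
  tw <- seq(0, 2 - 1 / 30000, by = 1 / 30000)
  env2 <- extractMuae(sin(2 * pi * 2000 * tw), 30000, 1000)
  mid <- env2[500:1500]
  expect_lt(sd(mid) / mean(mid), 0.2)
  expect_error(extractMuae(rnorm(1e4), fsIn = 8000), "too low")
  expect_error(extractMuae(rnorm(6e4), fsIn = 30000, fsOut = 7000),
               "divide")
})

test_that("trial segmentation aligns and bounds-checks onsets", {
  x <- seq_len(10000) * 0 + 5  # constant recording
  ts <- segmentTrials(x, fs = 1000, onsetsMs = c(1000, 4000, 6000),
                      condition = c(0, 10, 20))
  expect_identical(dim(trialSignal(ts)), c(1L, 3L, 3400L))
  expect_identical(stimulusOnset(ts), 800)
  expect_true(all(trialSignal(ts) == 5))
  expect_error(
    segmentTrials(x, 1000, onsetsMs = c(100), condition = 0),
    "100")
})

test_that("the seven band powers do not exceed the full-band power", {
  set.seed(3)
  x <- rnorm(8000)
  full <- filterBand(x, 1000, c(1, 250))
  bands <- defaultBands()
  bandPow <- sum(vapply(seq_len(nrow(bands)), function(k)
    mean(filterBand(x, 1000, bands[k, ])[2000:6000]^2), numeric(1)))
  expect_lte(bandPow, mean(full[2000:6000]^2))
})
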