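test_that("analytic features recover amplitude and phase of tones", {
  t <- seq(0, 2.999, by = 1e-3)
  x <- 3 * sin(2 * pi * 10 * t)
  f <- analyticFeatures(x, 1000)
  expect_false(f$degenerate)
  expect_lt(abs(mean(f$amplitude[500:2500]) - 3) / 3, 0.05)
  # unwrapped phase advances at 2*pi*f per second
  dphi <- diff(f$phase[500:2500])
  dphi <- (dphi + pi) %% (2 * pi) - pi
  slope <- mean(dphi) * 1000
  expect_lt(abs(slope - 2 * pi * 10) / (2 * pi * 10), 0.01)

  z <- analyticFeatures(rep(0, 3000), 1000)
  expect_true(z$degenerate)
  expect_true(all(z$amplitude == 0) && all(z$phase == 0))
})

test_that("windowed features crop after the full-trial transform", {
  t <- seq(0, 3.399, by = 1e-3)
  x <- 2 * sin(2 * pi * 10 * t)
  f <- analyticFeatures(x, 1000, windowMs = c(400, 1800),
                        alignmentMs = 800)
  expect_length(f$amplitude, 1400)
  expect_lt(abs(mean(f$amplitude) - 2) / 2, 0.05)
})

test_that("Pearson correlation obeys its contracts", {
  set.seed(7)
  x <- rnorm(100); y <- rnorm(100)
  expect_equal(correlateSeries(x, x), 1)
  expect_equal(correlateSeries(x, -x), -1)
  expect_equal(correlateSeries(x, y), correlateSeries(y, x))
  expect_error(correlateSeries(x, y[1:50]), "equal length")
  expect_error(correlateSeries(rep(1, 100), y), "zero variance")
  # independent noise at n = 1400: |r| below the ~2/sqrt(n) bound
  rs <- vapply(1:40, function(s) {
    set.seed(s)
    correlateSeries(rnorm(1400), rnorm(1400))
  }, numeric(1))
  expect_gte(mean(abs(rs) < 0.06), 0.9)
})

test_that("Modulation Index hits its analytic anchors", {
  set.seed(8)
  ph <- runif(1e4, -pi, pi)
  expect_equal(modulationIndex(ph, rep(2, 1e4)), 0)
  oneBin <- as.numeric(ph > 0 & ph <= pi / 9)
  expect_equal(modulationIndex(ph, oneBin), 1)
  expect_error(modulationIndex(ph, rep(0, 1e4)), "identically zero")
  expect_error(modulationIndex(ph, ph), "nonnegative")
})

test_that("MI matches an independent brute-force binned KL oracle", {
  set.seed(9)
  ph <- runif(1e4, -pi, pi)
  amp <- exp(2 * cos(ph)) + abs(rnorm(1e4, sd = 0.1))
  expect_equal(modulationIndex(ph, amp), bruteForceMI(ph, amp),
               tolerance = 1e-7)
})

test_that("MI is scale-invariant, bounded, and monotone in coupling", {
  set.seed(10)
  for (i in 1:5) {
    ph <- runif(2000, -pi, pi)
    amp <- abs(rnorm(2000)) + 0.1
    mi <- modulationIndex(ph, amp)
    expect_gte(mi, 0); expect_lte(mi, 1)
    expect_equal(modulationIndex(ph, 7.3 * amp), mi)
  }
  kappas <- c(0, 0.5, 1, 2, 4)
  mis <- vapply(kappas, function(k) {
    mean(vapply(1:5, function(s) {
      set.seed(100 * s)
      ph <- runif(1e4, -pi, pi)
      modulationIndex(ph, exp(k * cos(ph)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mis) >= 0))
})

test_that("circular-shift null separates coupled from uncoupled pairs", {
  set.seed(11)
  ph <- runif(5000, -pi, pi)
  coupled <- miShuffleNull(ph, exp(1.5 * cos(ph)), nIter = 200, seed = 1)
  expect_gt(coupled@percentile, 95)
  expect_length(coupled@null, 200)
  expect_error(miShuffleNull(ph, exp(cos(ph)), nIter = 0), "nIter")
})

test_that("PAC grid localizes configured coupling and handles constants", {
  fe <- smallFeatures10()
  grid <- pacGrid(fe)
  expect_identical(dim(grid), c(7L, 7L))
  # generator couples delta phase -> gamma amplitude
  offDiag <- grid[, "gamma"]
  expect_identical(names(which.max(offDiag)), "delta")
  # constant amplitudes: zero MI everywhere
  fe0 <- fe
  fe0@amplitude <- matrix(1, nrow(fe@amplitude), 7,
                          dimnames = dimnames(fe@amplitude))
  expect_true(all(pacGrid(fe0) == 0))
  # MUAe-amplitude variant: one MI per phase band
  v <- pacGrid(fe, amplitude = abs(rnorm(nrow(fe@amplitude))) + 1)
  expect_length(v, 7)
})

test_that("trial averaging is a pointwise mean with 1/n variance", {
  sig <- array(0, dim = c(1, 2, 100))
  sig[1, 1, ] <- sin(seq_len(100))
  sig[1, 2, ] <- -sin(seq_len(100))
  ts <- toyTrialSet(sig, condition = c(10, 10), alignment = 10)
  expect_equal(as.vector(trialAverage(ts, 10)), rep(0, 100))
  set.seed(12)
  n <- 20
  sigN <- array(rnorm(n * 2000), dim = c(1, n, 2000))
  tsN <- toyTrialSet(sigN, condition = rep(10, n), alignment = 10)
  avg <- trialAverage(tsN, 10)
  expect_lt(abs(var(as.vector(avg)) - 1 / n) / (1 / n), 0.25)
  expect_error(trialAverage(tsN, 40), "no trials")
})
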