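test_that("generation is deterministic and validated", {
  cfg <- simConfig(nChannels = 4, trialsPerEmotion = 2, trialLenS = 4,
                   kappa = 2, shift = 2, seed = 12)
  s1 <- simulateStore(cfg)
  s2 <- simulateStore(cfg)
  expect_identical(s1$store@data, s2$store@data)
  expect_identical(s1$truth$subjects, s2$truth$subjects)
  # per-subject streams: subject 2 alone equals subject 2 of a pair
  cfg2 <- simConfig(nSubjects = 2, nChannels = 4, trialsPerEmotion = 1,
                    trialLenS = 4, kappa = 2, shift = 2, seed = 12)
  pair <- simulateStore(cfg2)
  expect_identical(pair$truth$subjects$s01$epochFrame,
                   s1$truth$subjects$s01$epochFrame)
  expect_error(simConfig(effectSize = 0), "positive")
  expect_error(simConfig(relevantFraction = 0), "relevantFraction")
  expect_error(simConfig(fs = 80), "twice the highest")
})

test_that("the planted frame carries the planted energy boost", {
  sim <- makeSimSmall(seed = 13, nChannels = 6, trialsPerEmotion = 2,
                      effectSize = 2, snr = 5)
  st <- sim$store
  gt <- sim$truth$subjects$s01
  plan <- decomposeFrames(8, 2, 2, sampleRate(st))
  lab <- trialLabels(st)
  id <- lab$trial_id[lab$emotion == "excited"][1]
  x <- trialData(st, id)
  ch <- match(gt$relevant$excited$alpha, montage(st)$label)
  eByFrame <- vapply(seq_len(plan$n), function(k) {
    fr <- x[ch, ztwbes:::.frameSamples(plan, k), drop = FALSE]
    mean(bandEnergy(dftSpectrum(fr, sampleRate(st)), defaultBands("alpha")))
  }, numeric(1))
  expect_equal(which.max(eByFrame), gt$epochFrame)
  expect_gt(eByFrame[gt$epochFrame], 1.5 * max(eByFrame[-gt$epochFrame]))
})

test_that("effectSize 1 plants nothing", {
  simNull <- makeSimSmall(seed = 14, nChannels = 6, trialsPerEmotion = 2,
                          effectSize = 1)
  st <- simNull$store
  lab <- trialLabels(st)
  idN <- lab$trial_id[lab$emotion == "neutral"][1]
  idE <- lab$trial_id[lab$emotion == "happy"][1]
  eN <- multibandEnergy(dftSpectrum(trialData(st, idN), sampleRate(st)))
  eE <- multibandEnergy(dftSpectrum(trialData(st, idE), sampleRate(st)))
  expect_lt(abs(mean(eE) / mean(eN) - 1), 0.1)
})

test_that("generated spectra concentrate energy inside the rhythm bands", {
  sim <- makeSimSmall(seed = 15, nChannels = 4, trialsPerEmotion = 1,
                      snr = 3)
  st <- sim$store
  x <- trialData(st, 1)
  spec <- dftSpectrum(x, sampleRate(st))
  n <- spec$n
  half <- 2:(floor(n / 2) + 1)  # positive-frequency bins
  freqs <- (half - 1) * sampleRate(st) / n
  inband <- freqs >= 4 & freqs <= 42
  pw <- spec$values[, half]^2  # spectral power per bin
  frac <- sum(pw[, inband]) / sum(pw)
  expect_gte(frac, 0.9)
})

test_that("truthReport scores perfect and degenerate recoveries", {
  sim <- makeSimSmall(seed = 16, nChannels = 8, trialsPerEmotion = 3,
                      relevantFraction = 0.5)
  es <- runZtwbes(sim$store, "s01", kappa = 2, shift = 2)
  rel <- selectRelevant(sim$store, "s01", es)
  tr <- truthReport(sim$truth, "s01", epoch = es, relmap = rel)
  expect_true(is.logical(tr$epochHit))
  expect_true(all(tr$perSet$precision >= 0 | is.nan(tr$perSet$precision)))
  # empty Gamma everywhere: recall 0, precision NaN-with-flag
  relEmpty <- suppressWarnings(
    selectRelevant(sim$store, "s01", es, beta = 1e9))
  tre <- truthReport(sim$truth, "s01", relmap = relEmpty)
  expect_equal(tre$macroRecall, 0)
  expect_equal(tre$nUndefinedPrecision, nrow(tre$perSet))
  expect_error(truthReport(sim$truth, "s99"), "unknown subject")
})

test_that("random electrode guesses score precision near the base rate", {
  frac <- 0.5
  sim <- makeSimSmall(seed = 17, nChannels = 16, trialsPerEmotion = 2,
                      relevantFraction = frac)
  labels <- montage(sim$store)$label
  gt <- sim$truth$subjects$s01$relevant
  set.seed(18)
  precs <- replicate(200, {
    planted <- gt$happy$alpha
    guess <- sample(labels, length(planted))
    length(intersect(guess, planted)) / length(guess)
  })
  expect_lt(abs(mean(precs) - frac), 0.05)
})

test_that("epoch recovery is monotone non-decreasing in effect size", {
  effects <- c(1, 1.5, 2, 3)
  nSub <- 20L
  rates <- vapply(effects, function(ef) {
    hits <- vapply(seq_len(nSub), function(i) {
      sim <- simulateStore(simConfig(
        nChannels = 12, trialsPerEmotion = 3, trialLenS = 16, kappa = 4,
        shift = 4, effectSize = ef, relevantFraction = 0.6, snr = 3,
        seed = 500L + i))
      es <- suppressWarnings(runZtwbes(sim$store, "s01", kappa = 4,
                                       shift = 4))
      winnerLocation(es) == sim$truth$subjects$s01$epochFrame
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_lt(rates[1], 0.75)   # no effect: near chance over 4 frames
  expect_gte(rates[4], 0.95)  # strong effect: near-certain recovery
})
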