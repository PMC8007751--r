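test_that("deltaChange keeps the sign and rejects bad baselines", {
  expect_equal(deltaChange(1, 1), 0)
  expect_equal(deltaChange(3, 1), 2)
  expect_equal(deltaChange(0.25, 1), -0.75)
  expect_error(deltaChange(1, 0), "degenerate baseline")
  expect_error(deltaChange(1, -2), "degenerate baseline")
})

test_that("relevanceProbability is the exact ratio with guards", {
  expect_equal(relevanceProbability(3, 4), 0.75)
  expect_equal(relevanceProbability(0, 7), 0)
  expect_equal(relevanceProbability(7, 7), 1)
  expect_error(relevanceProbability(1, 0), ">= 1")
  expect_error(relevanceProbability(5, 4), "within")
})

test_that("significantTrials applies |delta| >= beta inclusively", {
  sim <- makeSimSmall(seed = 51, nChannels = 4, trialsPerEmotion = 3)
  st <- sim$store
  es <- suppressWarnings(runZtwbes(st, "s01", kappa = 2, shift = 2))
  plan <- decomposeFrames(8, 2, 2, sampleRate(st))
  refs <- bandReference(st, "s01", plan = plan,
                        epochIndex = winnerLocation(es))
  e <- montage(st)$label[1]
  # beta = 0 keeps every trial of the emotion
  all0 <- significantTrials(st, "s01", "happy", "alpha", e, refs, beta = 0,
                            plan = plan, epochIndex = winnerLocation(es))
  expect_setequal(all0, trialIds(queryTrials(st, "s01", "happy")))
  # raising beta never adds trials
  b1 <- significantTrials(st, "s01", "happy", "alpha", e, refs, beta = 0.5,
                          plan = plan, epochIndex = winnerLocation(es))
  b2 <- significantTrials(st, "s01", "happy", "alpha", e, refs, beta = 2,
                          plan = plan, epochIndex = winnerLocation(es))
  expect_true(all(b2 %in% b1))
  expect_true(all(b1 %in% all0))
})

test_that("bandReference averages neutral trials per electrode and band", {
  sim <- makeSimSmall(seed = 52, nChannels = 3, trialsPerEmotion = 2)
  st <- sim$store
  refs <- bandReference(st, "s01", segment = "trial")
  lab <- trialLabels(st)
  nids <- lab$trial_id[lab$emotion == "neutral"]
  E <- ztwbes:::.bandTrialEnergies(st, nids)
  expect_equal(refs$energy, apply(E, c(2, 3), mean))
  expect_equal(refs$nTrials, length(nids))
  expect_error(bandReference(st, "s01", segment = "epoch"),
               "needs a frame plan")
})

test_that("selectRelevant recovers planted electrode sets", {
  sim <- makeSimSmall(seed = 53, nChannels = 10, trialsPerEmotion = 4,
                      relevantFraction = 0.5)
  es <- runZtwbes(sim$store, "s01", kappa = 2, shift = 2)
  rel <- selectRelevant(sim$store, "s01", es)
  expect_s4_class(rel, "RelevanceMap")
  tr <- truthReport(sim$truth, "s01", epoch = es, relmap = rel)
  expect_gte(tr$macroPrecision, 0.9)
  expect_gte(tr$macroRecall, 0.9)
  # relevant sets live inside the elite, neutral is excluded
  expect_false("neutral" %in% names(rel@relevant))
  for (em in names(rel@relevant)) {
    for (b in names(rel@relevant[[em]])) {
      expect_true(all(rel@relevant[[em]][[b]] %in% eliteElectrodes(es)))
    }
  }
})

test_that("Gamma is antitone in both thresholds", {
  sim <- makeSimSmall(seed = 54, nChannels = 8, trialsPerEmotion = 3)
  es <- suppressWarnings(runZtwbes(sim$store, "s01", kappa = 2, shift = 2))
  sizes <- function(rel) {
    sum(vapply(rel@relevant, function(r) sum(lengths(r)), numeric(1)))
  }
  byAlpha <- vapply(c(0.2, 0.5, 0.8), function(a) {
    sizes(selectRelevant(sim$store, "s01", es, alpha = a))
  }, numeric(1))
  expect_true(all(diff(byAlpha) <= 0))
  byBeta <- vapply(c(0.1, 0.5, 1.5), function(b) {
    sizes(selectRelevant(sim$store, "s01", es, beta = b))
  }, numeric(1))
  expect_true(all(diff(byBeta) <= 0))
})

test_that("beta = 0 makes rho identically 1 and Gamma the elite set", {
  sim <- makeSimSmall(seed = 55, nChannels = 6, trialsPerEmotion = 2)
  es <- suppressWarnings(runZtwbes(sim$store, "s01", kappa = 2, shift = 2))
  rel <- selectRelevant(sim$store, "s01", es, beta = 0)
  expect_true(all(relevanceRho(rel) == 1))
  for (em in names(rel@relevant)) {
    for (b in names(rel@relevant[[em]])) {
      expect_setequal(rel@relevant[[em]][[b]], eliteElectrodes(es))
    }
  }
})

test_that("rho is invariant under duplicating every trial", {
  sim <- makeSimSmall(seed = 56, nChannels = 4, trialsPerEmotion = 2)
  st <- sim$store
  es <- suppressWarnings(runZtwbes(st, "s01", kappa = 2, shift = 2))
  rel1 <- selectRelevant(st, "s01", es)
  lab <- trialLabels(st)
  lab2 <- lab
  lab2$trial_id <- paste0(lab$trial_id, "_dup")
  data2 <- st@data
  names(data2) <- lab2$trial_id
  stDup <- TrialStore(c(st@data, data2), rbind(lab, lab2),
                      montage = montage(st), fs = sampleRate(st))
  rel2 <- selectRelevant(stDup, "s01", eliteElectrodes(es),
                         plan = decomposeFrames(8, 2, 2, sampleRate(st)),
                         epochIndex = winnerLocation(es))
  expect_equal(relevanceRho(rel2), relevanceRho(rel1))
})

test_that("relevant maps differ across subjects with different truths", {
  sim <- simulateStore(simConfig(nSubjects = 2, nChannels = 10,
                                 trialsPerEmotion = 3, trialLenS = 8,
                                 kappa = 2, shift = 2,
                                 relevantFraction = 0.4, seed = 57))
  rels <- lapply(c("s01", "s02"), function(s) {
    es <- suppressWarnings(runZtwbes(sim$store, s, kappa = 2, shift = 2))
    selectRelevant(sim$store, s, es)
  })
  g1 <- relevantElectrodes(rels[[1]], "happy", "alpha")
  g2 <- relevantElectrodes(rels[[2]], "happy", "alpha")
  expect_false(identical(sort(g1), sort(g2)))
})

test_that("an empty elite set yields empty Gamma with a warning", {
  sim <- makeSimSmall(seed = 58, nChannels = 4, trialsPerEmotion = 2)
  expect_warning(
    rel <- selectRelevant(sim$store, "s01", character(0), segment = "trial"),
    "empty elite")
  expect_true(all(lengths(unlist(rel@relevant, recursive = FALSE)) == 0))
})

test_that("windowed epoch energies degrade relevance precision", {
  sim <- makeSimSmall(seed = 59, nChannels = 10, trialsPerEmotion = 4,
                      relevantFraction = 0.5)
  es <- runZtwbes(sim$store, "s01", kappa = 2, shift = 2)
  plain <- selectRelevant(sim$store, "s01", es)
  windowed <- selectRelevant(sim$store, "s01", es, ztw = TRUE)
  trP <- truthReport(sim$truth, "s01", relmap = plain)
  trW <- truthReport(sim$truth, "s01", relmap = windowed)
  expect_gt(trP$macroPrecision, trW$macroPrecision)
  expect_gte(trP$macroPrecision, 0.9)
})
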