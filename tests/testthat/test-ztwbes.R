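test_that("decomposeFrames reproduces the printed frame arithmetic", {
  p <- decomposeFrames(8, kappa = 6, shift = 2, fs = 128)
  expect_equal(p$n, 2L)
  expect_equal(p$start_s, c(0, 2))
  expect_equal(p$end_s, c(6, 8))
  p2 <- decomposeFrames(60, kappa = 15, shift = 15, fs = 128)
  expect_equal(p2$n, 4L)
  # shift = kappa partitions the covered span: no overlap, no gap
  s <- unlist(lapply(seq_len(p2$n), function(k) ztwbes:::.frameSamples(p2, k)))
  expect_equal(s, seq_len(60 * 128))
  # kappa = trial length -> a single frame covering the trial
  p3 <- decomposeFrames(10, kappa = 10, shift = 3, fs = 100)
  expect_equal(p3$n, 1L)
  expect_equal(ztwbes:::.frameSamples(p3, 1), 1:1000)
  expect_error(decomposeFrames(5, kappa = 6, shift = 1, fs = 128),
               "exceeds")
  expect_error(decomposeFrames(8, kappa = 2, shift = 0, fs = 128),
               "positive")
})

test_that("neutralReference averages multiband NGD energy over trials", {
  sim <- makeSimSmall(seed = 41, nChannels = 2, trialsPerEmotion = 2)
  st <- sim$store
  ref <- neutralReference(st, "s01")
  lab <- trialLabels(st)
  nids <- lab$trial_id[lab$emotion == "neutral"]
  manual <- rowMeans(vapply(nids, function(id) {
    multibandEnergy(ngdSpectrum(trialData(st, id), sampleRate(st)),
                    bands(st))
  }, numeric(2)))
  expect_equal(unname(ref$energy), unname(manual))
  expect_true(all(ref$energy >= 0))
  # a subject without neutral trials has no baseline
  st2 <- st[trialIds(st)[trialLabels(st)$emotion != "neutral"]]
  expect_error(neutralReference(st2, "s01"), "missing baseline")
})

test_that("frameVariation is the absolute relative deviation", {
  set.seed(42)
  fr <- rnorm(128)
  w <- ztwWindow(128)
  e <- multibandEnergy(ngdSpectrum(applyZtw(fr, w), 128))
  expect_equal(frameVariation(fr, e, fs = 128), 0)
  expect_equal(frameVariation(fr, e / 2, fs = 128), 1)
  expect_equal(frameVariation(fr, 2 * e, fs = 128), 0.5)
  expect_error(frameVariation(fr, 0, fs = 128), "degenerate baseline")
})

test_that("tagTrial elects the planted frame and breaks ties early", {
  # bit-identical frames -> all variations tie -> earliest frame wins
  fs <- 128
  set.seed(40)
  x <- rep(rnorm(2 * fs), 4)
  p <- decomposeFrames(8, 2, 2, fs)
  expect_equal(unname(tagTrial(x, p, ref = 1, fs = fs)), 1L)
  # planted boost in a simulated subject's epoch frame
  sim <- makeSimSmall(seed = 43, effectSize = 3, snr = 10)
  st <- sim$store
  gt <- sim$truth$subjects$s01
  plan <- decomposeFrames(8, 2, 2, sampleRate(st))
  ref <- neutralReference(st, "s01")
  lab <- trialLabels(st)
  emoIds <- lab$trial_id[lab$emotion != "neutral"]
  tags <- vapply(emoIds, function(id) {
    tagTrial(trialData(st, id), plan, ref, bands(st), sampleRate(st))
  }, integer(nrow(montage(st))))
  # single-trial tags beat chance (1/4) on the modulated electrodes ...
  modulated <- unique(unlist(lapply(gt$relevant, unlist)))
  mi <- match(modulated, montage(st)$label)
  expect_gt(mean(tags[mi, ] == gt$epochFrame), 0.4)
  # ... and the per-electrode plurality over trials settles on the truth
  cand <- apply(tags[mi, , drop = FALSE], 1L, pluralityVote)
  expect_gt(mean(cand == gt$epochFrame), 0.8)
})

test_that("plurality and majority votes follow the printed rules", {
  expect_equal(pluralityVote(c(2, 2, 3)), 2L)
  expect_equal(pluralityVote(c(1, 2)), 1L)
  expect_equal(pluralityVote(3), 3L)
  expect_error(pluralityVote(integer(0)), "no tags")
  v <- setNames(c(rep(2L, 20), rep(3L, 12)), paste0("e", 1:32))
  mv <- majorityVote(v)
  expect_equal(mv$winner, 2L)
  expect_equal(length(mv$elite), 20L)
  expect_equal(mv$margin, 0.625)
  # exactly half is not a majority: plurality fallback with a warning
  v2 <- setNames(c(rep(2L, 16), rep(3L, 16)), paste0("e", 1:32))
  expect_warning(mv2 <- majorityVote(v2), "no strict majority")
  expect_equal(mv2$winner, 2L)
  expect_equal(mv2$margin, 0.5)
  vu <- setNames(rep(4L, 8), paste0("e", 1:8))
  expect_equal(majorityVote(vu)$margin, 1)
})

test_that("runZtwbes recovers planted epochs per subject", {
  sim <- makeSimSmall(seed = 44, nChannels = 10, trialsPerEmotion = 2,
                      relevantFraction = 0.6)
  es <- runZtwbes(sim$store, "s01", kappa = 2, shift = 2)
  expect_s4_class(es, "EpochSelection")
  expect_equal(winnerLocation(es), sim$truth$subjects$s01$epochFrame)
  expect_true(all(eliteElectrodes(es) %in% montage(sim$store)$label))
  expect_true(winnerLocation(es) >= 1 && winnerLocation(es) <= es@plan$n)
  expect_equal(voteMargin(es),
               length(eliteElectrodes(es)) / nrow(montage(sim$store)))
  # different subjects carry different planted epochs and recover them
  sim2 <- simulateStore(simConfig(nSubjects = 3, nChannels = 10,
                                  trialsPerEmotion = 2, trialLenS = 8,
                                  kappa = 2, shift = 2,
                                  relevantFraction = 0.6, seed = 45))
  winners <- vapply(names(sim2$truth$subjects), function(s) {
    winnerLocation(runZtwbes(sim2$store, s, kappa = 2, shift = 2))
  }, integer(1))
  planted <- vapply(sim2$truth$subjects, function(s) s$epochFrame,
                    integer(1))
  expect_equal(unname(winners), unname(planted))
  expect_gt(length(unique(planted)), 1L)
})

test_that("winner location is invariant to electrode order", {
  sim <- makeSimSmall(seed = 46, nChannels = 6, trialsPerEmotion = 2)
  st <- sim$store
  es1 <- suppressWarnings(runZtwbes(st, "s01", kappa = 2, shift = 2))
  perm <- c(4, 1, 6, 3, 2, 5)
  st2 <- st
  st2@montage <- st@montage[perm, ]
  st2@data <- lapply(st@data, function(m) m[perm, , drop = FALSE])
  validObject(st2)
  es2 <- suppressWarnings(runZtwbes(st2, "s01", kappa = 2, shift = 2))
  expect_equal(winnerLocation(es2), winnerLocation(es1))
  expect_setequal(eliteElectrodes(es2), eliteElectrodes(es1))
})

test_that("a single emotional trial degenerates to its own consensus", {
  sim <- makeSimSmall(seed = 47, nChannels = 6, trialsPerEmotion = 1)
  st <- sim$store
  lab <- trialLabels(st)
  keep <- lab$trial_id[lab$emotion %in% c("neutral", "happy")]
  st2 <- st[keep]
  es <- suppressWarnings(runZtwbes(st2, "s01", kappa = 2, shift = 2))
  plan <- decomposeFrames(8, 2, 2, sampleRate(st2))
  ref <- neutralReference(st2, "s01")
  id <- lab$trial_id[lab$emotion == "happy"]
  tags <- tagTrial(trialData(st2, id), plan, ref, bands(st2),
                   sampleRate(st2))
  expect_equal(winnerLocation(es),
               suppressWarnings(majorityVote(
                 setNames(tags, montage(st2)$label)))$winner)
})
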