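# Shared fixtures. Small stores are built per test; the heavy
# recovery study (used by two acceptance checks) is computed once per
# run and cached.

# hand-built miniature store: 2 subjects, known labels, tiny matrices
makeTinyStore <- function(fs = 128, ns = 64) {
  ids <- c("t1", "t2", "t3", "t4", "t5")
  lab <- data.frame(
    trial_id = ids,
    subject = c("s1", "s1", "s2", "s1", "s2"),
    emotion = c("happy", "calm", "happy", "neutral", "neutral"),
    stringsAsFactors = FALSE
  )
  set.seed(99)
  data <- lapply(ids, function(i) matrix(rnorm(2 * ns), 2, ns))
  names(data) <- ids
  TrialStore(data, lab, montage = deapMontage(2), fs = fs)
}

# small simulated subject for pipeline tests (8 s trials, 4 frames)
makeSimSmall <- function(seed = 4, nChannels = 8, trialsPerEmotion = 3,
                         effectSize = 2, relevantFraction = 0.5, snr = 3,
                         ...) {
  simulateStore(simConfig(
    nChannels = nChannels, trialsPerEmotion = trialsPerEmotion,
    trialLenS = 8, kappa = 2, shift = 2, effectSize = effectSize,
    relevantFraction = relevantFraction, snr = snr, seed = seed, ...))
}

# brute-force O(N^2) DFT oracle
bruteDft <- function(x) {
  N <- length(x)
  vapply(0:(N - 1), function(k) {
    sum(x * exp(-2i * pi * k * (0:(N - 1)) / N))
  }, complex(1))
}

# brute-force NGD oracle (term-by-term numerator evaluation)
bruteNgd <- function(x) {
  X <- bruteDft(x)
  Y <- bruteDft((0:(length(x) - 1)) * x)
  Re(X) * Re(Y) + Im(X) * Im(Y)
}

# 50-subject epoch/electrode recovery study at the strong-effect
# regime (multiplicative effect 2.0, SNR 3, 60% of the montage
# modulated); cached so the epoch and electrode checks share one run.
.recoveryCache <- new.env(parent = emptyenv())
recoveryStudy <- function(nSubjects = 50L) {
  key <- as.character(nSubjects)
  if (!is.null(.recoveryCache[[key]])) return(.recoveryCache[[key]])
  res <- vector("list", nSubjects)
  for (i in seq_len(nSubjects)) {
    sim <- simulateStore(simConfig(relevantFraction = 0.6, effectSize = 2,
                                   snr = 3, seed = 20000L + i))
    es <- suppressWarnings(runZtwbes(sim$store, "s01"))
    rel <- selectRelevant(sim$store, "s01", es)
    tr <- truthReport(sim$truth, "s01", epoch = es, relmap = rel)
    res[[i]] <- list(hit = isTRUE(tr$epochHit),
                     precision = tr$macroPrecision,
                     recall = tr$macroRecall,
                     margin = voteMargin(es))
    rm(sim, es, rel, tr)
    gc(verbose = FALSE)
  }
  .recoveryCache[[key]] <- res
  res
}
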