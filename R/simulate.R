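#' Configuration of the synthetic emotional-EEG generator
#'
#' Validated parameter bundle for [simulateStore()]. The defaults
#' mirror the recording setup the pipeline targets: 32 channels at
#' 128 Hz, 60-s trials, 10 trials per emotional state (neutral
#' included), 15-s epoch frames. The planted effect is a
#' multiplicative change of a band's oscillation amplitude
#' (`effectSize`; values below 1 model decreases) restricted to the
#' subject's epoch frame and to the planted relevant channels
#' (`relevantFraction` of the montage per emotion and band -- default
#' 0.25, i.e. a handful of channels out of 32, the sparsity scalp
#' relevance tables typically show). `snr` is the ratio of the
#' oscillation RMS to the noise standard deviation.
#'
#' @param nSubjects number of subjects (default 1).
#' @param nChannels montage size, up to 32 (default 32).
#' @param fs sampling rate in Hz (default 128).
#' @param trialLenS trial length in seconds (default 60).
#' @param trialsPerEmotion trials per emotional state incl. neutral
#'   (default 10).
#' @param kappa,shift epoch-frame length/shift in seconds (default 15/15).
#' @param effectSize multiplicative band-amplitude factor inside the
#'   epoch frame (> 0; default 2; 1 = no effect).
#' @param relevantFraction fraction of channels modulated per
#'   (emotion, band), in (0, 1] (default 0.25).
#' @param snr oscillation-to-noise amplitude ratio (default 3).
#' @param seed RNG seed (default 1).
#' @param noise `"white"` (default) or `"pink"` (1/f).
#' @param modulation `"multiplicative"` (default) or `"additive"` (an
#'   extra independent-phase oscillation of amplitude
#'   `(effectSize - 1) * a_band`).
#' @param amplitudes per-band oscillation amplitudes, one per band of
#'   [defaultBands()]; the default `(1, 0.9, 0.9, 0.7)` gives a mild
#'   high-frequency roll-off while keeping every rhythm detectable.
#' @return A validated `SimConfig` list.
#' @examples
#' simConfig(nSubjects = 2, effectSize = 1.5)
#' @export
simConfig <- function(nSubjects = 1L, nChannels = 32L, fs = 128,
                      trialLenS = 60, trialsPerEmotion = 10L, kappa = 15,
                      shift = 15, effectSize = 2, relevantFraction = 0.25,
                      snr = 3, seed = 1L, noise = c("white", "pink"),
                      modulation = c("multiplicative", "additive"),
                      amplitudes = c(theta = 1, alpha = 0.9, beta = 0.9,
                                     gamma = 0.7)) {
  noise <- match.arg(noise)
  modulation <- match.arg(modulation)
  bandTable <- defaultBands()
  if (effectSize <= 0) stop("effectSize must be positive")
  if (relevantFraction <= 0 || relevantFraction > 1) {
    stop("relevantFraction must be in (0, 1]")
  }
  if (fs <= 2 * max(bandTable$hi)) {
    stop("fs must exceed twice the highest band edge")
  }
  if (snr <= 0) stop("snr must be positive")
  stopifnot(nSubjects >= 1L, nChannels >= 1L, trialsPerEmotion >= 1L,
            trialLenS > 0, kappa > 0, shift > 0, kappa <= trialLenS,
            length(amplitudes) == nrow(bandTable))
  structure(list(
    nSubjects = as.integer(nSubjects), nChannels = as.integer(nChannels),
    fs = fs, trialLenS = trialLenS,
    trialsPerEmotion = as.integer(trialsPerEmotion),
    kappa = kappa, shift = shift, effectSize = effectSize,
    relevantFraction = relevantFraction, snr = snr,
    seed = as.integer(seed), noise = noise, modulation = modulation,
    amplitudes = amplitudes, bands = bandTable
  ), class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf(
    "SimConfig: %d subject(s) x %d emotion(s) x %d trial(s), %d ch @ %g Hz\n",
    x$nSubjects, length(emotionLevels()), x$trialsPerEmotion, x$nChannels,
    x$fs))
  cat(sprintf(
    "  effect %g in %.0f%% of channels, snr %g, %s noise, seed %d\n",
    x$effectSize, 100 * x$relevantFraction, x$snr, x$noise, x$seed))
  invisible(x)
}

.pinkNoise <- function(nch, ns) {
  w <- matrix(stats::rnorm(nch * ns), ns, nch)
  f <- c(1, seq_len(ns - 1L))
  f <- pmin(f, ns - f + 1)  # mirror for negative frequencies
  shaped <- stats::mvfft(w) / sqrt(f)
  y <- Re(stats::mvfft(shaped, inverse = TRUE)) / ns
  y <- sweep(y, 2L, apply(y, 2L, stats::sd), "/")
  t(y)
}

# one subject's trials + ground truth, from the current RNG stream
.simulateSubject <- function(cfg, subjectId) {
  nch <- cfg$nChannels
  ns <- round(cfg$trialLenS * cfg$fs)
  tvec <- (0:(ns - 1L)) / cfg$fs
  bandTable <- cfg$bands
  nb <- nrow(bandTable)
  plan <- decomposeFrames(cfg$trialLenS, cfg$kappa, cfg$shift, cfg$fs)
  mon <- deapMontage(nch)
  emoAll <- emotionLevels()
  emo8 <- emotionLevels(includeNeutral = FALSE)
  kstar <- sample.int(plan$n, 1L)
  nRel <- max(1L, round(cfg$relevantFraction * nch))
  relevant <- lapply(emo8, function(em) {
    r <- lapply(seq_len(nb), function(b) sort(sample.int(nch, nRel)))
    names(r) <- bandTable$name
    lapply(r, function(idx) mon$label[idx])
  })
  names(relevant) <- emo8
  noiseSd <- sqrt(sum(cfg$amplitudes^2) / 2) / cfg$snr
  frameIdx <- .frameSamples(plan, kstar)
  jitter <- (bandTable$hi - bandTable$lo) / 4
  centre <- (bandTable$hi + bandTable$lo) / 2

  trials <- list(); labs <- list(); signs <- list()
  for (em in emoAll) {
    for (r in seq_len(cfg$trialsPerEmotion)) {
      sig <- matrix(0, nch, ns)
      for (b in seq_len(nb)) {
        freqs <- centre[b] + stats::runif(nch, -1, 1) * jitter[b]
        phases <- stats::runif(nch, 0, 2 * pi)
        osc <- cfg$amplitudes[b] *
          sin(outer(freqs, 2 * pi * tvec) + phases)
        if (em != "neutral" && cfg$effectSize != 1) {
          chIdx <- match(relevant[[em]][[bandTable$name[b]]], mon$label)
          if (cfg$modulation == "multiplicative") {
            osc[chIdx, frameIdx] <- osc[chIdx, frameIdx] * cfg$effectSize
          } else {
            extraPh <- stats::runif(length(chIdx), 0, 2 * pi)
            extra <- (cfg$effectSize - 1) * cfg$amplitudes[b] *
              sin(outer(freqs[chIdx], 2 * pi * tvec[frameIdx]) + extraPh)
            osc[chIdx, frameIdx] <- osc[chIdx, frameIdx] + extra
          }
        }
        sig <- sig + osc
      }
      nz <- if (cfg$noise == "white") {
        matrix(stats::rnorm(nch * ns, 0, noiseSd), nch, ns)
      } else {
        noiseSd * .pinkNoise(nch, ns)
      }
      id <- sprintf("%s_%s_%02d", subjectId, em, r)
      trials[[id]] <- sig + nz
      labs[[id]] <- data.frame(trial_id = id, subject = subjectId,
                               emotion = em, stringsAsFactors = FALSE)
      signs[[id]] <- data.frame(
        trial_id = id,
        direction = if (em == "neutral" || cfg$effectSize == 1) "none"
        else if (cfg$effectSize > 1) "increase" else "decrease",
        stringsAsFactors = FALSE)
    }
  }
  list(trials = trials, labels = do.call(rbind, labs),
       truth = list(epochFrame = kstar, relevant = relevant,
                    plan = unclass(plan)),
       signs = do.call(rbind, signs))
}

#' Generate a ground-truthed synthetic emotional-EEG store
#'
#' Every trial is a mixture of one band-limited sinusoid per rhythm
#' band (random phase, frequency jittered around the band centre,
#' fixed per-band amplitude) plus broadband noise at the configured
#' SNR. For emotional trials the amplitude of band f in the planted
#' relevant channels R(subject, emotion, f) is multiplied by
#' `effectSize`, but only inside the samples of the subject's planted
#' epoch frame k*; neutral trials are never modulated. Both the epoch
#' location and the relevant sets are redrawn per subject, emulating
#' the between-subject variability the adaptive pipeline assumes.
#' Generation is fully deterministic given the config seed (subjects
#' are seeded independently, so generating subject 3 alone yields the
#' same trials as generating all subjects together).
#'
#' @param config a [simConfig()].
#' @return List with `store` (a [TrialStore-class]) and `truth` (a
#'   `GroundTruth`: per subject the planted `epochFrame`,
#'   `relevant[[emotion]][[band]]` channel labels and the frame plan,
#'   plus per-trial modulation directions).
#' @examples
#' sim <- simulateStore(simConfig(nChannels = 4, trialLenS = 4,
#'                                trialsPerEmotion = 2, kappa = 2,
#'                                shift = 2))
#' sim$store
#' sim$truth$subjects$s01$epochFrame
#' @export
simulateStore <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  allTrials <- list(); allLabs <- list(); subjectsTruth <- list()
  allSigns <- list()
  for (i in seq_len(config$nSubjects)) {
    sid <- sprintf("s%02d", i)
    set.seed(config$seed + 1013L * i)
    sub <- .simulateSubject(config, sid)
    allTrials <- c(allTrials, sub$trials)
    allLabs[[sid]] <- sub$labels
    allSigns[[sid]] <- sub$signs
    subjectsTruth[[sid]] <- sub$truth
  }
  store <- TrialStore(allTrials, do.call(rbind, allLabs),
                      montage = deapMontage(config$nChannels),
                      bands = config$bands, fs = config$fs)
  truth <- structure(list(subjects = subjectsTruth,
                          trialDirections = do.call(rbind, allSigns),
                          config = config),
                     class = "GroundTruth")
  list(store = store, truth = truth)
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf("GroundTruth: %d subject(s), epoch frame(s): %s\n",
              length(x$subjects),
              paste(vapply(x$subjects, function(s) s$epochFrame,
                           integer(1)), collapse = ", ")))
  invisible(x)
}

#' Score recovery of the planted structure
#'
#' Compares an epoch-selection result and/or a relevance map against
#' the generator's ground truth for the same subject: whether the
#' planted epoch frame was recovered, and the precision/recall of
#' every recovered relevant-electrode set against the planted set.
#' An empty recovered set has undefined precision, reported as `NaN`
#' and counted in `nUndefinedPrecision`.
#'
#' @param truth the `GroundTruth` from [simulateStore()].
#' @param subject subject id.
#' @param epoch optional [EpochSelection-class] for that subject.
#' @param relmap optional [RelevanceMap-class] for that subject.
#' @return List with `epochHit` (logical or `NA`), `perSet`
#'   (data.frame: emotion, band, tp, fp, fn, precision, recall),
#'   `macroPrecision`, `macroRecall`, `nUndefinedPrecision`.
#' @export
truthReport <- function(truth, subject, epoch = NULL, relmap = NULL) {
  stopifnot(inherits(truth, "GroundTruth"))
  if (!subject %in% names(truth$subjects)) {
    stop("unknown subject in ground truth: ", subject)
  }
  gt <- truth$subjects[[subject]]
  epochHit <- NA
  if (!is.null(epoch)) {
    stopifnot(is(epoch, "EpochSelection"))
    if (epoch@subject != subject) stop("subject mismatch with epoch result")
    epochHit <- epoch@winner == gt$epochFrame
  }
  perSet <- NULL
  macroPrecision <- NA_real_; macroRecall <- NA_real_
  nUndef <- 0L
  if (!is.null(relmap)) {
    stopifnot(is(relmap, "RelevanceMap"))
    if (relmap@subject != subject) stop("subject mismatch with relevance map")
    rows <- list()
    for (em in names(gt$relevant)) {
      if (!em %in% names(relmap@relevant)) next
      for (b in names(gt$relevant[[em]])) {
        planted <- gt$relevant[[em]][[b]]
        got <- relmap@relevant[[em]][[b]]
        tp <- length(intersect(got, planted))
        fp <- length(setdiff(got, planted))
        fn <- length(setdiff(planted, got))
        prec <- if (tp + fp == 0L) NaN else tp / (tp + fp)
        rows[[length(rows) + 1L]] <- data.frame(
          emotion = em, band = b, tp = tp, fp = fp, fn = fn,
          precision = prec, recall = tp / (tp + fn),
          stringsAsFactors = FALSE)
      }
    }
    perSet <- do.call(rbind, rows)
    nUndef <- sum(is.nan(perSet$precision))
    macroPrecision <- mean(perSet$precision, na.rm = TRUE)
    macroRecall <- mean(perSet$recall)
  }
  list(epochHit = epochHit, perSet = perSet,
       macroPrecision = macroPrecision, macroRecall = macroRecall,
       nUndefinedPrecision = nUndef)
}
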