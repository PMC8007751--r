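#' Leakage-free cross-validated emotion classification
#'
#' Runs the full per-subject pipeline under stratified k-fold
#' cross-validation. Within every fold, everything derived from data
#' -- the neutral baselines, the ZTWBES epoch location and elite set
#' (proposed variant), the relevance map, the band references and the
#' classifiers -- is recomputed from the training folds only; the
#' held-out trials contribute nothing but their own per-trial
#' energies. Per-trial energies are precomputed once for the store
#' (they involve no cross-trial statistics, so reusing them across
#' folds leaks nothing).
#'
#' Variants:
#' * `"proposed"` -- NGD spectra, ZTWBES epoch selection, relevance
#'   and features on the ZTW-windowed epoch frame of the elite
#'   electrodes;
#' * `"ngd"` / `"dft"` -- no epoch stage: whole-trial NGD or
#'   DFT-magnitude energies over the full montage.
#'
#' @param store a [TrialStore-class].
#' @param subject subject id.
#' @param mode classifier mode: `"qdc"`, `"nn1"` or `"nn2"`.
#' @param variant `"proposed"`, `"ngd"` or `"dft"`.
#' @param k number of folds (default 10). If some emotion has fewer
#'   than `k` trials the run falls back to leave-one-out with a
#'   warning.
#' @param seed RNG seed controlling fold assignment and network
#'   initialization; the same seed reproduces the run exactly.
#' @param alpha,beta relevance thresholds (default 0.5 each).
#' @param kappa,shift ZTWBES frame parameters in seconds (default 15).
#' @param bandlimit band-pass filter each band before its energy.
#' @param ztw apply the zero-time window to the epoch-frame energies
#'   used for relevance and features (default FALSE; the ZTWBES votes
#'   always use it).
#' @param strict use strict `>` threshold comparisons.
#' @param includeNeutralVotes include neutral trials in the ZTWBES
#'   voting pool.
#' @param shrink,nnIter classifier options, see [trainEnsemble()].
#' @param mode.energy spectrum-value mode (`"magnitude"`/`"real"`).
#' @return A `CvResult`: list with `finalAccuracy` (fraction of test
#'   trials whose fused label matches the truth; rejects count as
#'   errors), `finalAccuracyExclReject`, `perEmotionAccuracy` (binary
#'   one-vs-all test accuracies; `NA` for `"nn2"`), `confusion` (true
#'   x predicted counts, including `"reject"`), `epochByFold`,
#'   `folds`, `k`, `seed`, and the call parameters.
#' @examples
#' \donttest{
#' sim <- simulateStore(simConfig(nChannels = 8, trialsPerEmotion = 3,
#'                                trialLenS = 8, kappa = 2, shift = 2,
#'                                relevantFraction = 0.5, seed = 4))
#' cv <- crossvalidate(sim$store, "s01", k = 3, kappa = 2, shift = 2)
#' cv$finalAccuracy
#' }
#' @export
crossvalidate <- function(store, subject, mode = c("qdc", "nn1", "nn2"),
                          variant = c("proposed", "ngd", "dft"), k = 10L,
                          seed = 1L, alpha = 0.5, beta = 0.5, kappa = 15,
                          shift = 15, bandlimit = TRUE, ztw = FALSE,
                          strict = FALSE,
                          includeNeutralVotes = FALSE, shrink = NULL,
                          nnIter = 5L, mode.energy = c("magnitude", "real")) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  mode.energy <- match.arg(mode.energy)
  stopifnot(is(store, "TrialStore"))
  lab <- trialLabels(store)
  if (!subject %in% lab$subject) stop("unknown subject: ", subject)
  del <- lab[lab$subject == subject & !is.na(lab$emotion), , drop = FALSE]
  ids <- del$trial_id
  yAll <- stats::setNames(del$emotion, del$trial_id)
  counts <- table(yAll)
  if (!"neutral" %in% names(counts)) {
    stop("missing baseline: subject '", subject, "' has no neutral trials")
  }
  if (min(counts) < k) {
    warning(sprintf(
      "emotion '%s' has %d < k = %d trials; falling back to leave-one-out",
      names(counts)[which.min(counts)], min(counts), k))
    k <- length(ids)
  }
  set.seed(seed)
  fs <- sampleRate(store)
  trialLenS <- ncol(trialData(store, ids[1L])) / fs
  plan <- decomposeFrames(trialLenS, kappa, shift, fs)
  bandTable <- bands(store)
  mon <- montage(store)$label
  transform <- if (variant == "dft") "dft" else "ngd"

  # --- per-trial energy caches (no cross-trial information) ---
  if (variant == "proposed") {
    zt <- .ztwbesEnergies(store, ids, plan, bandTable, mode.energy)
    Eframe <- .bandFrameEnergies(store, ids, plan, bandTable, "ngd",
                                 bandlimit, mode.energy, ztw)
  } else {
    Etrial <- .bandTrialEnergies(store, ids, bandTable, transform,
                                 bandlimit, mode.energy)
  }

  # --- stratified fold assignment (leave-one-out when k = #trials) ---
  fold <- stats::setNames(integer(length(ids)), ids)
  if (k == length(ids)) {
    fold[ids] <- seq_along(ids)
  } else {
    for (em in names(counts)) {
      emIds <- sample(ids[yAll[ids] == em])
      fold[emIds] <- rep_len(seq_len(k), length(emIds))
    }
  }

  emoAll <- emotionLevels()
  predLevels <- c(emoAll, "reject")
  confusion <- matrix(0L, length(emoAll), length(predLevels),
                      dimnames = list(true = emoAll, predicted = predLevels))
  voteHits <- stats::setNames(numeric(8), emotionLevels(FALSE))
  voteTot <- voteHits
  epochByFold <- integer(k)

  for (f in seq_len(k)) {
    train <- ids[fold[ids] != f]
    test <- ids[fold[ids] == f]
    if (!length(test)) next
    yTrain <- yAll[train]
    neutralTrain <- train[yTrain == "neutral"]
    if (!length(neutralTrain)) {
      warning("fold ", f, " has no neutral training trials; skipping fold")
      next
    }

    if (variant == "proposed") {
      refMB <- colMeans(zt$full[neutralTrain, , drop = FALSE])
      votePool <- if (includeNeutralVotes) train else
        train[yTrain != "neutral"]
      vr <- abs(sweep(zt$frame[votePool, , , drop = FALSE], 2L, refMB,
                      function(e, r) (e - r) / r))
      tags <- apply(vr, c(1L, 2L), which.max)
      cand <- apply(tags, 2L, pluralityVote)
      mv <- suppressWarnings(majorityVote(stats::setNames(cand, mon)))
      epoch <- mv$winner
      elite <- mv$elite
      E <- Eframe[, , , epoch, drop = FALSE]
      dim(E) <- dim(Eframe)[1:3]
      dimnames(E) <- dimnames(Eframe)[1:3]
    } else {
      epoch <- NA_integer_
      elite <- mon
      E <- Etrial
    }
    epochByFold[f] <- epoch

    refMat <- apply(E[neutralTrain, , , drop = FALSE], c(2L, 3L), mean)
    if (any(refMat <= 0)) {
      stop("degenerate baseline: zero reference energy in fold ", f)
    }
    emoTrain <- setdiff(intersect(emoAll, unique(yTrain)), "neutral")
    phi <- lapply(emoTrain, function(em) train[yTrain == em])
    names(phi) <- emoTrain
    core <- .relevanceCore(E, refMat, phi, elite, alpha, beta, strict)
    relmap <- new("RelevanceMap", subject = subject, alpha = alpha,
                  beta = beta, rho = core$rho, counts = core$counts,
                  phiSizes = vapply(phi, length, integer(1)),
                  relevant = core$relevant, elite = elite)

    specNames <- if (mode == "nn2") "all" else emotionLevels(FALSE)
    specs <- lapply(specNames, function(em) featureSpec(relmap, em))
    names(specs) <- specNames
    featTrain <- lapply(specs, function(sp) .featureMatrix(E, train, sp,
                                                           refMat))
    featTest <- lapply(specs, function(sp) .featureMatrix(E, test, sp,
                                                          refMat))
    ens <- trainEnsemble(featTrain, yTrain, specs, mode = mode,
                         shrink = shrink, nnIter = nnIter)
    pred <- predictEnsemble(ens, featTest)

    yTest <- yAll[test]
    for (i in seq_along(test)) {
      confusion[yTest[i], pred$label[i]] <- confusion[yTest[i],
                                                      pred$label[i]] + 1L
    }
    if (!is.null(pred$votes)) {
      for (em in colnames(pred$votes)) {
        voteHits[em] <- voteHits[em] +
          sum(pred$votes[, em] == (yTest == em))
        voteTot[em] <- voteTot[em] + length(test)
      }
    }
  }

  nTest <- sum(confusion)
  hits <- sum(diag(confusion[, emoAll]))
  rejects <- sum(confusion[, "reject"])
  perEmotion <- ifelse(voteTot > 0, voteHits / voteTot, NA_real_)
  structure(list(
    subject = subject, mode = mode, variant = variant, k = k, seed = seed,
    alpha = alpha, beta = beta, kappa = kappa, shift = shift,
    finalAccuracy = hits / nTest,
    finalAccuracyExclReject = if (nTest > rejects)
      hits / (nTest - rejects) else NA_real_,
    rejectRate = rejects / nTest,
    perEmotionAccuracy = perEmotion,
    confusion = confusion,
    epochByFold = epochByFold,
    folds = fold
  ), class = "CvResult")
}

#' @export
print.CvResult <- function(x, ...) {
  cat(sprintf(
    "CvResult: subject %s, %s/%s, %d-fold (seed %d)\n",
    x$subject, x$variant, x$mode, x$k, x$seed))
  cat(sprintf(
    "  final-decision accuracy %.3f (excl. reject %.3f, reject rate %.3f)\n",
    x$finalAccuracy, x$finalAccuracyExclReject, x$rejectRate))
  if (!all(is.na(x$perEmotionAccuracy))) {
    cat(sprintf("  one-vs-all mean accuracy %.3f\n",
                mean(x$perEmotionAccuracy, na.rm = TRUE)))
  }
  invisible(x)
}
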