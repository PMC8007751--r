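#' Per-band reference energies from the neutral state
#'
#' Mean band energy over a subject's neutral trials, per (electrode,
#' band): the `Ref_Energy` denominator of the relative-change statistic.
#' In the epoch-based (proposed) pipeline the energies are computed on
#' the epoch frame located by [runZtwbes()]; in the whole-trial
#' baselines (`segment = "trial"`) on the full trial.
#'
#' @param store a [TrialStore-class].
#' @param subject subject id; must have neutral trials.
#' @param transform `"ngd"` (default) or `"dft"`.
#' @param segment `"epoch"` (the epoch frame; needs `plan` and
#'   `epochIndex`) or `"trial"` (whole trial).
#' @param plan a [decomposeFrames()] plan (epoch segment only).
#' @param epochIndex the epoch frame location (epoch segment only).
#' @param bandTable band table (default the store's bands).
#' @param bandlimit band-pass filter each band before its energy
#'   (default TRUE, mirroring the band-filtering stage of the pipeline).
#' @param ztw apply the zero-time window to the epoch frame before the
#'   transform (default FALSE: the window serves the epoch votes, and
#'   windowed energies are too high-variance for threshold statistics;
#'   see the methods vignette).
#' @param mode spectrum-value mode.
#' @return A `BandReference`: list with `subject`, `energy` (electrodes
#'   x bands matrix), `transform`, `segment`, `nTrials`.
#' @export
bandReference <- function(store, subject, transform = c("ngd", "dft"),
                          segment = c("epoch", "trial"), plan = NULL,
                          epochIndex = NULL, bandTable = NULL,
                          bandlimit = TRUE, ztw = FALSE,
                          mode = c("magnitude", "real")) {
  transform <- match.arg(transform)
  segment <- match.arg(segment)
  mode <- match.arg(mode)
  stopifnot(is(store, "TrialStore"))
  if (is.null(bandTable)) bandTable <- bands(store)
  lab <- trialLabels(store)
  if (!subject %in% lab$subject) stop("unknown subject: ", subject)
  ids <- lab$trial_id[lab$subject == subject &
                        !is.na(lab$emotion) & lab$emotion == "neutral"]
  if (!length(ids)) {
    stop("missing baseline: subject '", subject, "' has no neutral trials")
  }
  E <- .segmentEnergies(store, ids, transform, segment, plan, epochIndex,
                        bandTable, bandlimit, mode, ztw)
  energy <- apply(E, c(2L, 3L), mean)
  structure(list(subject = subject, energy = energy, transform = transform,
                 segment = segment, nTrials = length(ids)),
            class = "BandReference")
}

#' @export
print.BandReference <- function(x, ...) {
  cat(sprintf(
    "BandReference: subject %s (%s, %s segment), %d neutral trial(s)\n",
    x$subject, x$transform, x$segment, x$nTrials))
  invisible(x)
}

# trials x electrodes x bands energies on the configured segment
.segmentEnergies <- function(store, ids, transform, segment, plan,
                             epochIndex, bandTable, bandlimit, mode,
                             ztw = FALSE) {
  if (segment == "epoch") {
    if (is.null(plan) || is.null(epochIndex)) {
      stop("epoch segment needs a frame plan and an epoch index")
    }
    E4 <- .bandFrameEnergies(store, ids, plan, bandTable, transform,
                             bandlimit, mode, ztw, frames = epochIndex)
    E <- E4[, , , 1L, drop = FALSE]
    dim(E) <- dim(E4)[1:3]
    dimnames(E) <- dimnames(E4)[1:3]
    E
  } else {
    .bandTrialEnergies(store, ids, bandTable, transform, bandlimit, mode)
  }
}

#' Signed relative energy change
#'
#' `(energy - ref) / ref`: the percentage change of a trial's band
#' energy relative to the neutral reference. The sign is preserved here
#' (activity may rise or fall during an emotion); the significance test
#' applies the absolute value.
#'
#' @param energy observed energy (vectorised).
#' @param ref positive reference energy.
#' @return Signed relative change.
#' @examples
#' deltaChange(3, 1)    # +2
#' deltaChange(0.25, 1) # -0.75
#' @export
deltaChange <- function(energy, ref) {
  if (any(!is.finite(ref)) || any(ref <= 0)) {
    stop("degenerate baseline: reference energy must be positive")
  }
  (energy - ref) / ref
}

#' Trials with significant activity change
#'
#' The subset of a subject's trials of one emotion whose absolute
#' relative energy change at one (electrode, band) reaches the beta
#' threshold: the counting set behind the relevance probability.
#'
#' @param store a [TrialStore-class].
#' @param subject,emotion select the trial set phi(s, eta).
#' @param band band name (or one-row band table).
#' @param electrode electrode label.
#' @param ref the `Ref_Energy` scalar for this (electrode, band), or a
#'   `BandReference` to look it up in.
#' @param beta threshold on `|delta|` (default 0.5).
#' @param strict use strict `>` instead of `>=`.
#' @inheritParams bandReference
#' @return Character vector of trial ids.
#' @export
significantTrials <- function(store, subject, emotion, band, electrode, ref,
                              beta = 0.5, strict = FALSE,
                              transform = c("ngd", "dft"),
                              segment = c("epoch", "trial"), plan = NULL,
                              epochIndex = NULL, bandlimit = TRUE,
                              ztw = FALSE,
                              mode = c("magnitude", "real")) {
  transform <- match.arg(transform)
  segment <- match.arg(segment)
  mode <- match.arg(mode)
  emotion <- .canonEmotion(emotion)
  bandTable <- bands(store)
  if (is.character(band)) {
    bandName <- band
  } else {
    bandName <- band$name
  }
  if (!bandName %in% bandTable$name) stop("unknown band: ", bandName)
  sub <- queryTrials(store, subject, emotion)
  ids <- trialIds(sub)
  if (inherits(ref, "BandReference")) ref <- ref$energy[electrode, bandName]
  E <- .segmentEnergies(store, ids, transform, segment, plan, epochIndex,
                        bandTable, bandlimit, mode, ztw)
  d <- deltaChange(E[, electrode, bandName], ref)
  keep <- if (strict) abs(d) > beta else abs(d) >= beta
  ids[keep]
}

#' Relevance probability
#'
#' `rho = gammaCount / trialCount`: the fraction of an emotion's trials
#' showing a significant change at one (electrode, band).
#'
#' @param gammaCount number of significant trials (0..trialCount).
#' @param trialCount number of trials of the emotion (>= 1).
#' @return Probability in `[0, 1]`.
#' @examples
#' relevanceProbability(3, 4)  # 0.75
#' @export
relevanceProbability <- function(gammaCount, trialCount) {
  if (any(trialCount < 1)) stop("trialCount must be >= 1")
  if (any(gammaCount < 0) || any(gammaCount > trialCount)) {
    stop("gammaCount must be within 0..trialCount")
  }
  gammaCount / trialCount
}

# Core of the electrode selector, shared with the CV pipeline:
# energies/refs are precomputed; phi is a named list emotion -> trial
# ids. Returns counts, rho and the relevant sets over the elite.
.relevanceCore <- function(E, refMat, phi, elite, alpha, beta, strict) {
  bandNames <- dimnames(E)[[3]]
  emotionsHere <- names(phi)
  rho <- array(0, c(length(emotionsHere), length(bandNames), length(elite)),
               dimnames = list(emotionsHere, bandNames, elite))
  counts <- rho
  relevant <- list()
  for (em in emotionsHere) {
    ids <- phi[[em]]
    relevant[[em]] <- list()
    for (b in bandNames) {
      Em <- matrix(E[ids, elite, b, drop = FALSE], nrow = length(ids))
      d <- sweep(Em, 2L, refMat[elite, b], function(e, r) (e - r) / r)
      sig <- if (strict) abs(d) > beta else abs(d) >= beta
      cnt <- colSums(sig)
      counts[em, b, ] <- cnt
      rho[em, b, ] <- cnt / length(ids)
      keep <- if (strict) rho[em, b, ] > alpha else rho[em, b, ] >= alpha
      relevant[[em]][[b]] <- elite[keep]
    }
  }
  list(rho = rho, counts = counts, relevant = relevant)
}

#' Select relevant electrodes per emotion and band
#'
#' For every non-neutral emotion of a subject and every frequency band,
#' finds the elite electrodes whose probability of a significant
#' baseline-relative energy change reaches the alpha threshold:
#' \deqn{\Gamma(s,\eta,f) = \{e \in Elite[s] :
#'   \rho(s,\eta,f,e) \ge \alpha\}.}
#' The neutral state is excluded (it is the reference); emotions with
#' no trials yield empty sets with a warning.
#'
#' @param store a [TrialStore-class].
#' @param subject subject id.
#' @param elite elite electrode labels (from [runZtwbes()]), or an
#'   [EpochSelection-class] object (its elite, plan and winner are then
#'   used). For the whole-trial baselines pass the full montage.
#' @param alpha probability threshold (default 0.5).
#' @param beta energy-change threshold (default 0.5).
#' @param strict use strict `>` comparisons instead of `>=`.
#' @inheritParams bandReference
#' @param refs optional precomputed `BandReference`.
#' @return A [RelevanceMap-class] object.
#' @export
selectRelevant <- function(store, subject, elite, alpha = 0.5, beta = 0.5,
                           transform = c("ngd", "dft"),
                           segment = c("epoch", "trial"), plan = NULL,
                           epochIndex = NULL, bandlimit = TRUE,
                           ztw = FALSE, strict = FALSE,
                           mode = c("magnitude", "real"), refs = NULL) {
  transform <- match.arg(transform)
  segment <- match.arg(segment)
  mode <- match.arg(mode)
  stopifnot(is(store, "TrialStore"))
  if (is(elite, "EpochSelection")) {
    if (is.null(plan)) plan <- structure(elite@plan, class = "FramePlan")
    if (is.null(epochIndex)) epochIndex <- elite@winner
    elite <- elite@elite
  }
  if (!length(elite)) {
    warning("empty elite set: all relevant sets are empty")
  }
  miss <- setdiff(elite, montage(store)$label)
  if (length(miss)) stop("elite electrodes not in montage: ",
                         paste(miss, collapse = ", "))
  lab <- trialLabels(store)
  if (!subject %in% lab$subject) stop("unknown subject: ", subject)
  del <- lab[lab$subject == subject & !is.na(lab$emotion), , drop = FALSE]
  emo <- setdiff(intersect(emotionLevels(), unique(del$emotion)), "neutral")
  if (!length(emo)) warning("subject has no emotional trials")
  phi <- lapply(emo, function(em) del$trial_id[del$emotion == em])
  names(phi) <- emo
  if (is.null(refs)) {
    refs <- bandReference(store, subject, transform, segment, plan,
                          epochIndex, bands(store), bandlimit, ztw, mode)
  }
  if (any(refs$energy <= 0)) {
    stop("degenerate baseline: zero reference energy at some (electrode, band)")
  }
  allIds <- unlist(phi, use.names = FALSE)
  E <- .segmentEnergies(store, allIds, transform, segment, plan, epochIndex,
                        bands(store), bandlimit, mode, ztw)
  core <- .relevanceCore(E, refs$energy, phi, elite, alpha, beta, strict)
  new("RelevanceMap", subject = subject, alpha = alpha, beta = beta,
      rho = core$rho, counts = core$counts,
      phiSizes = vapply(phi, length, integer(1)),
      relevant = core$relevant, elite = elite)
}

#' @rdname ztwbes-generics
#' @export
setMethod("relevanceRho", "RelevanceMap", function(x) x@rho)

#' @rdname ztwbes-generics
#' @param emotion,band emotion label and band name.
#' @export
setMethod("relevantElectrodes", "RelevanceMap", function(x, emotion, band) {
  emotion <- .canonEmotion(emotion)
  if (!emotion %in% names(x@relevant)) {
    stop("no relevance entry for emotion: ", emotion)
  }
  if (!band %in% names(x@relevant[[emotion]])) stop("unknown band: ", band)
  x@relevant[[emotion]][[band]]
})

setMethod("show", "RelevanceMap", function(object) {
  cat(sprintf(
    "RelevanceMap: subject %s, alpha = %g, beta = %g, %d elite electrode(s)\n",
    object@subject, object@alpha, object@beta, length(object@elite)))
  for (em in names(object@relevant)) {
    sizes <- vapply(object@relevant[[em]], length, integer(1))
    cat(sprintf("  %-10s %s\n", em,
                paste(sprintf("%s:%d", names(sizes), sizes), collapse = " ")))
  }
})
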