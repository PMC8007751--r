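#' Neutral-baseline reference energy per electrode
#'
#' Average multiband NGD energy of a subject's neutral trials, per
#' electrode: the `Average_Energy` baseline the ZTWBES epoch votes are
#' measured against. By default the baseline is a whole-trial
#' statistic (full-trial NGD spectrum, no zero-time window); setting
#' `windowed = TRUE` instead averages ZTW-windowed frame energies over
#' the frames of `plan`, for sensitivity analysis.
#'
#' @param store a [TrialStore-class].
#' @param subject subject id; must have neutral trials.
#' @param bandTable band table (default the store's bands).
#' @param windowed use ZTW-windowed frame energies for the baseline?
#' @param plan [decomposeFrames()] plan, required when `windowed`.
#' @param mode spectrum-value mode passed to [multibandEnergy()].
#' @return A `NeutralReference`: list with `subject`, `energy` (named
#'   vector per electrode, >= 0) and `nTrials`.
#' @export
neutralReference <- function(store, subject, bandTable = NULL,
                             windowed = FALSE, plan = NULL,
                             mode = c("magnitude", "real")) {
  mode <- match.arg(mode)
  stopifnot(is(store, "TrialStore"))
  if (is.null(bandTable)) bandTable <- bands(store)
  lab <- trialLabels(store)
  ids <- lab$trial_id[lab$subject == subject &
                        !is.na(lab$emotion) & lab$emotion == "neutral"]
  if (!subject %in% lab$subject) stop("unknown subject: ", subject)
  if (!length(ids)) {
    stop("missing baseline: subject '", subject, "' has no neutral trials")
  }
  fs <- sampleRate(store)
  acc <- 0
  for (id in ids) {
    x <- trialData(store, id)
    if (windowed) {
      if (is.null(plan)) stop("windowed baseline needs a frame plan")
      w <- ztwWindow(plan$frameLen)
      e <- 0
      for (k in seq_len(plan$n)) {
        fr <- applyZtw(x[, .frameSamples(plan, k), drop = FALSE], w)
        e <- e + multibandEnergy(ngdSpectrum(fr, fs), bandTable, mode = mode)
      }
      acc <- acc + e / plan$n
    } else {
      acc <- acc + multibandEnergy(ngdSpectrum(x, fs), bandTable, mode = mode)
    }
  }
  energy <- acc / length(ids)
  names(energy) <- montage(store)$label
  structure(list(subject = subject, energy = energy,
                 nTrials = length(ids)),
            class = "NeutralReference")
}

#' @export
print.NeutralReference <- function(x, ...) {
  cat(sprintf(
    "NeutralReference: subject %s, %d neutral trial(s), %d electrode(s)\n",
    x$subject, x$nTrials, length(x$energy)))
  invisible(x)
}

#' Baseline-relative energy variation of one frame
#'
#' Applies the zero-time window to the frame, takes the NGD spectrum,
#' sums the band-weighted energy over the band table and returns the
#' absolute relative deviation from the reference energy,
#' `|(E - ref) / ref|`. The absolute value is taken because activity
#' may increase or decrease relative to the neutral state.
#'
#' @param frame numeric vector or channels x samples matrix.
#' @param refEnergy positive reference energy (scalar, or one value per
#'   channel).
#' @param bandTable band table (default [defaultBands()]).
#' @param fs sampling rate in Hz.
#' @param mode spectrum-value mode passed to [multibandEnergy()].
#' @return Non-negative variation, one value per channel.
#' @export
frameVariation <- function(frame, refEnergy, bandTable = defaultBands(),
                           fs = 128, mode = c("magnitude", "real")) {
  mode <- match.arg(mode)
  if (any(!is.finite(refEnergy)) || any(refEnergy <= 0)) {
    stop("degenerate baseline: reference energy must be positive")
  }
  w <- ztwWindow(if (is.vector(frame)) length(frame) else ncol(frame))
  spec <- ngdSpectrum(applyZtw(frame, w), fs)
  e <- multibandEnergy(spec, bandTable, mode = mode)
  abs((e - refEnergy) / refEnergy)
}

#' Tag the maximum-variation frame of a trial
#'
#' For every electrode, finds the frame whose ZTW+NGD multiband energy
#' deviates most (in absolute relative terms) from the electrode's
#' neutral reference. Ties break to the earliest frame.
#'
#' @param trial channels x samples matrix (or a vector for one channel).
#' @param plan a [decomposeFrames()] plan.
#' @param ref a `NeutralReference` (or a positive numeric vector of
#'   per-channel reference energies).
#' @param bandTable band table (default [defaultBands()]).
#' @param fs sampling rate in Hz.
#' @param mode spectrum-value mode.
#' @return Integer vector of elected frame locations, one per channel.
#' @export
tagTrial <- function(trial, plan, ref, bandTable = defaultBands(), fs = 128,
                     mode = c("magnitude", "real")) {
  mode <- match.arg(mode)
  if (is.vector(trial)) trial <- matrix(trial, nrow = 1L)
  refEnergy <- if (inherits(ref, "NeutralReference")) ref$energy else ref
  v <- matrix(0, nrow(trial), plan$n)
  for (k in seq_len(plan$n)) {
    fr <- trial[, .frameSamples(plan, k), drop = FALSE]
    v[, k] <- frameVariation(fr, refEnergy, bandTable, fs, mode = mode)
  }
  tags <- as.integer(apply(v, 1L, which.max))  # earliest index on ties
  names(tags) <- rownames(trial)
  tags
}

#' Plurality vote over frame locations
#'
#' Most frequent tag; ties break to the smallest frame index.
#'
#' @param tags integer vector of frame locations (non-empty).
#' @return The elected frame location (integer).
#' @examples
#' pluralityVote(c(2, 2, 3))  # 2
#' pluralityVote(c(1, 2))     # 1 (tie-break)
#' @export
pluralityVote <- function(tags) {
  if (!length(tags)) stop("no tags to vote over")
  tab <- table(as.integer(tags))
  winners <- as.integer(names(tab)[tab == max(tab)])
  min(winners)
}

#' Majority vote across electrodes
#'
#' Selects the frame location elected by more than 50% of the
#' electrodes. If no location reaches a strict majority the vote falls
#' back to plurality (smallest index on ties) with a warning, and the
#' recorded margin stays at or below 0.5.
#'
#' @param candidates named integer vector: one elected frame location
#'   per electrode.
#' @return List with `winner` (frame location), `elite` (labels of the
#'   agreeing electrodes) and `margin` (`|elite| / |electrodes|`).
#' @export
majorityVote <- function(candidates) {
  if (!length(candidates)) stop("no electrode candidates to vote over")
  if (is.null(names(candidates))) {
    names(candidates) <- paste0("e", seq_along(candidates))
  }
  tab <- table(as.integer(candidates))
  top <- max(tab)
  winner <- min(as.integer(names(tab)[tab == top]))
  if (top <= length(candidates) / 2) {
    warning(sprintf(
      "no strict majority (best location %d backed by %d of %d electrodes); %s",
      winner, top, length(candidates), "falling back to plurality"))
  }
  elite <- names(candidates)[candidates == winner]
  list(winner = winner, elite = elite,
       margin = length(elite) / length(candidates))
}

#' ZTW-based epoch selection (ZTWBES)
#'
#' Runs the full epoch-selection procedure for one subject: computes
#' the neutral baseline per electrode, decomposes every emotional trial
#' into frames, tags each electrode's maximum-variation frame per
#' trial, reduces each electrode's tags to a single candidate by
#' plurality vote, and elects the subject's epoch location by majority
#' vote across electrodes. Electrodes agreeing with the winner form the
#' elite set used by downstream relevance analysis.
#'
#' @param store a [TrialStore-class].
#' @param subject subject id with neutral and at least one emotional trial.
#' @param kappa frame length in seconds (default 15).
#' @param shift frame shift in seconds (default 15).
#' @param includeNeutral include the neutral trials in the voting pool?
#'   Off by default: they define the baseline.
#' @param windowedBaseline compute the baseline from ZTW-windowed frames
#'   instead of the whole trial (sensitivity analysis).
#' @param mode spectrum-value mode.
#' @return An [EpochSelection-class] object.
#' @examples
#' sim <- simulateStore(simConfig(nChannels = 8, trialLenS = 8,
#'                                trialsPerEmotion = 2, kappa = 2,
#'                                shift = 2, relevantFraction = 0.6))
#' es <- runZtwbes(sim$store, "s01", kappa = 2, shift = 2)
#' winnerLocation(es)
#' @export
runZtwbes <- function(store, subject, kappa = 15, shift = 15,
                      includeNeutral = FALSE, windowedBaseline = FALSE,
                      mode = c("magnitude", "real")) {
  mode <- match.arg(mode)
  stopifnot(is(store, "TrialStore"))
  lab <- trialLabels(store)
  if (!subject %in% lab$subject) stop("unknown subject: ", subject)
  del <- lab[lab$subject == subject, , drop = FALSE]
  voteIds <- del$trial_id[!is.na(del$emotion) &
                            (includeNeutral | del$emotion != "neutral")]
  if (!length(voteIds)) stop("subject '", subject, "' has no emotional trials")
  fs <- sampleRate(store)
  trialLenS <- ncol(trialData(store, voteIds[1L])) / fs
  plan <- decomposeFrames(trialLenS, kappa, shift, fs)
  ref <- neutralReference(store, subject, bands(store),
                          windowed = windowedBaseline, plan = plan,
                          mode = mode)
  bandTable <- bands(store)
  tags <- vapply(voteIds, function(id) {
    tagTrial(trialData(store, id), plan, ref, bandTable, fs, mode = mode)
  }, integer(nrow(montage(store))))
  tags <- matrix(tags, nrow = nrow(montage(store)),
                 dimnames = list(montage(store)$label, voteIds))
  candidates <- apply(tags, 1L, pluralityVote)
  res <- majorityVote(candidates)
  new("EpochSelection", subject = subject, winner = as.integer(res$winner),
      elite = res$elite, votes = as.integer(candidates) |>
        stats::setNames(names(candidates)),
      margin = res$margin, plan = unclass(plan))
}

#' @rdname ztwbes-generics
#' @export
setMethod("winnerLocation", "EpochSelection", function(x) x@winner)

#' @rdname ztwbes-generics
#' @export
setMethod("eliteElectrodes", "EpochSelection", function(x) x@elite)

#' @rdname ztwbes-generics
#' @export
setMethod("electrodeVotes", "EpochSelection", function(x) x@votes)

#' @rdname ztwbes-generics
#' @export
setMethod("voteMargin", "EpochSelection", function(x) x@margin)

setMethod("show", "EpochSelection", function(object) {
  cat(sprintf(
    "EpochSelection: subject %s, epoch at frame %d of %d (margin %.2f)\n",
    object@subject, object@winner, object@plan$n, object@margin))
  cat(sprintf("  elite: %d of %d electrode(s)\n",
              length(object@elite), length(object@votes)))
})
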