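#' TrialStore: a collection of labelled EEG trials
#'
#' Central container of the package: a set of multi-channel EEG trials,
#' each tied to a subject and either an emotion label or
#' valence/arousal/dominance/liking ratings, together with the montage,
#' the band table and the sampling rate.
#'
#' @slot data named list of numeric matrices, one per trial,
#'   channels x samples, in montage channel order.
#' @slot labels data.frame with columns `trial_id`, `subject`,
#'   `emotion`, `valence`, `arousal`, `dominance`, `liking`
#'   (ratings may be `NA`); row order defines store order.
#' @slot montage data.frame with columns `label`, `region`, `serial`.
#' @slot bands data.frame with columns `name`, `lo`, `hi` (Hz).
#' @slot fs sampling rate in Hz.
#'
#' @seealso [TrialStore()], [queryTrials()], [simulateStore()]
#' @name TrialStore-class
#' @aliases TrialStore-class
#' @exportClass TrialStore
setClass("TrialStore",
  representation(
    data    = "list",
    labels  = "data.frame",
    montage = "data.frame",
    bands   = "data.frame",
    fs      = "numeric"
  )
)

setValidity("TrialStore", function(object) {
  msg <- character()
  lab <- object@labels
  need <- c("trial_id", "subject", "emotion", "valence", "arousal",
            "dominance", "liking")
  if (!all(need %in% names(lab))) {
    return(paste("labels must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(lab$trial_id)) msg <- c(msg, "duplicated trial_id")
  if (!identical(names(object@data), as.character(lab$trial_id))) {
    msg <- c(msg, "names(data) must equal labels$trial_id in order")
  }
  nch <- nrow(object@montage)
  for (id in names(object@data)) {
    m <- object@data[[id]]
    if (!is.matrix(m) || !is.numeric(m)) {
      msg <- c(msg, sprintf("trial '%s': data must be a numeric matrix", id))
      break
    }
    if (nrow(m) != nch) {
      msg <- c(msg, sprintf(
        "trial '%s': %d rows but montage has %d electrodes", id, nrow(m), nch))
      break
    }
    if (!all(is.finite(m))) {
      msg <- c(msg, sprintf("trial '%s': non-finite samples", id))
      break
    }
  }
  em <- lab$emotion[!is.na(lab$emotion)]
  if (!all(em %in% emotionLevels())) {
    msg <- c(msg, "emotion labels must be in emotionLevels()")
  }
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0) {
    msg <- c(msg, "fs must be a positive scalar")
  } else if (nrow(object@bands) && object@fs <= 2 * max(object@bands$hi)) {
    msg <- c(msg, "fs must exceed twice the highest band edge")
  }
  if (length(msg)) msg else TRUE
})

#' EpochSelection: result of the ZTWBES algorithm for one subject
#'
#' @slot subject subject identifier.
#' @slot winner winning frame location (`Epoch[s]`), integer in 1..nFrames.
#' @slot elite electrode labels whose elected location matches the winner
#'   (`Elite[s]`).
#' @slot votes named integer vector: each electrode's elected frame.
#' @slot margin fraction of electrodes agreeing with the winner; a value
#'   not above 0.5 means the strict majority rule failed and the
#'   plurality fallback was used.
#' @slot plan the [decomposeFrames()] plan the locations refer to.
#'
#' @seealso [runZtwbes()]
#' @name EpochSelection-class
#' @aliases EpochSelection-class
#' @exportClass EpochSelection
setClass("EpochSelection",
  representation(
    subject = "character",
    winner  = "integer",
    elite   = "character",
    votes   = "integer",
    margin  = "numeric",
    plan    = "list"
  )
)

setValidity("EpochSelection", function(object) {
  msg <- character()
  if (length(object@winner) != 1L || object@winner < 1L) {
    msg <- c(msg, "winner must be a single frame index >= 1")
  }
  n <- object@plan$n
  if (!is.null(n) && length(object@winner) == 1L && object@winner > n) {
    msg <- c(msg, "winner exceeds the number of frames in the plan")
  }
  if (is.null(names(object@votes))) msg <- c(msg, "votes must be named")
  agreeing <- names(object@votes)[object@votes == object@winner]
  if (!setequal(object@elite, agreeing)) {
    msg <- c(msg, "elite must be exactly the electrodes voting the winner")
  }
  m <- length(object@elite) / max(1L, length(object@votes))
  if (length(object@margin) != 1L || abs(object@margin - m) > 1e-12) {
    msg <- c(msg, "margin must equal |elite| / |electrodes|")
  }
  if (length(msg)) msg else TRUE
})

#' RelevanceMap: relevant electrodes per emotion and band
#'
#' Per-subject map of relevance probabilities \eqn{\rho(s,\eta,f,e)} --
#' the fraction of the subject's trials of emotion \eqn{\eta} whose
#' absolute baseline-relative band-energy change at electrode e in band
#' f reaches `beta` -- and the derived relevant sets
#' \eqn{\Gamma(s,\eta,f)} of elite electrodes with \eqn{\rho \ge \alpha}.
#'
#' @slot subject subject identifier.
#' @slot alpha probability threshold in `[0,1]`.
#' @slot beta energy-change threshold (>= 0).
#' @slot rho numeric array emotion x band x electrode of probabilities.
#' @slot counts integer array, same shape: significant-trial counts.
#' @slot phiSizes named integer vector: trials per emotion.
#' @slot relevant list: `relevant[[emotion]][[band]]` electrode labels.
#' @slot elite the elite electrode labels the map was restricted to.
#'
#' @seealso [selectRelevant()], [relevantElectrodes()]
#' @name RelevanceMap-class
#' @aliases RelevanceMap-class
#' @exportClass RelevanceMap
setClass("RelevanceMap",
  representation(
    subject  = "character",
    alpha    = "numeric",
    beta     = "numeric",
    rho      = "array",
    counts   = "array",
    phiSizes = "integer",
    relevant = "list",
    elite    = "character"
  )
)

setValidity("RelevanceMap", function(object) {
  msg <- character()
  if (object@alpha < 0 || object@alpha > 1) msg <- c(msg, "alpha must be in [0,1]")
  if (object@beta < 0) msg <- c(msg, "beta must be >= 0")
  r <- object@rho
  if (length(r) && (min(r) < 0 || max(r) > 1)) msg <- c(msg, "rho outside [0,1]")
  for (em in names(object@relevant)) {
    for (b in names(object@relevant[[em]])) {
      if (!all(object@relevant[[em]][[b]] %in% object@elite)) {
        msg <- c(msg, "relevant sets must be subsets of the elite electrodes")
      }
    }
  }
  if (length(msg)) unique(msg) else TRUE
})

#' EmotionEnsemble: one-vs-all (or all-together) emotion classifiers
#'
#' @slot mode one of `"qdc"`, `"nn1"` (one-vs-all) or `"nn2"`
#'   (all-together network).
#' @slot members named list of fitted members; for one-vs-all modes one
#'   binary classifier per non-neutral emotion, for `"nn2"` a single
#'   multi-output network under `"all"`.
#' @slot trainAcc named numeric vector of training accuracies in `[0,1]`.
#' @slot specs named list of feature specifications ([featureSpec()]),
#'   fixing electrode order at training time.
#' @slot emotions the emotion labels covered, in canonical order.
#'
#' @seealso [trainEnsemble()], [predictEnsemble()], [fuseVotes()]
#' @name EmotionEnsemble-class
#' @aliases EmotionEnsemble-class
#' @exportClass EmotionEnsemble
setClass("EmotionEnsemble",
  representation(
    mode     = "character",
    members  = "list",
    trainAcc = "numeric",
    specs    = "list",
    emotions = "character"
  )
)

setValidity("EmotionEnsemble", function(object) {
  msg <- character()
  if (!object@mode %in% c("qdc", "nn1", "nn2")) {
    msg <- c(msg, "mode must be 'qdc', 'nn1' or 'nn2'")
  }
  if (object@mode %in% c("qdc", "nn1")) {
    if (length(object@members) != 8L) {
      msg <- c(msg, "one-vs-all ensembles hold exactly 8 members")
    }
    if ("neutral" %in% names(object@members)) {
      msg <- c(msg, "neutral has no one-vs-all member")
    }
  }
  acc <- object@trainAcc
  if (length(acc) && (min(acc) < 0 || max(acc) > 1)) {
    msg <- c(msg, "training accuracies must be in [0,1]")
  }
  if (length(msg)) msg else TRUE
})
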