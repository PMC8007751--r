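#' Build a TrialStore
#'
#' Assembles trials, labels, montage and band table into a validated
#' [TrialStore-class] object.
#'
#' @param data named list of numeric matrices (channels x samples), one
#'   per trial; names are the trial ids. A single matrix is accepted for
#'   a one-trial store.
#' @param labels data.frame with at least `trial_id`, `subject` and
#'   either `emotion` or rating columns (`valence`, `arousal`,
#'   `dominance`, `liking`). Missing rating columns are filled with NA.
#'   When `emotion` is absent but valence/arousal are present, labels
#'   are derived with [vadToEmotion()].
#' @param montage electrode table (default [deapMontage()] trimmed to
#'   the channel count of the first trial).
#' @param bands band table (default [defaultBands()]).
#' @param fs sampling rate in Hz (default 128).
#' @return A `TrialStore` object.
#' @examples
#' x <- matrix(rnorm(2 * 64), 2, 64)
#' st <- TrialStore(list(t1 = x),
#'                  data.frame(trial_id = "t1", subject = "s1",
#'                             emotion = "happy"),
#'                  montage = deapMontage(2), fs = 128)
#' nTrials(st)
#' @export
TrialStore <- function(data, labels, montage = NULL,
                       bands = defaultBands(), fs = 128) {
  if (is.matrix(data)) data <- list(trial1 = data)
  stopifnot(is.list(data), length(data) >= 1L)
  if (is.null(names(data)) && !is.null(labels$trial_id)) {
    names(data) <- as.character(labels$trial_id)
  }
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  labels$trial_id <- as.character(labels$trial_id)
  labels$subject <- as.character(labels$subject)
  for (col in c("valence", "arousal", "dominance", "liking")) {
    if (is.null(labels[[col]])) labels[[col]] <- NA_real_
    labels[[col]] <- as.numeric(labels[[col]])
  }
  if (is.null(labels$emotion)) {
    if (all(is.na(labels$valence)) || all(is.na(labels$arousal))) {
      stop("labels need either an 'emotion' column or valence/arousal ratings")
    }
    labels$emotion <- vadToEmotion(labels$valence, labels$arousal)
  }
  labels$emotion <- .canonEmotion(labels$emotion)
  labels <- labels[, c("trial_id", "subject", "emotion", "valence",
                       "arousal", "dominance", "liking")]
  rownames(labels) <- NULL
  if (!setequal(names(data), labels$trial_id)) {
    stop("names(data) and labels$trial_id must contain the same trial ids")
  }
  data <- data[labels$trial_id]
  data <- lapply(data, function(m) {
    if (is.vector(m)) m <- matrix(m, nrow = 1L)
    storage.mode(m) <- "double"
    m
  })
  if (is.null(montage)) montage <- deapMontage(nrow(data[[1L]]))
  .checkMontage(montage)
  .checkBands(bands)
  new("TrialStore", data = data, labels = labels, montage = montage,
      bands = bands, fs = as.numeric(fs))
}

#' @rdname ztwbes-generics
#' @export
setMethod("nTrials", "TrialStore", function(x) length(x@data))

#' @rdname ztwbes-generics
#' @export
setMethod("trialIds", "TrialStore", function(x) names(x@data))

#' @rdname ztwbes-generics
#' @export
setMethod("subjects", "TrialStore", function(x) unique(x@labels$subject))

#' @rdname ztwbes-generics
#' @export
setMethod("emotions", "TrialStore",
          function(x) unique(x@labels$emotion[!is.na(x@labels$emotion)]))

#' @rdname ztwbes-generics
#' @export
setMethod("montage", "TrialStore", function(x) x@montage)

#' @rdname ztwbes-generics
#' @export
setMethod("bands", "TrialStore", function(x) x@bands)

#' @rdname ztwbes-generics
#' @export
setMethod("sampleRate", "TrialStore", function(x) x@fs)

#' @rdname ztwbes-generics
#' @export
setMethod("trialLabels", "TrialStore", function(x) x@labels)

#' @rdname ztwbes-generics
#' @param id trial identifier (or index).
#' @export
setMethod("trialData", "TrialStore", function(x, id) {
  if (is.numeric(id)) id <- names(x@data)[id]
  if (length(id) != 1L || is.na(id) || !id %in% names(x@data)) {
    stop("unknown trial id: ", id)
  }
  x@data[[id]]
})

#' @describeIn TrialStore-class subset a store by trial ids or indices.
#' @param x,i store and trial selector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "TrialStore", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    miss <- setdiff(i, names(x@data))
    if (length(miss)) stop("unknown trial id(s): ", paste(miss, collapse = ", "))
    keep <- match(i, x@labels$trial_id)
  } else {
    keep <- seq_len(nTrials(x))[i]
  }
  initialize(x, data = x@data[keep],
             labels = x@labels[keep, , drop = FALSE])
})

setMethod("show", "TrialStore", function(object) {
  lab <- object@labels
  ns <- length(unique(lab$subject))
  ne <- length(unique(lab$emotion[!is.na(lab$emotion)]))
  len <- if (length(object@data)) ncol(object@data[[1L]]) else 0L
  cat(sprintf(
    "TrialStore: %d trial(s), %d channel(s) x %d sample(s) @ %g Hz\n",
    nTrials(object), nrow(object@montage), len, object@fs))
  cat(sprintf("  %d subject(s), %d emotion label(s); bands: %s\n",
              ns, ne, paste(object@bands$name, collapse = ", ")))
})

#' Query trials by subject and/or emotion
#'
#' Implements the trial-index maps of the data model: `delta(s)` (all
#' trials of a subject), `sigma(eta)` (all trials of an emotion) and
#' `phi(s, eta) = delta(s) intersect sigma(eta)`. The result preserves
#' store order.
#'
#' @param store a [TrialStore-class].
#' @param subject optional subject id.
#' @param emotion optional emotion label.
#' @return A sub-`TrialStore` with the matching trials.
#' @examples
#' st <- simulateStore(simConfig(nChannels = 4, trialLenS = 4,
#'                               trialsPerEmotion = 1, kappa = 2, shift = 2))$store
#' nTrials(queryTrials(st, subject = "s01", emotion = "happy"))
#' @export
queryTrials <- function(store, subject = NULL, emotion = NULL) {
  stopifnot(is(store, "TrialStore"))
  if (is.null(subject) && is.null(emotion)) {
    stop("give at least one of 'subject' and 'emotion'")
  }
  lab <- store@labels
  keep <- rep(TRUE, nrow(lab))
  if (!is.null(subject)) {
    if (!subject %in% lab$subject) stop("unknown subject: ", subject)
    keep <- keep & lab$subject == subject
  }
  if (!is.null(emotion)) {
    emotion <- .canonEmotion(emotion)
    if (!emotion %in% lab$emotion) stop("unknown emotion: ", emotion)
    keep <- keep & !is.na(lab$emotion) & lab$emotion == emotion
  }
  store[which(keep)]
}

#' Map valence/arousal ratings to an emotion label
#'
#' Splits each rating axis into low/mid/high at the given cutpoints and
#' reads the label from a 3 x 3 grid (arousal row x valence column).
#' The default grid is a circumplex-style placement -- low arousal:
#' depressed / calm / relaxed; mid: miserable / neutral / pleased;
#' high: distressed / excited / happy -- and can be overridden; the
#' source the mapping follows does not print its table, so the default
#' is a documented design choice.
#'
#' @param valence,arousal numeric ratings in `[1, 9]` (vectorised).
#' @param cutpoints two increasing thresholds splitting `[1, 9]`;
#'   default thirds `c(3.667, 6.333)`. A value below the first cutpoint
#'   is "low", below the second "mid", otherwise "high".
#' @param grid optional 3 x 3 character matrix (rows = arousal
#'   low/mid/high, columns = valence low/mid/high) overriding the
#'   default placement.
#' @return Character vector of emotion labels.
#' @examples
#' vadToEmotion(5, 5)  # "neutral"
#' vadToEmotion(8, 8)  # "happy"
#' vadToEmotion(2, 2)  # "depressed"
#' @export
vadToEmotion <- function(valence, arousal, cutpoints = c(3.667, 6.333),
                         grid = NULL) {
  stopifnot(length(cutpoints) == 2L, cutpoints[1] < cutpoints[2])
  if (length(valence) != length(arousal)) {
    stop("valence and arousal must have the same length")
  }
  if (any(!is.finite(valence)) || any(!is.finite(arousal)) ||
      any(valence < 1 | valence > 9) || any(arousal < 1 | arousal > 9)) {
    stop("ratings must be finite and within [1, 9]")
  }
  if (is.null(grid)) {
    grid <- matrix(c("depressed",  "calm",    "relaxed",
                     "miserable",  "neutral", "pleased",
                     "distressed", "excited", "happy"),
                   nrow = 3, byrow = TRUE)
  }
  stopifnot(is.matrix(grid), all(dim(grid) == c(3L, 3L)))
  lev <- function(v) 1L + (v >= cutpoints[1]) + (v >= cutpoints[2])
  grid[cbind(lev(arousal), lev(valence))]
}
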