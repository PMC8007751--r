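#' Feature specification from a relevance map
#'
#' Fixes, at training time, the ordered list of (band, electrode)
#' pairs whose relative energy changes form the feature vector of one
#' emotion's classifier. For `emotion = "all"` (the all-together
#' scheme) the union of every emotion's relevant electrodes is taken
#' per band. The order -- bands in table order, electrodes in elite
#' order -- is reused verbatim at predict time.
#'
#' @param relmap a [RelevanceMap-class].
#' @param emotion a non-neutral emotion label, or `"all"`.
#' @return A `FeatureSpec`: list with `emotion`, `pairs` (data.frame
#'   `band`, `electrode`) and `dimension`.
#' @export
featureSpec <- function(relmap, emotion) {
  stopifnot(is(relmap, "RelevanceMap"))
  bandNames <- dimnames(relmap@rho)[[2]]
  pairs <- list()
  for (b in bandNames) {
    if (identical(emotion, "all")) {
      els <- unique(unlist(lapply(relmap@relevant, function(r) r[[b]]),
                           use.names = FALSE))
      els <- relmap@elite[relmap@elite %in% els]  # stable elite order
    } else {
      emotion <- .canonEmotion(emotion)
      if (!emotion %in% names(relmap@relevant)) {
        stop("no relevance entry for emotion: ", emotion)
      }
      els <- relmap@relevant[[emotion]][[b]]
    }
    if (length(els)) {
      pairs[[b]] <- data.frame(band = b, electrode = els,
                               stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(band = character(), electrode = character())
  rownames(pairs) <- NULL
  structure(list(emotion = emotion, pairs = pairs,
                 dimension = nrow(pairs)),
            class = "FeatureSpec")
}

#' @export
print.FeatureSpec <- function(x, ...) {
  cat(sprintf("FeatureSpec ('%s'): %d feature(s)\n", x$emotion, x$dimension))
  invisible(x)
}

#' Extract a trial's feature vector
#'
#' The feature vector of a trial is the signed relative band-energy
#' change `(Energy - Ref) / Ref` at every (band, electrode) pair of
#' the specification, in specification order.
#'
#' @param store a [TrialStore-class].
#' @param trialId trial identifier.
#' @param spec a [featureSpec()].
#' @param refs a `BandReference` covering every (electrode, band) in
#'   the spec; its transform/segment configuration is reused for the
#'   trial energies.
#' @param plan,epochIndex frame plan and epoch location (needed when
#'   the reference was built on the epoch segment).
#' @param bandlimit,ztw,mode energy options, as in [bandReference()].
#' @return Numeric feature vector of length `spec$dimension`.
#' @export
extractFeatures <- function(store, trialId, spec, refs, plan = NULL,
                            epochIndex = NULL, bandlimit = TRUE,
                            ztw = FALSE, mode = c("magnitude", "real")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "FeatureSpec"), inherits(refs, "BandReference"))
  if (spec$dimension == 0L) return(numeric(0))
  miss <- setdiff(spec$pairs$electrode, rownames(refs$energy))
  if (length(miss)) {
    stop("missing reference for electrode(s): ", paste(miss, collapse = ", "))
  }
  E <- .segmentEnergies(store, trialId, refs$transform, refs$segment,
                        plan, epochIndex, bands(store), bandlimit, mode,
                        ztw)
  idx <- cbind(1L, match(spec$pairs$electrode, dimnames(E)[[2]]),
               match(spec$pairs$band, dimnames(E)[[3]]))
  if (anyNA(idx)) stop("spec electrodes/bands missing from the montage/bands")
  e <- E[idx]
  r <- refs$energy[cbind(spec$pairs$electrode, spec$pairs$band)]
  deltaChange(e, r)
}

# feature matrix for many trials from a precomputed trials x
# electrodes x bands energy array (internal fast path)
.featureMatrix <- function(E, ids, spec, refMat) {
  n <- length(ids)
  if (spec$dimension == 0L) {
    return(matrix(numeric(0), nrow = n, ncol = 0L))
  }
  cols <- matrix(NA_real_, n, spec$dimension)
  ei <- match(spec$pairs$electrode, dimnames(E)[[2]])
  bi <- match(spec$pairs$band, dimnames(E)[[3]])
  ti <- match(ids, dimnames(E)[[1]])
  for (j in seq_len(spec$dimension)) {
    r <- refMat[spec$pairs$electrode[j], spec$pairs$band[j]]
    cols[, j] <- (E[cbind(ti, ei[j], bi[j])] - r) / r
  }
  cols
}

#' Fuse one-vs-all votes into a final label
#'
#' The three-rule decision of the one-vs-all ensembles, applied to the
#' eight binary target/outlier votes:
#' * all eight vote *outlier* -- the trial is **neutral**;
#' * a minority (1--4) votes *target* -- the trial takes the label of
#'   the target-voting classifier with the highest training accuracy
#'   (ties to the first emotion in canonical order);
#' * a majority (5 or more) votes *target* -- the ensemble is
#'   inconsistent and the trial is **rejected** (`"reject"`).
#'
#' @param votes named vector over the eight non-neutral emotions:
#'   logical (`TRUE` = target) or character (`"target"`/`"outlier"`).
#' @param trainAcc named numeric vector of training accuracies in
#'   `[0, 1]` for the same emotions.
#' @return A single label: an emotion, `"neutral"` or `"reject"`.
#' @examples
#' emo <- emotionLevels(includeNeutral = FALSE)
#' acc <- stats::setNames(rep(0.9, 8), emo)
#' fuseVotes(stats::setNames(rep(FALSE, 8), emo), acc)  # "neutral"
#' @export
fuseVotes <- function(votes, trainAcc) {
  emo <- emotionLevels(includeNeutral = FALSE)
  if (is.character(votes)) {
    bad <- !votes %in% c("target", "outlier")
    if (any(bad)) stop("votes must be 'target' or 'outlier'")
    votes <- stats::setNames(votes == "target", names(votes))
  }
  if (is.null(names(votes)) || !setequal(names(votes), emo) ||
      length(votes) != 8L) {
    stop("votes must be named with exactly the eight non-neutral emotions")
  }
  if (anyNA(votes)) stop("missing vote")
  if (is.null(names(trainAcc)) || !all(emo %in% names(trainAcc))) {
    stop("trainAcc must be named with the eight non-neutral emotions")
  }
  votes <- votes[emo]
  trainAcc <- trainAcc[emo]
  ct <- sum(votes)
  if (ct == 0L) return("neutral")
  if (ct >= 5L) return("reject")
  cand <- emo[votes]
  cand[which.max(trainAcc[cand])]  # which.max: first (canonical) on ties
}

#' Train an emotion-classification ensemble
#'
#' For the one-vs-all modes (`"qdc"`, `"nn1"`), trains one binary
#' target-vs-outlier classifier per non-neutral emotion on that
#' emotion's own feature space; for `"nn2"`, trains a single
#' all-together network with one output per emotion (neutral
#' included). An emotion whose feature space is empty, or with too few
#' target trials, gets a trivial always-outlier member whose training
#' accuracy is its outlier fraction.
#'
#' @param featureList named list: for one-vs-all modes,
#'   `featureList[[emotion]]` is the training feature matrix (rows =
#'   training trials in `y` order) for that emotion's spec; for
#'   `"nn2"`, a single-element list `list(all = X)`.
#' @param y emotion labels of the training trials.
#' @param specs named list of [featureSpec()] objects matching
#'   `featureList`.
#' @param mode `"qdc"`, `"nn1"` or `"nn2"`.
#' @param includeNeutralOutliers include neutral training trials among
#'   the outliers of the one-vs-all members (default FALSE: the
#'   neutral state is the reference, not an outlier class).
#' @param shrink QDC covariance shrinkage: `NULL` (default) picks
#'   `d / (d + n_k)` per class when a class has `n_k <= d` samples and
#'   0 otherwise; a number fixes it globally.
#' @param nnIter,nnLambda,nnLambdaFactor,nnErrTarget LM training
#'   parameters for the network modes (defaults 5, 3, 10, 1e-10).
#' @return An [EmotionEnsemble-class].
#' @export
trainEnsemble <- function(featureList, y, specs, mode = c("qdc", "nn1", "nn2"),
                          includeNeutralOutliers = FALSE, shrink = NULL,
                          nnIter = 5L, nnLambda = 3, nnLambdaFactor = 10,
                          nnErrTarget = 1e-10) {
  mode <- match.arg(mode)
  y <- .canonEmotion(y)
  emo <- emotionLevels(includeNeutral = FALSE)
  members <- list(); acc <- numeric(0)
  if (mode == "nn2") {
    X <- featureList[["all"]]
    stopifnot(!is.null(X), nrow(X) == length(y))
    labs <- emotionLevels()
    Y <- outer(y, labs, "==") * 1
    if (ncol(X) < 1L) {
      # empty feature space: degenerate model predicting the reference state
      members[["all"]] <- structure(list(), class = "NeutralOnly")
      acc["all"] <- mean(y == "neutral")
      return(new("EmotionEnsemble", mode = mode, members = members,
                 trainAcc = acc, specs = specs["all"], emotions = labs))
    }
    net <- lmNet(ncol(X), outputSize = length(labs))
    net <- lmFit(net, X, Y, maxIter = nnIter, errTarget = nnErrTarget,
                 lambda = nnLambda, lambdaFactor = nnLambdaFactor)
    pred <- nnPredict(net, X, labels = labs)
    members[["all"]] <- net
    acc["all"] <- mean(pred == y)
    return(new("EmotionEnsemble", mode = mode, members = members,
               trainAcc = acc, specs = specs["all"], emotions = labs))
  }
  for (em in emo) {
    X <- featureList[[em]]
    keep <- if (includeNeutralOutliers) rep(TRUE, length(y)) else
      y != "neutral"
    Xk <- X[keep, , drop = FALSE]
    yk <- ifelse(y[keep] == em, "target", "outlier")
    nTarget <- sum(yk == "target")
    if (is.null(X) || ncol(X) == 0L || nTarget < 2L ||
        sum(yk == "outlier") < 2L) {
      members[[em]] <- structure(list(emotion = em), class = "OutlierOnly")
      acc[em] <- mean(yk == "outlier")
      next
    }
    if (mode == "qdc") {
      s <- shrink
      if (is.null(s)) {
        d <- ncol(Xk)
        nmin <- min(table(yk))
        s <- if (nmin <= d) d / (d + nmin) else 0
      }
      fit <- qdcFit(Xk, yk, shrink = s)
      pred <- qdcPredict(fit, Xk)$label
    } else {
      net <- lmNet(ncol(Xk))
      net <- lmFit(net, Xk, as.numeric(yk == "target"), maxIter = nnIter,
                   errTarget = nnErrTarget, lambda = nnLambda,
                   lambdaFactor = nnLambdaFactor)
      fit <- net
      pred <- ifelse(nnPredict(net, Xk) == 1L, "target", "outlier")
    }
    members[[em]] <- fit
    acc[em] <- mean(pred == yk)
  }
  new("EmotionEnsemble", mode = mode, members = members, trainAcc = acc,
      specs = specs[emo], emotions = emo)
}

#' @rdname ztwbes-generics
#' @export
setMethod("trainingAccuracy", "EmotionEnsemble", function(x) x@trainAcc)

setMethod("show", "EmotionEnsemble", function(object) {
  cat(sprintf("EmotionEnsemble (%s): %d member(s)\n", object@mode,
              length(object@members)))
  cat(sprintf("  training accuracy: %s\n",
              paste(sprintf("%s %.2f", names(object@trainAcc),
                            object@trainAcc), collapse = ", ")))
})

#' Predict emotions with a trained ensemble
#'
#' One-vs-all modes collect the eight binary votes per trial and fuse
#' them with [fuseVotes()]; the all-together mode takes the network
#' argmax.
#'
#' @param ensemble an [EmotionEnsemble-class].
#' @param featureList named list of feature matrices matching the
#'   ensemble's specs; every matrix must have one row per trial, in
#'   the same trial order.
#' @return List with `label` (character vector of final decisions,
#'   possibly `"neutral"`/`"reject"`) and, for one-vs-all modes,
#'   `votes` (trials x emotions logical matrix).
#' @export
predictEnsemble <- function(ensemble, featureList) {
  stopifnot(is(ensemble, "EmotionEnsemble"))
  if (ensemble@mode == "nn2") {
    X <- featureList[["all"]]
    if (inherits(ensemble@members[["all"]], "NeutralOnly")) {
      return(list(label = rep("neutral", nrow(X)), votes = NULL))
    }
    lab <- nnPredict(ensemble@members[["all"]], X,
                     labels = ensemble@emotions)
    return(list(label = as.character(lab), votes = NULL))
  }
  emo <- ensemble@emotions
  n <- nrow(featureList[[emo[1L]]])
  votes <- matrix(FALSE, n, length(emo), dimnames = list(NULL, emo))
  for (em in emo) {
    member <- ensemble@members[[em]]
    X <- featureList[[em]]
    if (is.null(X) || nrow(X) != n) {
      stop("featureList[['", em, "']] must have ", n, " row(s)")
    }
    if (inherits(member, "OutlierOnly")) {
      votes[, em] <- FALSE
    } else if (inherits(member, "QdcModel")) {
      votes[, em] <- qdcPredict(member, X)$label == "target"
    } else {
      votes[, em] <- nnPredict(member, X) == 1L
    }
  }
  lab <- vapply(seq_len(n), function(i) {
    fuseVotes(votes[i, ], ensemble@trainAcc)
  }, character(1))
  list(label = lab, votes = votes)
}
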