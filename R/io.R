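#' Write / read a TrialStore in the native plain-text layout
#'
#' The native container is a directory holding `labels.csv`,
#' `montage.csv`, `bands.csv`, `meta.csv` (the sampling rate) and one
#' `trial_<id>.csv` per trial (channels x samples, no header). Sample
#' values are written with 17 significant digits so that a write
#' followed by a read reproduces the data matrices bit for bit.
#'
#' @param store a [TrialStore-class].
#' @param path directory to create/read.
#' @return `writeStore` returns `path` invisibly; `readStore` returns a
#'   `TrialStore`.
#' @examples
#' st <- simulateStore(simConfig(nChannels = 2, trialLenS = 2,
#'                               trialsPerEmotion = 1, kappa = 1, shift = 1,
#'                               fs = 32))$store
#' d <- file.path(tempdir(), "store-demo")
#' writeStore(st, d)
#' st2 <- readStore(d)
#' identical(trialData(st, 1), trialData(st2, 1))
#' @export
writeStore <- function(store, path) {
  stopifnot(is(store, "TrialStore"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(store@labels, file.path(path, "labels.csv"),
                   row.names = FALSE)
  utils::write.csv(store@montage, file.path(path, "montage.csv"),
                   row.names = FALSE)
  utils::write.csv(store@bands, file.path(path, "bands.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(key = "fs", value = store@fs),
                   file.path(path, "meta.csv"), row.names = FALSE)
  for (id in trialIds(store)) {
    m <- store@data[[id]]
    lines <- vapply(seq_len(nrow(m)), function(i) {
      paste(sprintf("%.17g", m[i, ]), collapse = ",")
    }, character(1))
    writeLines(lines, file.path(path, paste0("trial_", id, ".csv")))
  }
  invisible(path)
}

#' @rdname writeStore
#' @export
readStore <- function(path) {
  if (!dir.exists(path)) stop("no such store directory: ", path)
  labels <- utils::read.csv(file.path(path, "labels.csv"),
                            stringsAsFactors = FALSE)
  montage <- utils::read.csv(file.path(path, "montage.csv"),
                             stringsAsFactors = FALSE)
  bandTab <- utils::read.csv(file.path(path, "bands.csv"),
                             stringsAsFactors = FALSE)
  meta <- utils::read.csv(file.path(path, "meta.csv"),
                          stringsAsFactors = FALSE)
  fs <- as.numeric(meta$value[meta$key == "fs"])
  files <- list.files(path, pattern = "^trial_.*\\.csv$")
  fileIds <- sub("^trial_(.*)\\.csv$", "\\1", files)
  miss <- setdiff(as.character(labels$trial_id), fileIds)
  if (length(miss)) {
    stop("store format error: no data file for trial '", miss[1], "'")
  }
  orphan <- setdiff(fileIds, as.character(labels$trial_id))
  if (length(orphan)) {
    stop("store format error: labels.csv has no row for trial '",
         orphan[1], "'")
  }
  nch <- nrow(montage)
  data <- lapply(as.character(labels$trial_id), function(id) {
    m <- as.matrix(data.table::fread(
      file.path(path, paste0("trial_", id, ".csv")), header = FALSE))
    dimnames(m) <- NULL
    if (nrow(m) != nch) {
      stop(sprintf(
        "store format error: trial '%s' has %d channels, montage has %d",
        id, nrow(m), nch))
    }
    m
  })
  names(data) <- as.character(labels$trial_id)
  TrialStore(data, labels, montage = montage, bands = bandTab, fs = fs)
}

#' Convert a DEAP-layout per-subject array to a TrialStore
#'
#' Adapts one subject of the preprocessed DEAP release: a
#' trials x channels x samples array (40 x 40 x 8064 as distributed)
#' plus a trials x 4 rating matrix (valence, arousal, dominance,
#' liking, each in `[1, 9]`). Only the first 32 channels -- the EEG
#' electrodes -- are kept; the peripheral channels are dropped.
#' Emotion labels are derived from the valence/arousal ratings with
#' [vadToEmotion()].
#'
#' @param data numeric array, trials x channels x samples.
#' @param labels numeric matrix, trials x 4 ratings.
#' @param subject subject id used in trial ids.
#' @param fs sampling rate (DEAP preprocessed data are 128 Hz).
#' @return A [TrialStore-class] with 32-channel trials.
#' @export
deapToStore <- function(data, labels, subject = "s01", fs = 128) {
  if (length(dim(data)) != 3L) {
    stop("data must be a trials x channels x samples array")
  }
  nt <- dim(data)[1]
  if (!is.matrix(labels) || nrow(labels) != nt || ncol(labels) < 4L) {
    stop("labels must be a ", nt, " x 4 rating matrix")
  }
  nch <- min(32L, dim(data)[2])
  montage <- deapMontage(nch)
  ids <- sprintf("%s_t%02d", subject, seq_len(nt))
  trials <- lapply(seq_len(nt), function(i) {
    m <- data[i, seq_len(nch), , drop = TRUE]
    matrix(as.numeric(m), nrow = nch)
  })
  names(trials) <- ids
  lab <- data.frame(
    trial_id = ids, subject = subject,
    emotion = vadToEmotion(labels[, 1], labels[, 2]),
    valence = labels[, 1], arousal = labels[, 2],
    dominance = labels[, 3], liking = labels[, 4],
    stringsAsFactors = FALSE
  )
  TrialStore(trials, lab, montage = montage, fs = fs)
}
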