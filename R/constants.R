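#' Default EEG frequency bands
#'
#' The four rhythm bands used throughout the package: theta (4--7 Hz),
#' alpha (8--12 Hz), beta (12--36 Hz) and gamma (36--42 Hz), ordered by
#' lower edge.
#'
#' @param names optional character vector to subset the band table.
#' @return A data.frame with columns `name`, `lo`, `hi` (Hz).
#' @examples
#' defaultBands()
#' @export
defaultBands <- function(names = NULL) {
  b <- data.frame(
    name = c("theta", "alpha", "beta", "gamma"),
    lo   = c(4, 8, 12, 36),
    hi   = c(7, 12, 36, 42),
    stringsAsFactors = FALSE
  )
  if (!is.null(names)) {
    miss <- setdiff(names, b$name)
    if (length(miss)) stop("unknown band(s): ", paste(miss, collapse = ", "))
    b <- b[match(names, b$name), , drop = FALSE]
    rownames(b) <- NULL
  }
  b
}

.checkBands <- function(bands) {
  stopifnot(is.data.frame(bands), all(c("name", "lo", "hi") %in% names(bands)))
  if (any(bands$lo >= bands$hi)) stop("band lower edge must be below upper edge")
  if (is.unsorted(bands$lo)) stop("bands must be ordered by lower edge")
  invisible(bands)
}

#' Emotional-state labels
#'
#' The nine emotional states handled by the package, in canonical order
#' (used for classifier ordering and vote tie-breaks): happy, pleased,
#' relaxed, excited, neutral, calm, distressed, miserable, depressed.
#' "pleasant" is accepted as an alias of "pleased".
#'
#' @param includeNeutral keep the neutral reference state in the list?
#' @return Character vector of labels.
#' @examples
#' emotionLevels()
#' emotionLevels(includeNeutral = FALSE)
#' @export
emotionLevels <- function(includeNeutral = TRUE) {
  lev <- c("happy", "pleased", "relaxed", "excited", "neutral",
           "calm", "distressed", "miserable", "depressed")
  if (!includeNeutral) lev <- setdiff(lev, "neutral")
  lev
}

.canonEmotion <- function(x) {
  x <- as.character(x)
  x[x == "pleasant"] <- "pleased"
  bad <- !is.na(x) & !(x %in% emotionLevels())
  if (any(bad)) {
    stop("unknown emotion label(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  x
}

#' Standard 32-channel montage
#'
#' Electrode table in the channel order of the 32-EEG-channel DEAP
#' montage (Geneva layout). `region` is the cerebral-region part of the
#' label and `serial` the within-region index: odd numbers sit over the
#' left hemisphere, even numbers over the right, and 0 marks midline
#' ("z") sites.
#'
#' @param n number of leading channels to keep (default all 32).
#' @return A data.frame with columns `label`, `region`, `serial`.
#' @examples
#' head(deapMontage())
#' @export
deapMontage <- function(n = 32L) {
  labels <- c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
              "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
              "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC2", "Cz",
              "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2")
  if (n < 1L || n > length(labels)) stop("n must be in 1..32")
  labels <- labels[seq_len(n)]
  region <- sub("[0-9z]+$", "", labels)
  serial <- ifelse(grepl("z$", labels), 0L,
                   as.integer(sub("^[A-Za-z]+", "", labels)))
  data.frame(label = labels, region = region, serial = serial,
             stringsAsFactors = FALSE)
}

.checkMontage <- function(montage) {
  stopifnot(is.data.frame(montage), "label" %in% names(montage))
  if (anyDuplicated(montage$label)) stop("montage labels must be unique")
  invisible(montage)
}
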