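#' Experiment configuration
#'
#' Bundles every stage parameter of the three experiment pipelines.
#' The variants differ only in the spectral transform and in whether
#' the epoch-selection stages run: `"dft"` and `"ngd"` skip epoch
#' selection and use the whole montage as the elite set; `"proposed"`
#' enables ZTWBES and works on the epoch frame.
#'
#' @param variant `"proposed"`, `"ngd"` or `"dft"`.
#' @param mode classifier mode (`"qdc"`, `"nn1"`, `"nn2"`).
#' @param kappa,shift,alpha,beta,bandlimit,strict,nnIter,shrink stage
#'   parameters, as in [crossvalidate()].
#' @param k folds (default 10).
#' @param seed RNG seed.
#' @return An `ExperimentConfig` list.
#' @examples
#' experimentConfig("proposed")
#' @export
experimentConfig <- function(variant = c("proposed", "ngd", "dft"),
                             mode = "qdc", kappa = 15, shift = 15,
                             alpha = 0.5, beta = 0.5, bandlimit = TRUE,
                             strict = FALSE, k = 10L, seed = 1L,
                             nnIter = 5L, shrink = NULL) {
  variant <- match.arg(variant)
  structure(list(
    variant = variant,
    transform = if (variant == "dft") "dft" else "ngd",
    epochSelection = variant == "proposed",
    mode = mode, kappa = kappa, shift = shift, alpha = alpha, beta = beta,
    bandlimit = bandlimit, strict = strict, k = k, seed = seed,
    nnIter = nnIter, shrink = shrink
  ), class = "ExperimentConfig")
}

#' @export
print.ExperimentConfig <- function(x, ...) {
  cat(sprintf("ExperimentConfig: %s (%s), k = %d, seed = %d\n",
              x$variant, x$mode, x$k, x$seed))
  invisible(x)
}

#' Run an experiment pipeline end to end
#'
#' Executes filter -> (DFT | NGD) -> (ZTWBES if proposed) -> relevance
#' -> features -> cross-validated classification for every requested
#' subject of a store and aggregates the accuracies. All data-derived
#' statistics are fold-local (see [crossvalidate()]).
#'
#' @param store a [TrialStore-class].
#' @param config an [experimentConfig()] (or a variant name).
#' @param subjects subject ids (default: all subjects in the store).
#' @param outDir optional directory; when given, the per-subject
#'   results and this report are persisted as JSON.
#' @return An `ExperimentReport`: list with `config`, `perSubject`
#'   (list of `CvResult`), `meanFinalAccuracy`,
#'   `meanFinalAccuracyExclReject`, `meanPerEmotionAccuracy`.
#' @export
runExperiment <- function(store, config = experimentConfig(),
                          subjects = NULL, outDir = NULL) {
  if (is.character(config)) config <- experimentConfig(config)
  stopifnot(inherits(config, "ExperimentConfig"), is(store, "TrialStore"))
  lab <- trialLabels(store)
  if (is.null(subjects)) subjects <- unique(lab$subject)
  perSubject <- lapply(subjects, function(s) {
    crossvalidate(store, s, mode = config$mode, variant = config$variant,
                  k = config$k, seed = config$seed, alpha = config$alpha,
                  beta = config$beta, kappa = config$kappa,
                  shift = config$shift, bandlimit = config$bandlimit,
                  strict = config$strict, shrink = config$shrink,
                  nnIter = config$nnIter)
  })
  names(perSubject) <- subjects
  finals <- vapply(perSubject, function(r) r$finalAccuracy, numeric(1))
  finalsEx <- vapply(perSubject, function(r) r$finalAccuracyExclReject,
                     numeric(1))
  perEmo <- vapply(perSubject, function(r) {
    mean(r$perEmotionAccuracy, na.rm = TRUE)
  }, numeric(1))
  report <- structure(list(
    config = config,
    perSubject = perSubject,
    meanFinalAccuracy = mean(finals),
    meanFinalAccuracyExclReject = mean(finalsEx, na.rm = TRUE),
    meanPerEmotionAccuracy = mean(perEmo, na.rm = TRUE)
  ), class = "ExperimentReport")
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (s in subjects) {
      r <- perSubject[[s]]
      jsonlite::write_json(list(
        subject = s, variant = r$variant, mode = r$mode, seed = r$seed,
        finalAccuracy = r$finalAccuracy,
        finalAccuracyExclReject = r$finalAccuracyExclReject,
        rejectRate = r$rejectRate,
        perEmotionAccuracy = as.list(r$perEmotionAccuracy),
        epochByFold = r$epochByFold
      ), file.path(outDir, paste0("cv_", s, ".json")), auto_unbox = TRUE,
      digits = NA)
      utils::write.csv(r$confusion,
                       file.path(outDir, paste0("confusion_", s, ".csv")))
    }
    jsonlite::write_json(list(
      variant = config$variant, mode = config$mode, seed = config$seed,
      parameters = unclass(config)[c("kappa", "shift", "alpha", "beta",
                                     "bandlimit", "strict", "k", "nnIter")],
      meanFinalAccuracy = report$meanFinalAccuracy,
      meanFinalAccuracyExclReject = report$meanFinalAccuracyExclReject,
      meanPerEmotionAccuracy = report$meanPerEmotionAccuracy
    ), file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.ExperimentReport <- function(x, ...) {
  cat(sprintf("ExperimentReport: %s (%s), %d subject(s)\n",
              x$config$variant, x$config$mode, length(x$perSubject)))
  cat(sprintf("  mean final-decision accuracy %.3f (excl. reject %.3f)\n",
              x$meanFinalAccuracy, x$meanFinalAccuracyExclReject))
  cat(sprintf("  mean one-vs-all accuracy %.3f\n", x$meanPerEmotionAccuracy))
  invisible(x)
}
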