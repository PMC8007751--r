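#' Decompose a trial into overlapping frames
#'
#' Frame k (k = 1..n) starts at `(k - 1) * shift` seconds and ends at
#' `(k - 1) * shift + kappa` seconds, with
#' `n = floor((trialLenS - kappa) / shift) + 1`; every frame fits
#' inside the trial. Sample indices are half-open:
#' `[round(start * fs), round(start * fs) + round(kappa * fs))`,
#' reported 1-based.
#'
#' @param trialLenS trial length in seconds.
#' @param kappa frame length in seconds (<= trial length).
#' @param shift frame shift in seconds (> 0).
#' @param fs sampling rate in Hz.
#' @return A `FramePlan`: list with `kappa`, `shift`, `fs`, `n`,
#'   `start_s`, `end_s`, `startSample` (1-based), `frameLen`.
#' @examples
#' p <- decomposeFrames(8, kappa = 6, shift = 2, fs = 128)
#' cbind(p$start_s, p$end_s)  # (0,6) and (2,8)
#' @export
decomposeFrames <- function(trialLenS, kappa, shift, fs) {
  if (kappa > trialLenS) stop("frame length kappa exceeds the trial length")
  if (shift <= 0) stop("shift must be positive")
  n <- floor((trialLenS - kappa) / shift) + 1L
  start_s <- (seq_len(n) - 1L) * shift
  structure(list(
    kappa = kappa, shift = shift, fs = fs, n = as.integer(n),
    start_s = start_s, end_s = start_s + kappa,
    startSample = as.integer(round(start_s * fs)) + 1L,
    frameLen = as.integer(round(kappa * fs))
  ), class = "FramePlan")
}

#' @export
print.FramePlan <- function(x, ...) {
  cat(sprintf("FramePlan: %d frame(s), kappa = %g s, shift = %g s @ %g Hz\n",
              x$n, x$kappa, x$shift, x$fs))
  for (k in seq_len(min(x$n, 8L))) {
    cat(sprintf("  frame %d: %g-%g s (samples %d..%d)\n", k,
                x$start_s[k], x$end_s[k], x$startSample[k],
                x$startSample[k] + x$frameLen - 1L))
  }
  if (x$n > 8L) cat("  ...\n")
  invisible(x)
}

.frameSamples <- function(plan, k) {
  stopifnot(k >= 1L, k <= plan$n)
  plan$startSample[k]:(plan$startSample[k] + plan$frameLen - 1L)
}
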