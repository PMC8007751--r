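# Internal energy tables shared by ZTWBES, relevance and the
# cross-validated pipelines. All energies are per-trial quantities, so
# they can be computed once per store and reused across CV folds
# without leaking fold information (only the *references* -- means over
# training-fold neutral trials -- are fold-dependent).

# Multiband NGD energies driving the ZTWBES votes: one broadband
# spectrum per segment, summed over the four bands' bins.
# Returns list(full = trials x channels, frame = trials x channels x n).
.ztwbesEnergies <- function(store, ids, plan, bandTable = NULL,
                            mode = "magnitude") {
  if (is.null(bandTable)) bandTable <- bands(store)
  fs <- sampleRate(store)
  nch <- nrow(montage(store))
  full <- matrix(NA_real_, length(ids), nch,
                 dimnames = list(ids, montage(store)$label))
  frame <- array(NA_real_, c(length(ids), nch, plan$n),
                 dimnames = list(ids, montage(store)$label, NULL))
  w <- ztwWindow(plan$frameLen)
  for (i in seq_along(ids)) {
    x <- trialData(store, ids[i])
    full[i, ] <- multibandEnergy(ngdSpectrum(x, fs), bandTable, mode = mode)
    for (k in seq_len(plan$n)) {
      fr <- applyZtw(x[, .frameSamples(plan, k), drop = FALSE], w)
      frame[i, , k] <- multibandEnergy(ngdSpectrum(fr, fs), bandTable,
                                       mode = mode)
    }
  }
  list(full = full, frame = frame)
}

# Per-band energies of whole trials (no zero-time window), used by the
# DFT/NGD baseline variants. Returns trials x channels x bands.
.bandTrialEnergies <- function(store, ids, bandTable = NULL,
                               transform = c("ngd", "dft"),
                               bandlimit = TRUE, mode = "magnitude") {
  transform <- match.arg(transform)
  if (is.null(bandTable)) bandTable <- bands(store)
  fs <- sampleRate(store)
  mon <- montage(store)$label
  E <- array(NA_real_, c(length(ids), length(mon), nrow(bandTable)),
             dimnames = list(ids, mon, bandTable$name))
  tf <- if (transform == "ngd") ngdSpectrum else dftSpectrum
  for (i in seq_along(ids)) {
    x <- trialData(store, ids[i])
    if (bandlimit) {
      for (b in seq_len(nrow(bandTable))) {
        bd <- bandTable[b, , drop = FALSE]
        E[i, , b] <- bandEnergy(tf(bandpass(x, bd, fs), fs), bd, mode = mode)
      }
    } else {
      spec <- tf(x, fs)
      for (b in seq_len(nrow(bandTable))) {
        E[i, , b] <- bandEnergy(spec, bandTable[b, , drop = FALSE],
                                mode = mode)
      }
    }
  }
  E
}

# Per-band energies of trial frames, used by the proposed
# (epoch-based) variant. Returns trials x channels x bands x frames
# (the 4th dimension covers `frames`, defaulting to all frames of the
# plan). Band-limiting filters each analysed frame segment; the
# zero-time window is optional (ztw = TRUE): it concentrates the
# energy statistic on the first samples of the frame, which suits the
# voting argmax but makes threshold statistics high-variance.
.bandFrameEnergies <- function(store, ids, plan, bandTable = NULL,
                               transform = c("ngd", "dft"),
                               bandlimit = TRUE, mode = "magnitude",
                               ztw = FALSE, frames = NULL) {
  transform <- match.arg(transform)
  if (is.null(bandTable)) bandTable <- bands(store)
  if (is.null(frames)) frames <- seq_len(plan$n)
  fs <- sampleRate(store)
  mon <- montage(store)$label
  nb <- nrow(bandTable)
  E <- array(NA_real_, c(length(ids), length(mon), nb, length(frames)),
             dimnames = list(ids, mon, bandTable$name, frames))
  w <- if (ztw) ztwWindow(plan$frameLen) else NULL
  tf <- if (transform == "ngd") ngdSpectrum else dftSpectrum
  for (i in seq_along(ids)) {
    x <- trialData(store, ids[i])
    for (ki in seq_along(frames)) {
      fr0 <- x[, .frameSamples(plan, frames[ki]), drop = FALSE]
      if (bandlimit) {
        for (b in seq_len(nb)) {
          bd <- bandTable[b, , drop = FALSE]
          fr <- bandpass(fr0, bd, fs)
          if (ztw) fr <- applyZtw(fr, w)
          E[i, , b, ki] <- bandEnergy(tf(fr, fs), bd, mode = mode)
        }
      } else {
        fr <- if (ztw) applyZtw(fr0, w) else fr0
        spec <- tf(fr, fs)
        for (b in seq_len(nb)) {
          E[i, , b, ki] <- bandEnergy(spec, bandTable[b, , drop = FALSE],
                                      mode = mode)
        }
      }
    }
  }
  E
}
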