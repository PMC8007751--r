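#' Spectra of EEG segments
#'
#' `dftSpectrum` returns the magnitude of the discrete Fourier
#' transform, \eqn{X[k] = \sum_n x[n] e^{-j 2\pi k n / N}}.
#' `ngdSpectrum` returns the numerator of the group-delay function,
#' \deqn{NGD[k] = Re(X[k]) Re(Y[k]) + Im(X[k]) Im(Y[k]),}
#' where \eqn{Y} is the transform of the time-weighted signal
#' \eqn{n \cdot x[n]}. Keeping only the numerator preserves the
#' formant (spectral-peak) structure while avoiding division by
#' near-zero magnitudes, which is what makes it usable on short
#' zero-time-windowed segments. NGD values may be negative.
#'
#' Both accept a single channel (numeric vector) or a channels x
#' samples matrix; all channels are transformed in one pass.
#'
#' @param x numeric vector or channels x samples matrix; length >= 2.
#' @param fs sampling rate in Hz (bin k maps to `k * fs / N` Hz).
#' @return A `Spectrum` object: list with `values` (channels x N
#'   matrix), `n` (N), `fs` and `kind` (`"dft-magnitude"` or `"ngd"`).
#' @examples
#' s <- dftSpectrum(c(1, 1, 1, 1), fs = 4)
#' s$values  # 4 at bin 0, 0 elsewhere
#' @export
dftSpectrum <- function(x, fs = 128) {
  x <- .asChannelMatrix(x)
  vals <- Mod(t(stats::mvfft(t(x))))
  .Spectrum(vals, fs, "dft-magnitude")
}

#' @rdname dftSpectrum
#' @export
ngdSpectrum <- function(x, fs = 128) {
  x <- .asChannelMatrix(x)
  .Spectrum(.ngdValues(x), fs, "ngd")
}

.asChannelMatrix <- function(x) {
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, nrow = 1L)
  if (!is.matrix(x) || !is.numeric(x)) stop("input must be numeric")
  if (ncol(x) < 2L) stop("input must have at least 2 samples")
  if (!all(is.finite(x))) stop("input contains non-finite samples")
  x
}

.Spectrum <- function(values, fs, kind) {
  structure(list(values = values, n = ncol(values), fs = fs, kind = kind),
            class = "Spectrum")
}

#' @export
print.Spectrum <- function(x, ...) {
  cat(sprintf("Spectrum (%s): %d channel(s) x %d bins, fs = %g Hz\n",
              x$kind, nrow(x$values), x$n, x$fs))
  invisible(x)
}

# NGD for all channels with a single complex FFT per channel:
# pack z = x + i * (n x); by conjugate symmetry of real transforms,
# X = (Z + Conj(Z~)) / 2 and Y = (Z - Conj(Z~)) / (2i), Z~ the
# index-reversed spectrum.
.ngdValues <- function(x) {
  n <- ncol(x)
  w <- 0:(n - 1L)
  z <- stats::mvfft(t(x) + (0+1i) * (t(x) * w))
  idx <- c(1L, n:2L)
  zr <- Conj(z[idx, , drop = FALSE])
  X <- (z + zr) / 2
  Y <- (z - zr) / (0+2i)
  t(Re(X) * Re(Y) + Im(X) * Im(Y))
}

#' Zero-time window
#'
#' Window similar in shape to the frequency response of a zero-frequency
#' resonator: `psi[0] = 0` and `psi[n] = 1 / (4 sin^2(pi n / (2 N)))`
#' for `n = 1..F_l - 1`, with N set equal to the window length `F_l` so
#' the window spans exactly one frame. The zero first sample forces the
#' mean of the windowed signal's spectrum to zero without moving the
#' spectral peaks; the heavy emphasis near n = 0 is what gives the
#' method its instantaneous ("zero-time") character.
#'
#' @param F_l window length in samples (>= 2).
#' @return A `ZtwWindow`: list with `length` and `samples`.
#' @examples
#' ztwWindow(2)$samples  # c(0, 0.5)
#' @export
ztwWindow <- function(F_l) {
  F_l <- as.integer(F_l)
  if (is.na(F_l) || F_l < 2L) stop("window length must be >= 2")
  n <- 1:(F_l - 1L)
  structure(list(length = F_l,
                 samples = c(0, 1 / (4 * sin(pi * n / (2 * F_l))^2))),
            class = "ZtwWindow")
}

#' Apply a zero-time window to a frame
#'
#' Element-wise product of a frame and a [ztwWindow()] of the same
#' length. Because `psi[0] = 0`, the DFT bins of the output always sum
#' to zero.
#'
#' @param frame numeric vector or channels x samples matrix.
#' @param w a `ZtwWindow` whose length matches the frame.
#' @return Windowed frame with the same shape as the input.
#' @export
applyZtw <- function(frame, w) {
  stopifnot(inherits(w, "ZtwWindow"))
  if (is.vector(frame)) {
    if (length(frame) != w$length) {
      stop("frame length must equal the window length")
    }
    return(frame * w$samples)
  }
  if (ncol(frame) != w$length) {
    stop("frame length must equal the window length")
  }
  frame * rep(w$samples, each = nrow(frame))
}

.bandBins <- function(band, n, fs) {
  klo <- round(band$lo * n / fs)
  khi <- round(band$hi * n / fs)
  if (khi > floor(n / 2) || klo < 0) {
    stop(sprintf("band %s..%s Hz outside the spectrum range", band$lo, band$hi))
  }
  if (klo > khi) stop("band maps to an empty bin range")
  klo:khi
}

#' Band energy of a spectrum
#'
#' Bin-index-weighted energy over a band's bins:
#' \eqn{\sum_{k = k_{lo}}^{k_{hi}} k \, |X[k]|} with
#' `k_lo = round(lo N / fs)` and `k_hi = round(hi N / fs)`, inclusive
#' on both edges. The magnitude is taken by default so the energy stays
#' non-negative for NGD spectra too; `mode = "real"` uses the raw
#' values. `multibandEnergy` sums `bandEnergy` over a band table.
#'
#' @param spec a `Spectrum` from [dftSpectrum()] or [ngdSpectrum()].
#' @param band one row of a band table (list/data.frame with `lo`, `hi`).
#' @param mode `"magnitude"` (default) or `"real"`.
#' @return Numeric vector, one energy per channel.
#' @examples
#' s <- dftSpectrum(cos(2 * pi * 10 * (0:127) / 128), fs = 128)
#' bandEnergy(s, defaultBands("alpha"))
#' @export
bandEnergy <- function(spec, band, mode = c("magnitude", "real")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "Spectrum"))
  if (is.data.frame(band)) {
    stopifnot(nrow(band) == 1L)
    band <- as.list(band)
  }
  k <- .bandBins(band, spec$n, spec$fs)
  v <- spec$values[, k + 1L, drop = FALSE]
  if (mode == "magnitude") v <- abs(v)
  as.numeric(v %*% k)
}

#' @rdname bandEnergy
#' @param bandTable data.frame of bands as [defaultBands()].
#' @export
multibandEnergy <- function(spec, bandTable = defaultBands(),
                            mode = c("magnitude", "real")) {
  mode <- match.arg(mode)
  tot <- 0
  for (i in seq_len(nrow(bandTable))) {
    tot <- tot + bandEnergy(spec, bandTable[i, , drop = FALSE], mode = mode)
  }
  tot
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) 4th-order Butterworth band-pass,
#' applied column-vectorised across channels. Coefficients come from
#' [signal::butter()]; the two passes use odd-reflection padding at the
#' edges to suppress start-up transients. The forward-backward scheme
#' squares the magnitude response, so the effective attenuation one
#' band away exceeds 20 dB.
#'
#' @param x numeric vector or channels x samples matrix.
#' @param band list/one-row data.frame with `lo`, `hi` in Hz.
#' @param fs sampling rate in Hz; band edges must lie below `fs / 2`.
#' @param order Butterworth prototype order per pass (default 4).
#' @return Filtered signal, same shape as the input.
#' @examples
#' x <- sin(2 * pi * 10 * (0:511) / 128)
#' y <- bandpass(x, defaultBands("alpha"), fs = 128)
#' @export
bandpass <- function(x, band, fs, order = 4L) {
  if (is.data.frame(band)) {
    stopifnot(nrow(band) == 1L)
    band <- as.list(band)
  }
  if (band$hi >= fs / 2 || band$lo <= 0) {
    stop("band edges must lie strictly inside (0, fs/2)")
  }
  flt <- signal::butter(order, c(band$lo, band$hi) / (fs / 2), type = "pass")
  vec <- is.vector(x)
  xm <- if (vec) matrix(x, ncol = 1L) else t(x)  # samples x channels
  y <- .filtfiltMat(flt$b, flt$a, xm)
  if (vec) as.numeric(y) else t(y)
}

# zero-phase filtering with odd-reflection padding, columns = channels
.filtfiltMat <- function(b, a, x) {
  n <- nrow(x)
  L <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L))
  if (L > 0L) {
    top <- 2 * x[rep(1L, L), , drop = FALSE] - x[(L + 1L):2L, , drop = FALSE]
    bot <- 2 * x[rep(n, L), , drop = FALSE] -
      x[(n - 1L):(n - L), , drop = FALSE]
    xp <- rbind(top, x, bot)
  } else {
    xp <- x
  }
  y <- .iirPassCpp(b, a, xp)
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- .iirPassCpp(b, a, y)
  y <- y[nrow(y):1L, , drop = FALSE]
  y[(L + 1L):(L + n), , drop = FALSE]
}
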