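#' Welch PSD configuration
#'
#' Parameters of the Welch power-spectral-density estimator: segment length
#' M, fractional overlap, taper window, and the frequency band used when a
#' scalar band-power feature is requested.  The window normalization factor
#' U is the mean of the squared window values and is computed internally.
#'
#' @param segmentLength Samples per segment M; \code{NULL} means 2 s worth
#'   of samples, decided when the sampling rate is known.
#' @param overlap Fractional overlap between consecutive segments in [0,1).
#' @param window One of "hamming", "hann", "rectangular".
#' @param band Frequency band (Hz) for scalar band-power extraction.
#' @return List of class \code{"WelchConfig"}.
#' @export
welchConfig <- function(segmentLength = NULL, overlap = 0.5,
                        window = c("hamming", "hann", "rectangular"),
                        band = c(1, 40)) {
  window <- match.arg(window)
  if (overlap < 0 || overlap >= 1) .stopf("overlap must lie in [0,1)")
  if (length(band) != 2 || band[1] >= band[2]) .stopf("band must be [lo, hi] with lo < hi")
  structure(list(segmentLength = segmentLength, overlap = overlap,
                 window = window, band = band),
            class = "WelchConfig")
}

.welchWindow <- function(window, M) {
  n <- 0:(M - 1)
  switch(window,
    rectangular = rep(1, M),
    hamming = 0.54 - 0.46 * cos(2 * pi * n / (M - 1)),
    hann = 0.5 - 0.5 * cos(2 * pi * n / (M - 1)),
    .stopf("unknown window: %s", window))
}

#' Welch power spectral density
#'
#' Estimates the one-sided PSD of a signal by averaging windowed
#' periodograms over (possibly overlapping) segments: the signal is split
#' into L segments of M samples; each is multiplied by the taper w(n) and
#' its periodogram normalized by M times U, where U is the mean squared
#' window value; the PSD is the mean of the L periodograms, scaled to a
#' density so that the integral of PSD over frequency approximates the
#' signal's power (its population variance, for a zero-mean signal).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param cfg A \code{\link{welchConfig}}.
#' @return List with \code{freq} (Hz, 0..fs/2) and \code{psd} (uV^2/Hz),
#'   plus attributes \code{nSegments} and \code{U}.
#' @examples
#' fs <- 500
#' x <- sin(2 * pi * 10 * seq(0, 2, by = 1 / fs))
#' w <- welchPsd(x, fs, welchConfig(segmentLength = 500))
#' w$freq[which.max(w$psd)]  # 10 Hz
#' @export
welchPsd <- function(x, fs, cfg = welchConfig()) {
  N <- length(x)
  if (N == 0) .stopf("zero-length signal")
  if (!all(is.finite(x))) .stopf("signal contains non-finite samples")
  M <- if (is.null(cfg$segmentLength)) min(N, round(2 * fs)) else as.integer(cfg$segmentLength)
  if (M > N) .stopf("segment length M (%d) exceeds signal length (%d)", M, N)
  if (M < 2) .stopf("segment length must be >= 2")
  step <- max(1L, as.integer(round(M * (1 - cfg$overlap))))
  starts <- seq.int(1L, N - M + 1L, by = step)
  L <- length(starts)
  w <- .welchWindow(cfg$window, M)
  U <- mean(w^2)
  seg <- matrix(0, M, L)
  for (j in seq_len(L)) seg[, j] <- x[starts[j]:(starts[j] + M - 1L)] * w
  nf <- M %/% 2 + 1L
  X <- stats::mvfft(seg)[seq_len(nf), , drop = FALSE]
  # mean periodogram, scaled to a one-sided density
  P <- rowMeans(Mod(X)^2) / (M * U)
  dens <- 2 * P / fs
  dens[1] <- dens[1] / 2
  if (M %% 2L == 0L) dens[nf] <- dens[nf] / 2
  structure(list(freq = seq(0, fs / 2, length.out = nf), psd = dens),
            nSegments = L, U = U)
}

#' Integrated band power
#'
#' Trapezoidal integral of a PSD over a frequency band, in signal-power
#' units (uV^2).
#'
#' @param freq Frequency grid (Hz), ascending.
#' @param psd PSD values aligned with \code{freq}.
#' @param band Numeric \code{c(lo, hi)} in Hz.
#' @return Non-negative scalar.
#' @export
bandPower <- function(freq, psd, band) {
  if (length(band) != 2 || band[1] >= band[2]) .stopf("band must be [lo, hi] with lo < hi")
  if (band[1] < min(freq) || band[2] > max(freq))
    .stopf("band [%g, %g] outside frequency grid [%g, %g]",
           band[1], band[2], min(freq), max(freq))
  i <- freq >= band[1] & freq <= band[2]
  f <- freq[i]; p <- psd[i]
  if (length(f) < 2) .stopf("band too narrow for frequency resolution %g Hz", diff(freq[1:2]))
  sum(diff(f) * (p[-length(p)] + p[-1]) / 2)
}
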