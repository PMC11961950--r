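#' Preprocessing configuration
#'
#' Parameters of the preprocessing chain (filtering, re-referencing,
#' artifact rejection, segmentation).  Defaults: 1-40 Hz zero-phase
#' band-pass (covers delta through beta), no mains notch, common-average
#' reference, 150 uV peak-to-peak rejection threshold, 30 s epochs.
#'
#' @param bandpassLow,bandpassHigh Band-pass edges in Hz.
#' @param notch Optional mains notch frequency in Hz (\code{NULL} = none).
#' @param reference "common_average", "as_recorded", or a channel name.
#' @param artifactThreshold Peak-to-peak rejection threshold in uV
#'   (\code{Inf} disables rejection).
#' @param epochLength Epoch length in seconds.
#' @param filterOrder Butterworth magnitude order (roll-off steepness).
#' @return List of class \code{"PreprocessConfig"}.
#' @export
preprocessConfig <- function(bandpassLow = 1, bandpassHigh = 40, notch = NULL,
                             reference = "common_average",
                             artifactThreshold = 150, epochLength = 30,
                             filterOrder = 8) {
  if (bandpassLow <= 0 || bandpassHigh <= bandpassLow)
    .stopf("need 0 < bandpassLow < bandpassHigh")
  if (artifactThreshold <= 0) .stopf("artifactThreshold must be positive")
  if (epochLength <= 0) .stopf("epochLength must be positive")
  structure(list(bandpassLow = bandpassLow, bandpassHigh = bandpassHigh,
                 notch = notch, reference = reference,
                 artifactThreshold = artifactThreshold,
                 epochLength = epochLength, filterOrder = filterOrder),
            class = "PreprocessConfig")
}

# Butterworth power-gain band-pass response at frequencies f (Hz):
# high-pass corner at lo, low-pass corner at hi, order n each.
.butterGain <- function(f, lo, hi, n) {
  g <- 1 / (1 + (f / hi)^(2 * n))
  pos <- f > 0
  g[pos] <- g[pos] / (1 + (lo / f[pos])^(2 * n))
  g[!pos] <- 0
  g
}

# symmetric notch gain, unity away from f0, zero at f0, half-width hw
.notchGain <- function(f, f0, hw = 1, n = 2) {
  r <- ((f - f0) / hw)^(2 * n)
  r / (1 + r)
}

# zero-phase filtering: multiply the spectrum of every channel by a real,
# non-negative gain (applied via FFT, so no recursive edge transients)
.applyGain <- function(dat, fs, gain) {
  n <- ncol(dat)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)                 # fold to [0, fs/2]
  g <- gain(f)
  out <- t(Re(stats::mvfft(stats::mvfft(t(dat)) * g, inverse = TRUE)) / n)
  dimnames(out) <- dimnames(dat)
  out
}

#' Zero-phase band-pass filter
#'
#' Applies a zero-phase band-pass per channel: each channel's spectrum is
#' multiplied by a Butterworth magnitude response of the configured order
#' (high-pass corner at \code{bandpassLow}, low-pass corner at
#' \code{bandpassHigh}).  Working in the frequency domain keeps the filter
#' exactly zero-phase and avoids the long edge transients a recursive
#' implementation leaves on short epochs when the low corner sits near 1
#' Hz.  The DC component is removed whenever the low edge is at or above
#' 0.5 Hz.  An optional notch removes mains interference.
#'
#' @param rec An \linkS4class{EEGRecording}.
#' @param cfg A \code{\link{preprocessConfig}}.
#' @return Filtered \linkS4class{EEGRecording}.
#' @export
bandpassFilter <- function(rec, cfg = preprocessConfig()) {
  stopifnot(is(rec, "EEGRecording"))
  nyq <- samplingRate(rec) / 2
  if (cfg$bandpassHigh >= nyq)
    .stopf("bandpassHigh (%g Hz) must be below Nyquist (%g Hz)", cfg$bandpassHigh, nyq)
  if (!is.null(cfg$notch) && cfg$notch >= nyq)
    .stopf("notch frequency must be below Nyquist")
  gain <- function(f) {
    g <- .butterGain(f, cfg$bandpassLow, cfg$bandpassHigh, cfg$filterOrder)
    if (!is.null(cfg$notch)) g <- g * .notchGain(f, cfg$notch)
    g
  }
  out <- .applyGain(eegData(rec), samplingRate(rec), gain)
  initialize(rec, data = out)
}

#' Re-reference a recording
#'
#' \code{"common_average"} subtracts the instantaneous mean across channels
#' from every channel; \code{"as_recorded"} returns the input unchanged; a
#' channel name subtracts that channel's signal (the named channel becomes
#' all zeros).  Channel-name matching is case-insensitive.
#'
#' @inheritParams bandpassFilter
#' @return Re-referenced \linkS4class{EEGRecording}.
#' @export
rereference <- function(rec, cfg = preprocessConfig()) {
  stopifnot(is(rec, "EEGRecording"))
  ref <- cfg$reference
  dat <- eegData(rec)
  if (identical(ref, "as_recorded")) return(rec)
  if (identical(ref, "common_average")) {
    out <- sweep(dat, 2, colMeans(dat))
  } else {
    i <- match(tolower(ref), tolower(channelNames(rec)))
    if (is.na(i)) .stopf("reference channel not found: %s", ref)
    out <- sweep(dat, 2, dat[i, ])
  }
  dimnames(out) <- dimnames(dat)
  initialize(rec, data = out)
}

#' Segment a recording into epochs
#'
#' Cuts a recording into non-overlapping epochs of \code{epochLength}
#' seconds; a trailing partial epoch is discarded.  Every epoch inherits
#' the recording's label, condition and subject id.
#'
#' @inheritParams bandpassFilter
#' @return An \linkS4class{EpochSet}.
#' @export
segmentEpochs <- function(rec, cfg = preprocessConfig()) {
  stopifnot(is(rec, "EEGRecording"))
  len <- round(cfg$epochLength * samplingRate(rec))
  n <- ncol(eegData(rec))
  k <- n %/% len
  if (k < 1) .stopf("recording (%d samples) shorter than one epoch (%d samples)", n, len)
  eps <- lapply(seq_len(k), function(j)
    eegData(rec)[, ((j - 1) * len + 1):(j * len), drop = FALSE])
  new("EpochSet", epochs = eps,
      labels = rep(stressLabel(rec), k),
      conditions = rep(condition(rec), k),
      subjectIds = rep(subjectId(rec), k),
      rejectedCount = 0L, fs = samplingRate(rec),
      channelNames = channelNames(rec))
}

#' Reject artifact-contaminated epochs
#'
#' Removes every epoch whose peak-to-peak amplitude on any channel exceeds
#' the configured threshold; \code{rejectedCount} is incremented
#' accordingly and label alignment is preserved.  A threshold of \code{Inf}
#' disables rejection.  Rejecting every epoch is an error, never a silent
#' empty set.
#'
#' @param es An \linkS4class{EpochSet}.
#' @param cfg A \code{\link{preprocessConfig}}.
#' @return Screened \linkS4class{EpochSet}.
#' @export
rejectArtifacts <- function(es, cfg = preprocessConfig()) {
  stopifnot(is(es, "EpochSet"))
  thr <- cfg$artifactThreshold
  if (!is.finite(thr)) return(es)
  p2p <- vapply(epochs(es), function(ep)
    max(apply(ep, 1, function(x) max(x) - min(x))), numeric(1))
  keep <- p2p <= thr
  if (!any(keep))
    .stopf("all %d epochs exceed the %g uV artifact threshold", length(keep), thr)
  new("EpochSet", epochs = epochs(es)[keep],
      labels = epochLabels(es)[keep],
      conditions = epochConditions(es)[keep],
      subjectIds = epochSubjects(es)[keep],
      rejectedCount = es@rejectedCount + sum(!keep),
      fs = samplingRate(es), channelNames = channelNames(es))
}

#' Full preprocessing chain for one recording
#'
#' Filter, re-reference, segment and screen one recording in order,
#' returning its clean epochs.
#'
#' @inheritParams bandpassFilter
#' @return An \linkS4class{EpochSet}.
#' @export
preprocessRecording <- function(rec, cfg = preprocessConfig()) {
  rec |> bandpassFilter(cfg) |> rereference(cfg) |>
    segmentEpochs(cfg) |> rejectArtifacts(cfg)
}

#' Combine epoch sets
#'
#' Concatenates epoch sets from multiple recordings (same montage and
#' sampling rate) into one, summing their rejection counts.
#'
#' @param sets List of \linkS4class{EpochSet} objects.
#' @return One \linkS4class{EpochSet}.
#' @export
combineEpochSets <- function(sets) {
  stopifnot(length(sets) > 0, all(vapply(sets, is, TRUE, "EpochSet")))
  fs <- samplingRate(sets[[1]])
  cn <- channelNames(sets[[1]])
  for (s in sets[-1])
    if (samplingRate(s) != fs || !identical(channelNames(s), cn))
      .stopf("epoch sets have incompatible montage or sampling rate")
  new("EpochSet",
      epochs = do.call(c, lapply(sets, epochs)),
      labels = do.call(c, lapply(sets, epochLabels)),
      conditions = do.call(c, lapply(sets, epochConditions)),
      subjectIds = do.call(c, lapply(sets, epochSubjects)),
      rejectedCount = sum(vapply(sets, rejectedCount, 0L)),
      fs = fs, channelNames = cn)
}
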