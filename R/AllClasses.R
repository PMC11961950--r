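#' @import methods
NULL

# Ordered stress states, level 1 (calm) .. level 5 (severe).
.STATE_NAMES <- c("calm", "almost_no_stress", "slight", "moderate", "severe")

# Intervention conditions: "baseline" marks a pre-intervention recording,
# "none" a recording that received no regulation stage at all.
.CONDITIONS <- c("baseline", "joyful", "sorrowful", "exhilarating", "gentle", "none")
.MUSIC_TYPES <- c("joyful", "sorrowful", "exhilarating", "gentle")

# Canonical 31-channel 10-10 montage used throughout.
.CHANNELS_31 <- c(
  "Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
  "FC5", "FC1", "FC2", "FC6", "C5", "C3", "Cz", "C4", "C6",
  "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
  "PO3", "PO4", "O1", "O2")

# EEG frequency bands (Hz) used by the synthesis and feature code.
.BANDS <- list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))

#' Ordered stress-state levels
#'
#' The five ordinal stress states, from level 1 (\code{calm}) to level 5
#' (\code{severe}).  The level/name mapping is a bijection used everywhere a
#' stress label appears.
#'
#' @return Named integer vector of levels 1--5; names are the state names.
#' @examples
#' stressLevels()
#' stressLevel("moderate")
#' @export
stressLevels <- function() {
  structure(1:5, names = .STATE_NAMES)
}

#' @rdname stressLevels
#' @param name Stress-state name (one of \code{names(stressLevels())}).
#' @export
stressLevel <- function(name) {
  lv <- stressLevels()[match(name, .STATE_NAMES)]
  if (anyNA(lv)) stop("unknown stress state: ", paste(name[is.na(lv)], collapse = ", "))
  unname(lv)
}

#' @rdname stressLevels
#' @param level Integer stress level in 1..5.
#' @export
stressName <- function(level) {
  if (any(!level %in% 1:5)) stop("stress level must be in 1..5")
  .STATE_NAMES[level]
}

#' CohortSpec: parameters of the synthetic EEG cohort
#'
#' Holds every knob of the synthetic-data generator: cohort composition,
#' recording geometry, per-band oscillation power, the per-state Fp1-Fp2
#' alpha-power asymmetry targets the generator is calibrated to, noise and
#' artifact parameters, and the per-music-type intervention pull fractions.
#'
#' @slot nPerState Named integer, recordings per stress state.
#' @slot duration Recording length in seconds.
#' @slot fs Sampling rate in Hz.
#' @slot channels Ordered 10-10 channel names; must contain Fp1 and Fp2.
#' @slot seed Integer master seed for the cohort.
#' @slot asymmetryTargets Named numeric, target Fp1-Fp2 alpha-power
#'   difference (uV^2) per state; strictly decreasing with stress level.
#' @slot bandPowers Named numeric, baseline oscillation power (uV^2) per band
#'   (delta/theta/alpha/beta).
#' @slot noiseSd Total additive Gaussian noise standard deviation (uV).
#' @slot noiseCommon Fraction of noise variance carried by a single
#'   scalp-wide background process shared by all channels.
#' @slot artifactRate Blink-artifact events per minute on frontal channels.
#' @slot regionalEffect Fraction of the stress band-modulation applied to
#'   channels outside the frontal pole.
#' @slot alphaSuppression,betaEnhancement Depth of the stress-state
#'   modulation of alpha (suppressed) and beta (enhanced) power at full
#'   stress.
#' @slot subjectSd Log-scale SD of the per-subject global power factor
#'   emulating inter-individual amplitude variability; the factor is a
#'   subject trait, shared by all of a subject's recordings.
#' @slot interventionPull Named numeric in [0,1]: fraction by which each
#'   music type pulls the stress intensity (and with it the asymmetry)
#'   back toward the calm state.
#' @export
setClass("CohortSpec",
  representation(
    nPerState = "integer", duration = "numeric", fs = "numeric",
    channels = "character", seed = "integer",
    asymmetryTargets = "numeric", bandPowers = "numeric",
    noiseSd = "numeric", noiseCommon = "numeric", artifactRate = "numeric",
    regionalEffect = "numeric", alphaSuppression = "numeric",
    betaEnhancement = "numeric", subjectSd = "numeric",
    interventionPull = "numeric"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (!identical(sort(names(object@nPerState)), sort(.STATE_NAMES)) ||
      any(object@nPerState < 1L))
    msg <- c(msg, "nPerState must be a named count >= 1 for each of the five states")
  hi <- max(vapply(.BANDS, max, numeric(1)))
  if (object@fs <= 2 * hi)
    msg <- c(msg, sprintf("fs must exceed twice the highest band edge (%g Hz)", hi))
  cn <- tolower(object@channels)
  if (!all(c("fp1", "fp2") %in% cn))
    msg <- c(msg, "channel list must contain Fp1 and Fp2")
  if (anyDuplicated(cn)) msg <- c(msg, "duplicate channel names")
  at <- object@asymmetryTargets[.STATE_NAMES]
  if (anyNA(at) || any(diff(at) >= 0))
    msg <- c(msg, "asymmetryTargets must be defined for all states and strictly decreasing with stress level")
  if (!identical(sort(names(object@bandPowers)), sort(names(.BANDS))) ||
      any(object@bandPowers < 0))
    msg <- c(msg, "bandPowers must be named non-negative values for delta/theta/alpha/beta")
  if (object@noiseCommon < 0 || object@noiseCommon > 1)
    msg <- c(msg, "noiseCommon must be in [0,1]")
  num <- c(object@duration, object@fs, object@noiseSd, object@artifactRate,
           object@regionalEffect, object@alphaSuppression,
           object@betaEnhancement, object@subjectSd, object@asymmetryTargets,
           object@bandPowers, object@interventionPull)
  if (any(!is.finite(num))) msg <- c(msg, "all numeric parameters must be finite")
  if (object@duration <= 0) msg <- c(msg, "duration must be positive")
  if (!all(.MUSIC_TYPES %in% names(object@interventionPull)) ||
      any(object@interventionPull < 0 | object@interventionPull > 1))
    msg <- c(msg, "interventionPull must map every music type to a fraction in [0,1]")
  if (length(msg)) msg else TRUE
})

#' EEGRecording: one multi-channel EEG recording
#'
#' A channel x sample matrix of microvolt values together with its sampling
#' rate, ordered channel names, ordinal stress label, intervention condition
#' and subject identifier.
#'
#' @slot data Numeric matrix, channels x samples (uV).
#' @slot fs Sampling rate (Hz).
#' @slot channelNames Ordered channel labels, one per row of \code{data}.
#' @slot label Stress-state name (see \code{\link{stressLevels}}).
#' @slot condition One of baseline/joyful/sorrowful/exhilarating/gentle/none.
#' @slot subjectId Opaque subject identifier.
#' @export
setClass("EEGRecording",
  representation(data = "matrix", fs = "numeric", channelNames = "character",
                 label = "character", condition = "character",
                 subjectId = "character"))

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@channelNames))
    msg <- c(msg, "row count of data must equal length(channelNames)")
  if (!all(is.finite(object@data))) msg <- c(msg, "all samples must be finite")
  if (length(object@fs) != 1 || object@fs <= 0) msg <- c(msg, "fs must be a positive scalar")
  if (!object@label %in% .STATE_NAMES) msg <- c(msg, "invalid stress label")
  if (!object@condition %in% .CONDITIONS) msg <- c(msg, "invalid condition")
  if (length(msg)) msg else TRUE
})

#' EpochSet: aligned analysis epochs
#'
#' Fixed-length epochs cut from one or more recordings, with stress labels,
#' conditions and subject identifiers aligned 1:1 with the epochs, plus the
#' running count of epochs removed by artifact screening.
#'
#' @slot epochs List of channel x sample matrices, all the same shape.
#' @slot labels,conditions,subjectIds Character vectors aligned with epochs.
#' @slot rejectedCount Number of epochs removed by artifact screening.
#' @slot fs Sampling rate (Hz).
#' @slot channelNames Ordered channel labels shared by all epochs.
#' @export
setClass("EpochSet",
  representation(epochs = "list", labels = "character", conditions = "character",
                 subjectIds = "character", rejectedCount = "integer",
                 fs = "numeric", channelNames = "character"))

setValidity("EpochSet", function(object) {
  msg <- character()
  n <- length(object@epochs)
  if (length(object@labels) != n || length(object@conditions) != n ||
      length(object@subjectIds) != n)
    msg <- c(msg, "labels, conditions and subjectIds must align 1:1 with epochs")
  if (n > 0) {
    dims <- vapply(object@epochs, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      msg <- c(msg, "all epochs must have the same shape")
    if (dims[1, 1] != length(object@channelNames))
      msg <- c(msg, "epoch rows must match channelNames")
  }
  if (object@rejectedCount < 0L) msg <- c(msg, "rejectedCount must be >= 0")
  if (!all(object@labels %in% .STATE_NAMES)) msg <- c(msg, "invalid stress label")
  if (!all(object@conditions %in% .CONDITIONS)) msg <- c(msg, "invalid condition")
  if (length(msg)) msg else TRUE
})

#' ClassifierReport: evaluation of one model on one region
#'
#' Stores the confusion matrix (rows = true state, columns = predicted) of a
#' fitted stress classifier together with overall accuracy, macro-averaged
#' one-vs-rest precision/recall/F1, the per-class TP/TN/FP/FN counts they
#' are derived from, and the train/test sizes.
#'
#' @slot model Model name (e.g. \code{"ga_bpnn"}).
#' @slot region Brain-region key (Fp/F/C/P/O) or \code{NA}.
#' @slot accuracy,precision,recall,f1 Scalar metrics in [0,1].
#' @slot confusion Square count matrix, rows true, columns predicted.
#' @slot perClass data.frame with one row per class: TP, TN, FP, FN.
#' @slot nTrain,nTest Training/test sample counts.
#' @slot split Evaluation protocol ("holdout" or "loo").
#' @export
setClass("ClassifierReport",
  representation(model = "character", region = "character",
                 accuracy = "numeric", precision = "numeric",
                 recall = "numeric", f1 = "numeric",
                 confusion = "matrix", perClass = "data.frame",
                 nTrain = "integer", nTest = "integer", split = "character"))

setValidity("ClassifierReport", function(object) {
  msg <- character()
  if (nrow(object@confusion) != ncol(object@confusion))
    msg <- c(msg, "confusion matrix must be square")
  if (any(object@confusion < 0)) msg <- c(msg, "confusion entries must be >= 0")
  if (sum(object@confusion) != object@nTest)
    msg <- c(msg, "confusion entries must sum to nTest")
  m <- c(object@accuracy, object@precision, object@recall, object@f1)
  if (any(m < 0 | m > 1)) msg <- c(msg, "metrics must lie in [0,1]")
  if (length(msg)) msg else TRUE
})
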