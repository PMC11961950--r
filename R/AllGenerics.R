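#' Accessors for stressEEG containers
#'
#' Standard accessor generics for the package's S4 containers.  Slot access
#' via \code{@} is discouraged; these are the supported interface.
#'
#' @param x A \linkS4class{EEGRecording}, \linkS4class{EpochSet} or
#'   \linkS4class{ClassifierReport}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("stressLabel", function(x) standardGeneric("stressLabel"))
#' @rdname accessors
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))
#' @rdname accessors
#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))
#' @rdname accessors
#' @export
setGeneric("epochConditions", function(x) standardGeneric("epochConditions"))
#' @rdname accessors
#' @export
setGeneric("epochSubjects", function(x) standardGeneric("epochSubjects"))
#' @rdname accessors
#' @export
setGeneric("rejectedCount", function(x) standardGeneric("rejectedCount"))
#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))
#' @rdname accessors
#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))

#' @rdname accessors
setMethod("eegData", "EEGRecording", function(x) x@data)
#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(x) x@fs)
#' @rdname accessors
setMethod("channelNames", "EEGRecording", function(x) x@channelNames)
#' @rdname accessors
setMethod("channelNames", "EpochSet", function(x) x@channelNames)
#' @rdname accessors
setMethod("stressLabel", "EEGRecording", function(x) x@label)
#' @rdname accessors
setMethod("condition", "EEGRecording", function(x) x@condition)
#' @rdname accessors
setMethod("subjectId", "EEGRecording", function(x) x@subjectId)
#' @rdname accessors
setMethod("epochs", "EpochSet", function(x) x@epochs)
#' @rdname accessors
setMethod("epochLabels", "EpochSet", function(x) x@labels)
#' @rdname accessors
setMethod("epochConditions", "EpochSet", function(x) x@conditions)
#' @rdname accessors
setMethod("epochSubjects", "EpochSet", function(x) x@subjectIds)
#' @rdname accessors
setMethod("rejectedCount", "EpochSet", function(x) x@rejectedCount)
#' @rdname accessors
setMethod("confusionMatrix", "ClassifierReport", function(x) x@confusion)
#' @rdname accessors
setMethod("metrics", "ClassifierReport", function(x)
  c(accuracy = x@accuracy, precision = x@precision,
    recall = x@recall, f1 = x@f1))

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", sum(object@nPerState), "recordings (",
      paste(sprintf("%s=%d", names(object@nPerState), object@nPerState),
            collapse = ", "), ")\n")
  cat(sprintf("  %g s @ %g Hz, %d channels, seed %d\n",
              object@duration, object@fs, length(object@channels), object@seed))
  cat("  asymmetry targets:",
      paste(sprintf("%.4f", object@asymmetryTargets[.STATE_NAMES]), collapse = " "), "\n")
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording %s: %d channels x %d samples @ %g Hz [%s, %s]\n",
              object@subjectId, nrow(object@data), ncol(object@data),
              object@fs, object@label, object@condition))
})

setMethod("show", "EpochSet", function(object) {
  d <- if (length(object@epochs)) dim(object@epochs[[1]]) else c(0L, 0L)
  cat(sprintf("EpochSet: %d epochs of %d channels x %d samples @ %g Hz (%d rejected)\n",
              length(object@epochs), d[1], d[2], object@fs, object@rejectedCount))
})

setMethod("show", "ClassifierReport", function(object) {
  cat(sprintf("ClassifierReport %s / %s [%s]: acc %.3f  prec %.3f  rec %.3f  F1 %.3f (n=%d/%d)\n",
              object@model, object@region, object@split, object@accuracy,
              object@precision, object@recall, object@f1,
              object@nTrain, object@nTest))
})
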