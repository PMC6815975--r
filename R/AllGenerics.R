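#' @name qeegr-accessors
#' @title Accessors for qeegr data containers
#'
#' @description Accessor generics for the package's S4 containers:
#' `sampleRate()` returns the sampling rate in Hz, `eegSamples()` the numeric
#' sample matrix (uV), `animalId()` the animal identifier, `durationMin()` the
#' spanned duration in minutes, and `intervals()` the labelled interval table
#' of a [PatternTimeline-class].
#'
#' @param x a qeegr object.
#' @return The accessed slot value.
NULL

#' @rdname qeegr-accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname qeegr-accessors
#' @export
setGeneric("eegSamples", function(x) standardGeneric("eegSamples"))

#' @rdname qeegr-accessors
#' @export
setGeneric("animalId", function(x) standardGeneric("animalId"))

#' @rdname qeegr-accessors
#' @export
setGeneric("durationMin", function(x) standardGeneric("durationMin"))

#' @rdname qeegr-accessors
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))

#' @rdname qeegr-accessors
#' @export
setMethod("sampleRate", "EEGRecording", function(x) x@fs)

#' @rdname qeegr-accessors
#' @export
setMethod("sampleRate", "EEGSegment", function(x) x@fs)

#' @rdname qeegr-accessors
#' @export
setMethod("sampleRate", "EnvelopeTrace", function(x) x@fs)

#' @rdname qeegr-accessors
#' @export
setMethod("eegSamples", "EEGRecording", function(x) x@samples)

#' @rdname qeegr-accessors
#' @export
setMethod("eegSamples", "EEGSegment", function(x) x@samples)

#' @rdname qeegr-accessors
#' @export
setMethod("animalId", "EEGRecording", function(x) x@animalId)

#' @rdname qeegr-accessors
#' @export
setMethod("animalId", "PatternTimeline", function(x) x@animalId)

#' @rdname qeegr-accessors
#' @export
setMethod("durationMin", "EEGRecording",
          function(x) nrow(x@samples) / x@fs / 60)

#' @rdname qeegr-accessors
#' @export
setMethod("durationMin", "PatternTimeline", function(x) x@durationMin)

#' @rdname qeegr-accessors
#' @export
setMethod("intervals", "PatternTimeline", function(x) x@intervals)

#' Timepoint and artifact flag of a segment
#'
#' @param x an [EEGSegment-class].
#' @return `timepointMin()`: the scheduled timepoint in minutes post-ROSC
#'   (`NA` for the baseline segment); `artifactFlag()`: logical artifact flag.
#' @export
setGeneric("timepointMin", function(x) standardGeneric("timepointMin"))

#' @rdname timepointMin
#' @export
setGeneric("artifactFlag", function(x) standardGeneric("artifactFlag"))

#' @rdname timepointMin
#' @export
setMethod("timepointMin", "EEGSegment", function(x) x@timepointMin)

#' @rdname timepointMin
#' @export
setMethod("artifactFlag", "EEGSegment", function(x) x@artifactFlag)
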