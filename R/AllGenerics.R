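#' Accessor generics
#'
#' Small accessor generics shared by the stimulus, recording and decoder
#' classes. All container slots are reached through these rather than `@`.
#'
#' @param object an object of one of the package's S4 classes.
#' @param ... further arguments for methods.
#' @return The slot value documented on each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object, ...) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object, ...) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("eegData", function(object, ...) standardGeneric("eegData"))

#' @rdname accessors
#' @export
setGeneric("events", function(object, ...) standardGeneric("events"))

#' @rdname accessors
#' @export
setGeneric("discFrequencies", function(object, ...) standardGeneric("discFrequencies"))

#' @rdname accessors
#' @export
setGeneric("missingOnsets", function(object, ...) standardGeneric("missingOnsets"))

#' @rdname accessors
#' @export
setGeneric("frameSequence", function(object, ...) standardGeneric("frameSequence"))

#' @rdname accessors
#' @export
setGeneric("nTrials", function(object, ...) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setGeneric("trialLabels", function(object, ...) standardGeneric("trialLabels"))

#' @rdname accessors
#' @export
setGeneric("nEpochs", function(object, ...) standardGeneric("nEpochs"))

#' @rdname accessors
#' @export
setGeneric("epochArray", function(object, ...) standardGeneric("epochArray"))

#' @rdname accessors
#' @export
setGeneric("epochWindow", function(object, ...) standardGeneric("epochWindow"))

#' @rdname accessors
#' @export
setGeneric("decodingElectrodes", function(object, ...) standardGeneric("decodingElectrodes"))

#' @rdname accessors
#' @export
setGeneric("bayesTable", function(object, ...) standardGeneric("bayesTable"))

#' @rdname accessors
#' @export
setGeneric("svmBank", function(object, ...) standardGeneric("svmBank"))

#' @rdname accessors
#' @export
setGeneric("accuracy", function(object, ...) standardGeneric("accuracy"))

#' @rdname accessors
#' @export
setGeneric("itrBitsPerMin", function(object, ...) standardGeneric("itrBitsPerMin"))

#' @rdname accessors
#' @export
setGeneric("selectedFrequency", function(object, ...) standardGeneric("selectedFrequency"))
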