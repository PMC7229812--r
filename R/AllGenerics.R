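#' @rdname NanoporeReadSet-class
#' @export
setGeneric("readIDs", function(x) standardGeneric("readIDs"))

#' @rdname NanoporeReadSet-class
#' @export
setGeneric("readSequences", function(x) standardGeneric("readSequences"))

#' @rdname NanoporeReadSet-class
#' @export
setGeneric("phredScores", function(x) standardGeneric("phredScores"))

#' @rdname NanoporeReadSet-class
#' @export
setGeneric("readLengths", function(x) standardGeneric("readLengths"))

#' @rdname SplitAlignments-class
#' @export
setGeneric("alignmentSegments", function(x) standardGeneric("alignmentSegments"))

#' @rdname SplitAlignments-class
#' @export
setGeneric("referenceLengths", function(x) standardGeneric("referenceLengths"))

#' @rdname SignalTraceSet-class
#' @export
setGeneric("signalSamples", function(x) standardGeneric("signalSamples"))

#' @rdname SignalTraceSet-class
#' @export
setGeneric("baseIndex", function(x) standardGeneric("baseIndex"))

#' @rdname SignalTraceSet-class
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
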