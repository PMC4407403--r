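#' @rdname BaseMatrix-class
#' @param object,x A package object.
#' @export
setGeneric("baseWeights", function(x) standardGeneric("baseWeights"))

#' @rdname BaseMatrix-class
#' @export
setGeneric("weightScheme", function(x) standardGeneric("weightScheme"))

#' @rdname BaseMatrix-class
#' @export
setGeneric("probeCounts", function(x) standardGeneric("probeCounts"))

#' @rdname CnaAnnotation-class
#' @export
setGeneric("pseudogenes", function(x) standardGeneric("pseudogenes"))

#' @rdname CnaAnnotation-class
#' @export
setGeneric("probes", function(x) standardGeneric("probes"))

#' @rdname ConsensusResult-class
#' @export
setGeneric("consensusMatrix", function(x) standardGeneric("consensusMatrix"))

#' @rdname ConsensusResult-class
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname LoocvResult-class
#' @export
setGeneric("bestM", function(x) standardGeneric("bestM"))

#' @rdname LoocvResult-class
#' @export
setGeneric("bestAccuracy", function(x) standardGeneric("bestAccuracy"))

#' @rdname LoocvResult-class
#' @export
setGeneric("foldAccuracy", function(x) standardGeneric("foldAccuracy"))
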