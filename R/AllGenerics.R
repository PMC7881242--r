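#' @rdname SampleTable-class
#' @param x,object an object.
#' @export
setGeneric("sampleValues", function(x) standardGeneric("sampleValues"))

#' @rdname SampleTable-class
#' @export
setGeneric("sampleDates", function(x) standardGeneric("sampleDates"))

#' @rdname SampleTable-class
#' @export
setGeneric("variableTypes", function(x) standardGeneric("variableTypes"))

#' @rdname SampleTable-class
#' @export
setGeneric("variableNames", function(x) standardGeneric("variableNames"))

#' @rdname DiscreteMatrix-class
#' @param x an object.
#' @export
setGeneric("stateMatrix", function(x) standardGeneric("stateMatrix"))

#' @rdname DiscreteMatrix-class
#' @export
setGeneric("stateThresholds", function(x) standardGeneric("stateThresholds"))

#' @rdname DiscreteMatrix-class
#' @export
setGeneric("degenerateVariables",
           function(x) standardGeneric("degenerateVariables"))

#' @rdname EdgeBlacklist-class
#' @param x an object.
#' @export
setGeneric("blacklistPairs", function(x) standardGeneric("blacklistPairs"))

#' @rdname BayesNet-class
#' @param x an object.
#' @export
setGeneric("netNodes", function(x) standardGeneric("netNodes"))

#' @rdname BayesNet-class
#' @export
setGeneric("netEdges", function(x) standardGeneric("netEdges"))

#' @rdname BayesNet-class
#' @export
setGeneric("netScore", function(x) standardGeneric("netScore"))

#' @rdname BayesNet-class
#' @param node a node name.
#' @export
setGeneric("cpt", function(x, node) standardGeneric("cpt"))

#' @rdname BayesNet-class
#' @export
setGeneric("parentsOf", function(x, node) standardGeneric("parentsOf"))

#' @rdname ConsensusNetwork-class
#' @param x an object.
#' @export
setGeneric("consensusEdges", function(x) standardGeneric("consensusEdges"))

#' @rdname ConsensusNetwork-class
#' @export
setGeneric("edgeSummaries", function(x) standardGeneric("edgeSummaries"))
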