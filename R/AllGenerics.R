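#' Number of nodes / edges of a network object
#'
#' @param x an [Interactome-class] (or [Subnetwork-class]).
#' @return integer count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname nNodes
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' Node symbols of a network object
#' @param x an [Interactome-class].
#' @return character vector of gene symbols.
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' Extract the underlying igraph of a network object
#' @param x an [Interactome-class].
#' @return the `igraph` object.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Per-edge source provenance
#' @param x an [Interactome-class].
#' @return a data.frame with columns `from`, `to`, `sources`
#'   (list column of character vectors).
#' @export
setGeneric("edgeProvenance", function(x) standardGeneric("edgeProvenance"))

#' Score matrix of a CentralityTable
#' @param x a [CentralityTable-class].
#' @return numeric node-by-measure matrix.
#' @export
setGeneric("centralityScores", function(x) standardGeneric("centralityScores"))

#' Consensus hub table of a HubReport
#' @param x a [HubReport-class].
#' @return data.frame with `node`, `nMeasures`, `meanRank`.
#' @export
setGeneric("consensusHubs", function(x) standardGeneric("consensusHubs"))
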