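#' @import methods
#' @importFrom igraph is_igraph gorder gsize is_directed which_loop
#'   edge_attr V E any_multiple
NULL

setOldClass("igraph")

#' Interactome: an undirected simple protein-protein interaction graph
#'
#' Wraps an [igraph::igraph] object holding gene-symbol nodes and
#' undirected, de-duplicated, loop-free interaction edges.  Each edge
#' carries a `sources` attribute recording which input database(s) it came
#' from, so the merged "entire interactome" retains provenance.
#'
#' Objects are normally created by [mergeInteractomes()] or
#' [readInteractome()], not by `new()`.
#'
#' @slot graph an undirected simple `igraph` with vertex attribute `name`
#'   (uppercase gene symbol) and edge attribute `sources`
#'   (pipe-separated source identifiers).
#' @slot log named list of merge diagnostics (`droppedSelfLoops`,
#'   `duplicateRecords`, `nInputRecords`).
#'
#' @seealso [mergeInteractomes()], [networkStats()], [extractNeighborhood()]
#' @export
setClass("Interactome", representation(graph = "igraph", log = "list"))

setValidity("Interactome", function(object) {
    g <- object@graph
    if (!igraph::is_igraph(g)) return("graph slot must hold an igraph object")
    if (igraph::is_directed(g)) return("interactome graph must be undirected")
    if (any(igraph::which_loop(g))) return("interactome must not contain self-loops")
    if (igraph::any_multiple(g)) return("interactome must not contain duplicate edges")
    if (igraph::gorder(g) > 0 && is.null(igraph::V(g)$name))
        return("vertices must be named with gene symbols")
    if (igraph::gsize(g) > 0 && is.null(igraph::edge_attr(g, "sources")))
        return("edges must carry a 'sources' provenance attribute")
    TRUE
})

#' Subnetwork: a seed-anchored induced subgraph of an Interactome
#'
#' The induced subgraph on all nodes within `order` hops (1 or 2) of a
#' seed set, as produced by [extractNeighborhood()].  All parent edges
#' among the selected nodes are retained (induced closure, the
#' neighborhood-selection semantics of Cytoscape).
#'
#' @slot seeds character vector of seed symbols present in the parent graph.
#' @slot order integer neighborhood order (1 or 2).
#' @slot parent single character naming the parent network.
#' @export
setClass("Subnetwork", contains = "Interactome",
    representation(seeds = "character", order = "integer", parent = "character"))

setValidity("Subnetwork", function(object) {
    if (length(object@order) != 1L || !object@order %in% c(1L, 2L))
        return("order must be 1 or 2")
    if (!all(object@seeds %in% igraph::V(object@graph)$name))
        return("all seeds must be nodes of the subnetwork")
    TRUE
})

#' CentralityTable: node-by-measure topological scores
#'
#' One row per node, one column per topological measure among
#' `degree`, `MNC`, `DMNC`, `MCC`, `EPC`, `bottleneck`, `eccentricity`,
#' `closeness`, `radiality`, `betweenness`, `stress`.
#'
#' @slot scores numeric matrix, rownames = node symbols, colnames = measures.
#' @slot params list of scoring parameters actually used
#'   (`epcIterations`, `epcSeed`, `dmncEpsilon`).
#' @seealso [centralityTable()], [rankHubs()]
#' @export
setClass("CentralityTable", representation(scores = "matrix", params = "list"))

setValidity("CentralityTable", function(object) {
    s <- object@scores
    if (!is.numeric(s)) return("scores must be a numeric matrix")
    if (is.null(rownames(s)) || is.null(colnames(s)))
        return("scores must have node rownames and measure colnames")
    if (any(!is.finite(s))) return("all scores must be finite")
    TRUE
})

#' HubReport: per-measure top-k lists and consensus hub ranking
#'
#' @slot topNodes named list, one character vector of top-k nodes per measure.
#' @slot consensus data.frame with columns `node`, `nMeasures`
#'   (number of measures whose top-k contains the node) and `meanRank`
#'   (mean rank over those supporting measures), ordered by `nMeasures`
#'   decreasing, `meanRank` increasing, then symbol.
#' @slot params list with `k` and `minMeasures`.
#' @seealso [rankHubs()]
#' @export
setClass("HubReport",
    representation(topNodes = "list", consensus = "data.frame", params = "list"))

#' SyntheticTruth: planted ground truth of a simulated dataset
#'
#' Every simulator in the package returns the generated data together with
#' one of these objects, so downstream estimators can be checked against
#' the parameters that were planted.
#'
#' @slot plantedHubs character vector of planted hub node labels.
#' @slot plantedLog2FC named numeric vector of planted log2 fold changes.
#' @slot latentRho numeric, latent bivariate-normal correlation (or NA).
#' @slot hazardRatio numeric, planted hazard ratio (or NA).
#' @slot seed integer seed that fully determines the dataset.
#' @slot params list of all remaining generator parameters, plus any
#'   per-record truth (e.g. survival group assignment).
#' @export
setClass("SyntheticTruth", representation(
    plantedHubs = "character", plantedLog2FC = "numeric",
    latentRho = "numeric", hazardRatio = "numeric",
    seed = "integer", params = "list"),
    prototype(plantedHubs = character(), plantedLog2FC = numeric(),
        latentRho = NA_real_, hazardRatio = NA_real_,
        seed = NA_integer_, params = list()))

SyntheticTruth <- function(plantedHubs = character(),
                           plantedLog2FC = numeric(),
                           latentRho = NA_real_, hazardRatio = NA_real_,
                           seed, params = list()) {
    new("SyntheticTruth", plantedHubs = plantedHubs,
        plantedLog2FC = plantedLog2FC, latentRho = latentRho,
        hazardRatio = hazardRatio, seed = as.integer(seed), params = params)
}
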