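#' @describeIn nNodes node count of an Interactome
#' @export
setMethod("nNodes", "Interactome", function(x) igraph::gorder(x@graph))

#' @describeIn nNodes edge count of an Interactome
#' @export
setMethod("nEdges", "Interactome", function(x) igraph::gsize(x@graph))

#' @describeIn nodeNames symbols of an Interactome
#' @export
setMethod("nodeNames", "Interactome", function(x) igraph::V(x@graph)$name)

#' @describeIn asIgraph underlying graph of an Interactome
#' @export
setMethod("asIgraph", "Interactome", function(x) x@graph)

#' @describeIn edgeProvenance provenance of an Interactome
#' @export
setMethod("edgeProvenance", "Interactome", function(x) {
    g <- x@graph
    el <- igraph::as_edgelist(g)
    src <- if (igraph::gsize(g) > 0) strsplit(igraph::E(g)$sources, "|", fixed = TRUE)
           else list()
    data.frame(from = el[, 1], to = el[, 2], sources = I(src))
})

setMethod("show", "Interactome", function(object) {
    cat(sprintf("%s with %d nodes and %d edges\n", class(object),
        nNodes(object), nEdges(object)))
    srcs <- sort(unique(unlist(strsplit(
        igraph::E(object@graph)$sources %||% character(), "|", fixed = TRUE))))
    if (length(srcs)) cat("sources:", paste(srcs, collapse = ", "), "\n")
    if (length(object@log))
        cat(sprintf("merge log: %d input records, %d self-loops dropped, %d duplicates collapsed\n",
            object@log$nInputRecords %||% NA_integer_,
            object@log$droppedSelfLoops %||% 0L,
            object@log$duplicateRecords %||% 0L))
    invisible(object)
})

setMethod("show", "Subnetwork", function(object) {
    cat(sprintf("Subnetwork (order %d) with %d nodes and %d edges; %d seeds; parent: %s\n",
        object@order, nNodes(object), nEdges(object),
        length(object@seeds), object@parent))
    invisible(object)
})

#' @describeIn centralityScores score matrix accessor
#' @export
setMethod("centralityScores", "CentralityTable", function(x) x@scores)

#' @describeIn nodeNames nodes of a CentralityTable
#' @export
setMethod("nodeNames", "CentralityTable", function(x) rownames(x@scores))

setMethod("show", "CentralityTable", function(object) {
    cat(sprintf("CentralityTable: %d nodes x %d measures (%s)\n",
        nrow(object@scores), ncol(object@scores),
        paste(colnames(object@scores), collapse = ", ")))
    cat(sprintf("EPC: K = %d, seed = %s; DMNC epsilon = %.2f\n",
        object@params$epcIterations %||% NA_integer_,
        format(object@params$epcSeed %||% NA), object@params$dmncEpsilon %||% NA_real_))
    invisible(object)
})

#' @describeIn consensusHubs consensus table accessor
#' @export
setMethod("consensusHubs", "HubReport", function(x) x@consensus)

setMethod("show", "HubReport", function(object) {
    cat(sprintf("HubReport (k = %d, minMeasures = %d): %d consensus hubs\n",
        object@params$k, object@params$minMeasures, nrow(object@consensus)))
    if (nrow(object@consensus))
        print(utils::head(object@consensus, 10))
    invisible(object)
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth (seed", object@seed, ")\n")
    if (length(object@plantedHubs))
        cat("  planted hubs:", paste(object@plantedHubs, collapse = ", "), "\n")
    if (length(object@plantedLog2FC))
        cat("  planted log2FC on", length(object@plantedLog2FC), "genes\n")
    if (!is.na(object@latentRho)) cat("  latent rho:", object@latentRho, "\n")
    if (!is.na(object@hazardRatio)) cat("  hazard ratio:", object@hazardRatio, "\n")
    invisible(object)
})
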