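#' Consensus hub ranking across the eleven measures
#'
#' Each measure contributes a top-`k` node list (scores descending,
#' except eccentricity which is ranked ascending: a small maximum
#' distance means central, a large one peripheral; ties broken by
#' symbol).  A node is a consensus hub when it appears in the top-`k` of
#' at least `minMeasures` measures; consensus hubs are ordered by the
#' number of supporting measures (decreasing), mean rank across the
#' supporting measures (increasing), then symbol.  The combination rule (top-k
#' membership count) is this package's construction and its parameters
#' are recorded in the report.
#'
#' @param t a [CentralityTable-class].
#' @param k per-measure list depth (default 10; clamped to the node
#'   count with a warning).
#' @param minMeasures minimum supporting measures (default 6).
#' @return a [HubReport-class].
#' @examples
#' sim <- simulateInteractomeSources(60, nPlantedHubs = 1, seed = 11)
#' ct <- centralityTable(sim$union, epcIterations = 100, epcSeed = 11)
#' consensusHubs(rankHubs(ct))[1, ]
#' @export
rankHubs <- function(t, k = 10L, minMeasures = 6L) {
    stopifnot(is(t, "CentralityTable"), k >= 1)
    s <- t@scores
    n <- nrow(s)
    measures <- colnames(s)
    if (minMeasures > length(measures))
        stop("minMeasures exceeds the number of measures", call. = FALSE)
    if (k > n) {
        warning("k = ", k, " exceeds node count ", n, "; clamped", call. = FALSE)
        k <- n
    }
    nodes <- rownames(s)
    rankMat <- matrix(0L, n, length(measures),
        dimnames = list(nodes, measures))
    topNodes <- vector("list", length(measures))
    names(topNodes) <- measures
    for (msr in measures) {
        key <- if (msr == "eccentricity") s[, msr] else -s[, msr]
        ord <- order(key, nodes)
        rankMat[ord, msr] <- seq_len(n)
        topNodes[[msr]] <- nodes[ord[seq_len(k)]]
    }
    support <- table(unlist(topNodes))
    inTop <- names(support)
    # mean rank over the measures whose top-k actually contains the node
    meanRank <- vapply(inTop, function(nd)
        mean(rankMat[nd, vapply(topNodes, function(tn) nd %in% tn, TRUE)]),
        numeric(1))
    cons <- data.frame(node = inTop,
        nMeasures = as.integer(support),
        meanRank = meanRank,
        row.names = NULL, stringsAsFactors = FALSE)
    cons <- cons[cons$nMeasures >= minMeasures, , drop = FALSE]
    cons <- cons[order(-cons$nMeasures, cons$meanRank, cons$node), ,
        drop = FALSE]
    rownames(cons) <- NULL
    new("HubReport", topNodes = topNodes, consensus = cons,
        params = list(k = as.integer(k), minMeasures = as.integer(minMeasures)))
}

#' Write a HubReport as JSON
#'
#' @param x a [HubReport-class].
#' @param file path.
#' @return the path, invisibly.
#' @export
writeHubReport <- function(x, file) {
    stopifnot(is(x, "HubReport"))
    jsonlite::write_json(list(params = x@params, topNodes = x@topNodes,
        consensus = x@consensus), file, auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    invisible(file)
}
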