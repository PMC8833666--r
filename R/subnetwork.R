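#' Map gene symbols onto an interactome
#'
#' Partitions an input gene list by membership in the network's node set,
#' preserving the original order.  Duplicate occurrences are kept (one
#' entry per occurrence) and flagged.
#'
#' @param g an [Interactome-class] (or igraph).
#' @param genes character vector of symbols (normalized before lookup).
#' @return list with `present`, `absent` (both in input order) and
#'   `duplicated` (symbols occurring more than once in the input).
#' @export
mapNodes <- function(g, genes) {
    graph <- if (is(g, "Interactome")) g@graph else g
    genes <- normalizeSymbols(genes)
    inNet <- genes %in% igraph::V(graph)$name
    dup <- unique(genes[duplicated(genes)])
    if (length(dup))
        message("duplicate input symbol(s): ", paste(dup, collapse = ", "))
    list(present = genes[inNet], absent = genes[!inNet], duplicated = dup)
}

#' Extract a seed neighborhood subnetwork
#'
#' Selects all nodes within `order` hops (1 or 2) of any seed and returns
#' the induced subgraph: every parent edge whose two endpoints are both
#' selected is retained (Cytoscape neighborhood-selection semantics).
#' Seeds absent from the parent network are dropped with a message; the
#' extraction fails only if no seed maps.
#'
#' @param g an [Interactome-class].
#' @param seeds character vector of seed symbols (duplicates collapse).
#' @param order neighborhood order, 1 or 2.
#' @param parent label for the parent network recorded in the result.
#' @return a [Subnetwork-class].
#' @examples
#' recs <- parseInteractions(c("A\tB", "B\tC", "C\tD"), dialect = "tsv2")
#' g <- mergeInteractomes(list(recs))
#' extractNeighborhood(g, "A", order = 2)
#' @export
extractNeighborhood <- function(g, seeds, order = 1L, parent = "network") {
    stopifnot(is(g, "Interactome"))
    order <- as.integer(order)
    if (!order %in% c(1L, 2L)) stop("order must be 1 or 2", call. = FALSE)
    mapped <- mapNodes(g, unique(seeds))
    if (length(mapped$absent))
        message(length(mapped$absent), " seed(s) absent from parent network: ",
            paste(mapped$absent, collapse = ", "))
    if (!length(mapped$present))
        stop("no seed is present in the parent network", call. = FALSE)
    hood <- igraph::ego(g@graph, order = order, nodes = mapped$present)
    sel <- unique(names(unlist(hood)))
    sub <- igraph::induced_subgraph(g@graph, sel)
    new("Subnetwork", graph = sub, log = g@log,
        seeds = mapped$present, order = order, parent = parent)
}

#' Shortest connection paths from a hub to each seed
#'
#' For every seed, enumerates all distinct shortest paths from the hub
#' with at most `maxLen` edges, within the given subnetwork.  Direct
#' interactions are length-1 paths; paths are sorted lexicographically by
#' their intermediate node labels.  Seeds unreachable within `maxLen`
#' (and the hub itself, if listed as a seed) get an empty path list.
#'
#' @param sn a [Subnetwork-class] (or [Interactome-class]).
#' @param hub hub symbol (must be a node).
#' @param seeds character vector of seed symbols.
#' @param maxLen maximum path length in edges (default 2).
#' @return named list (one element per seed) of character-vector paths,
#'   each starting at the hub and ending at the seed.
#' @export
seedHubPaths <- function(sn, hub, seeds, maxLen = 2L) {
    graph <- if (is(sn, "Interactome")) sn@graph else sn
    hub <- normalizeSymbols(hub)
    seeds <- unique(normalizeSymbols(seeds))
    if (!hub %in% igraph::V(graph)$name)
        stop("hub '", hub, "' is not a node of the subnetwork", call. = FALSE)
    out <- lapply(seeds, function(s) {
        if (!s %in% igraph::V(graph)$name || s == hub) return(list())
        sp <- suppressWarnings(igraph::all_shortest_paths(graph, from = hub,
            to = s))$vpaths
        paths <- lapply(sp, function(p) igraph::V(graph)$name[p])
        paths <- Filter(function(p) length(p) - 1L <= maxLen, paths)
        if (!length(paths)) return(list())
        inner <- vapply(paths, function(p)
            paste(p[-c(1L, length(p))], collapse = "\r"), "")
        paths[order(inner)]
    })
    stats::setNames(out, seeds)
}
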