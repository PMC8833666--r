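# Eleven-measure topological hub scoring (CytoHubba conventions).
# The geodesic measures run on a single hand-written breadth-first
# Brandes pass so that the exhaustive path-enumeration oracle used in
# the tests stays an independent route.

asGraph <- function(g) {
    graph <- if (is(g, "Interactome")) g@graph else g
    stopifnot(igraph::is_igraph(graph))
    if (is.null(igraph::V(graph)$name))
        igraph::V(graph)$name <- as.character(seq_len(igraph::gorder(graph)))
    graph
}

adjacencyList <- function(graph) {
    lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
}

#' Node degree scores
#'
#' @param g an [Interactome-class], [Subnetwork-class] or igraph.
#' @return named numeric vector of neighbor counts.
#' @export
degreeScores <- function(g) {
    graph <- asGraph(g)
    stats::setNames(as.numeric(igraph::degree(graph, loops = FALSE)),
        igraph::V(graph)$name)
}

#' Maximum Neighborhood Component (MNC) and its density-scaled variant
#' (DMNC)
#'
#' For each node v, the subgraph induced on v's neighbors (v excluded) is
#' decomposed into connected components.  `MNC(v)` is the size of the
#' largest component; `DMNC(v) = E_c / V_c^epsilon` for that component
#' (largest size, then most edges on ties), or 0 when `MNC(v) <= 1`.
#'
#' @param g network object or igraph.
#' @param epsilon DMNC exponent (> 0; conventional default 1.7).
#' @return list with named numeric vectors `MNC` and `DMNC`.
#' @export
mncDmncScores <- function(g, epsilon = 1.7) {
    stopifnot(epsilon > 0)
    graph <- asGraph(g)
    n <- igraph::gorder(graph)
    mnc <- numeric(n); dmnc <- numeric(n)
    nbrs <- igraph::as_adj_list(graph, mode = "all")
    for (v in seq_len(n)) {
        nb <- nbrs[[v]]
        if (length(nb) == 0L) next
        sub <- igraph::induced_subgraph(graph, nb)
        comp <- igraph::components(sub)
        best <- max(comp$csize)
        mnc[v] <- best
        if (best > 1L) {
            cand <- which(comp$csize == best)
            ec <- vapply(cand, function(ci)
                igraph::gsize(igraph::induced_subgraph(sub,
                    which(comp$membership == ci))), numeric(1))
            dmnc[v] <- max(ec) / best^epsilon
        }
    }
    ns <- igraph::V(graph)$name
    list(MNC = stats::setNames(mnc, ns), DMNC = stats::setNames(dmnc, ns))
}

#' Maximal Clique Centrality (MCC)
#'
#' `MCC(v)` is the sum of `(|C| - 1)!` over all maximal cliques C
#' containing v.  Maximal cliques of size 2 (bare edges) contribute 1
#' each, so a node whose neighborhood is edgeless scores its degree;
#' isolated nodes score 0.  Maximal cliques are enumerated with igraph;
#' enumeration is refused above a configurable budget because clique
#' counts can grow exponentially.
#'
#' @param g network object or igraph.
#' @param maxNodes node-count budget (default 10000).
#' @param maxCliques maximal-clique-count budget (default 2e6).
#' @return named numeric vector.
#' @export
mccScores <- function(g, maxNodes = 10000L, maxCliques = 2e6) {
    graph <- asGraph(g)
    n <- igraph::gorder(graph)
    if (n > maxNodes)
        stop("MCC clique enumeration refused for ", n, " nodes (budget ",
            maxNodes, "); decompose the network first", call. = FALSE)
    scores <- numeric(n)
    if (igraph::gsize(graph) > 0) {
        nCl <- igraph::count_max_cliques(graph, min = 2)
        if (nCl > maxCliques)
            stop("MCC aborted: ", nCl, " maximal cliques exceed budget ",
                format(maxCliques), "; decompose the network first",
                call. = FALSE)
        cliques <- igraph::max_cliques(graph, min = 2)
        for (cl in cliques) {
            idx <- as.integer(cl)
            scores[idx] <- scores[idx] + factorial(length(idx) - 1L)
        }
    }
    stats::setNames(scores, igraph::V(graph)$name)
}

#' Edge Percolated Component (EPC)
#'
#' Monte-Carlo percolation score: in each of `iterations` realizations an
#' independent Uniform(0,1) weight is drawn per edge together with one
#' Uniform(0,1) threshold, edges with weight >= threshold are retained,
#' and each node contributes the size of its connected component in the
#' retained graph.  `EPC(v)` is the mean contribution; an isolated node
#' scores exactly 1.  The seed is recorded by [centralityTable()] and the
#' same seed reproduces the scores exactly.  The per-node Monte-Carlo
#' standard error is attached as attribute `se`.
#'
#' @param g network object or igraph.
#' @param iterations number of percolation realizations (>= 1).
#' @param seed integer RNG seed.
#' @return named numeric vector.
#' @export
epcScores <- function(g, iterations = 1000L, seed = 1L) {
    stopifnot(iterations >= 1)
    graph <- asGraph(g)
    n <- igraph::gorder(graph)
    el <- igraph::as_edgelist(graph, names = FALSE)
    m <- nrow(el)
    acc <- numeric(n)
    accSq <- numeric(n)
    withSeed(seed, {
        for (it in seq_len(iterations)) {
            th <- stats::runif(1)
            keep <- if (m > 0) stats::runif(m) >= th else logical(0)
            parent <- seq_len(n)
            if (any(keep)) {
                ka <- el[keep, 1]; kb <- el[keep, 2]
                for (e in seq_along(ka)) {
                    ra <- ka[e]
                    while (parent[ra] != ra) {
                        parent[ra] <- parent[parent[ra]]; ra <- parent[ra]
                    }
                    rb <- kb[e]
                    while (parent[rb] != rb) {
                        parent[rb] <- parent[parent[rb]]; rb <- parent[rb]
                    }
                    if (ra != rb) parent[rb] <- ra
                }
                # pointer jumping to full root resolution
                repeat {
                    p2 <- parent[parent]
                    if (identical(p2, parent)) break
                    parent <- p2
                }
            }
            sizes <- tabulate(parent, nbins = n)
            contrib <- sizes[parent]
            acc <- acc + contrib
            accSq <- accSq + contrib^2
        }
    })
    out <- stats::setNames(acc / iterations, igraph::V(graph)$name)
    # Monte-Carlo standard error of each mean, for convergence checks
    if (iterations > 1) {
        v <- pmax(0, (accSq - acc^2 / iterations) / (iterations - 1))
        attr(out, "se") <- stats::setNames(sqrt(v / iterations), names(out))
    }
    out
}

#' BottleNeck (BN) scores
#'
#' For every source node s one breadth-first shortest-path tree is built
#' with deterministic tie-breaking (each node's tree parent is its
#' lexicographically smallest predecessor), making the score reproducible.
#' A node v (not the root) collects one point from source s when more
#' than a quarter of the nodes reachable from s lie strictly below v in
#' the tree; `BN(v)` is the total over all sources.
#'
#' @param g network object or igraph.
#' @return named numeric vector (integer-valued).
#' @export
bottleneckScores <- function(g) {
    graph <- asGraph(g)
    n <- igraph::gorder(graph)
    labels <- igraph::V(graph)$name
    lexRank <- rank(labels, ties.method = "first")
    adj <- adjacencyList(graph)
    bn <- numeric(n)
    for (s in seq_len(n)) {
        dist <- rep.int(-1L, n); dist[s] <- 0L
        queue <- integer(n); queue[1] <- s; qh <- 1L; qt <- 1L
        orderVisited <- integer(0)
        while (qh <= qt) {
            v <- queue[qh]; qh <- qh + 1L
            orderVisited <- c(orderVisited, v)
            for (w in adj[[v]]) if (dist[w] < 0L) {
                dist[w] <- dist[v] + 1L
                qt <- qt + 1L; queue[qt] <- w
            }
        }
        reach <- which(dist >= 0L)
        nS <- length(reach)
        if (nS <= 1L) next
        parent <- rep.int(0L, n)
        for (w in reach) {
            if (w == s) next
            cand <- adj[[w]][dist[adj[[w]]] == dist[w] - 1L]
            parent[w] <- cand[which.min(lexRank[cand])]
        }
        size <- rep.int(0L, n); size[reach] <- 1L
        for (w in rev(orderVisited)) {
            if (w == s) next
            size[parent[w]] <- size[parent[w]] + size[w]
        }
        scorers <- reach[reach != s & (size[reach] - 1L) > nS / 4]
        bn[scorers] <- bn[scorers] + 1
    }
    stats::setNames(bn, labels)
}

#' Shortest-path centrality family
#'
#' One Brandes-style breadth-first pass per source computes, for every
#' node over its connected component:
#'
#' * `closeness`: harmonic closeness, `sum_w 1/d(v, w)` (unreachable
#'   nodes contribute 0);
#' * `eccentricity`: maximum distance to a reachable node;
#' * `radiality`: `sum_w (diam + 1 - d(v, w)) / (n_c - 1)` with `diam`
#'   the component diameter and `n_c` the component size;
#' * `betweenness`: `sum_{s != v != t} sigma_st(v) / sigma_st` over
#'   unordered pairs, endpoints excluded;
#' * `stress`: the number of shortest paths on which v is interior.
#'
#' Isolated nodes score 0 on all five measures.
#'
#' @param g network object or igraph.
#' @return list of five named numeric vectors: `closeness`,
#'   `eccentricity`, `radiality`, `betweenness`, `stress`.
#' @export
geodesicScores <- function(g) {
    graph <- asGraph(g)
    n <- igraph::gorder(graph)
    labels <- igraph::V(graph)$name
    adj <- adjacencyList(graph)
    closeness <- numeric(n); ecc <- numeric(n)
    betw <- numeric(n); stressv <- numeric(n)
    distSum <- numeric(n)

    for (s in seq_len(n)) {
        dist <- rep.int(-1L, n); dist[s] <- 0L
        sigma <- numeric(n); sigma[s] <- 1
        preds <- vector("list", n)
        queue <- integer(n); queue[1] <- s; qh <- 1L; qt <- 1L
        visited <- integer(0)
        while (qh <= qt) {
            v <- queue[qh]; qh <- qh + 1L
            visited <- c(visited, v)
            for (w in adj[[v]]) {
                if (dist[w] < 0L) {
                    dist[w] <- dist[v] + 1L
                    qt <- qt + 1L; queue[qt] <- w
                }
                if (dist[w] == dist[v] + 1L) {
                    sigma[w] <- sigma[w] + sigma[v]
                    preds[[w]] <- c(preds[[w]], v)
                }
            }
        }
        reach <- which(dist > 0L)
        if (length(reach)) {
            closeness[s] <- sum(1 / dist[reach])
            ecc[s] <- max(dist[reach])
            distSum[s] <- sum(dist[reach])
        }
        deltaB <- numeric(n); deltaS <- numeric(n)
        for (w in rev(visited)) {
            for (v in preds[[w]]) {
                deltaB[v] <- deltaB[v] + sigma[v] / sigma[w] * (1 + deltaB[w])
                deltaS[v] <- deltaS[v] + sigma[v] * (1 + deltaS[w] / sigma[w])
            }
            if (w != s) {
                betw[w] <- betw[w] + deltaB[w]
                stressv[w] <- stressv[w] + deltaS[w]
            }
        }
    }
    betw <- betw / 2
    stressv <- stressv / 2

    comp <- igraph::components(graph)
    radial <- numeric(n)
    for (ci in seq_len(comp$no)) {
        members <- which(comp$membership == ci)
        nc <- length(members)
        if (nc < 2L) next
        diam <- max(ecc[members])
        radial[members] <- ((diam + 1) * (nc - 1) - distSum[members]) / (nc - 1)
    }

    list(closeness = stats::setNames(closeness, labels),
        eccentricity = stats::setNames(ecc, labels),
        radiality = stats::setNames(radial, labels),
        betweenness = stats::setNames(betw, labels),
        stress = stats::setNames(stressv, labels))
}

#' Score all eleven topological measures
#'
#' Runs [degreeScores()], [mncDmncScores()], [mccScores()],
#' [epcScores()], [bottleneckScores()] and [geodesicScores()] and
#' assembles the node-by-measure matrix used for consensus hub ranking.
#' All scoring parameters are recorded in the result.
#'
#' @param g an [Interactome-class], [Subnetwork-class] or igraph.
#' @param epcIterations EPC Monte-Carlo realizations (default 1000).
#' @param epcSeed EPC RNG seed.
#' @param dmncEpsilon DMNC exponent (default 1.7).
#' @param mccMaxNodes,mccMaxCliques MCC enumeration budgets.
#' @return a [CentralityTable-class] with measures `degree`, `MNC`,
#'   `DMNC`, `MCC`, `EPC`, `bottleneck`, `eccentricity`, `closeness`,
#'   `radiality`, `betweenness`, `stress`.
#' @examples
#' sim <- simulateInteractomeSources(50, nPlantedHubs = 1, seed = 5)
#' ct <- centralityTable(sim$union, epcIterations = 100, epcSeed = 5)
#' @export
centralityTable <- function(g, epcIterations = 1000L, epcSeed = 1L,
                            dmncEpsilon = 1.7, mccMaxNodes = 10000L,
                            mccMaxCliques = 2e6) {
    graph <- asGraph(g)
    md <- mncDmncScores(graph, epsilon = dmncEpsilon)
    geo <- geodesicScores(graph)
    scores <- cbind(
        degree = degreeScores(graph),
        MNC = md$MNC, DMNC = md$DMNC,
        MCC = mccScores(graph, maxNodes = mccMaxNodes,
            maxCliques = mccMaxCliques),
        EPC = epcScores(graph, iterations = epcIterations, seed = epcSeed),
        bottleneck = bottleneckScores(graph),
        eccentricity = geo$eccentricity, closeness = geo$closeness,
        radiality = geo$radiality, betweenness = geo$betweenness,
        stress = geo$stress)
    new("CentralityTable", scores = scores,
        params = list(epcIterations = as.integer(epcIterations),
            epcSeed = as.integer(epcSeed), dmncEpsilon = dmncEpsilon))
}

#' Write a CentralityTable as TSV
#'
#' @param x a [CentralityTable-class].
#' @param file path.
#' @return the path, invisibly.
#' @export
writeCentralityTable <- function(x, file) {
    stopifnot(is(x, "CentralityTable"))
    df <- data.frame(node = rownames(x@scores), x@scores,
        check.names = FALSE, row.names = NULL)
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}
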