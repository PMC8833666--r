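# Independent brute-force oracles for the centrality suite.  These
# deliberately avoid the package's Brandes BFS code path: distances come
# from igraph, shortest-path counts from a distance-layered recursion,
# and betweenness/stress from an explicit triple loop over (s, v, t).

# named igraph from "A-B" edge strings
edgeGraph <- function(...) {
    pairs <- do.call(rbind, strsplit(c(...), "-", fixed = TRUE))
    igraph::graph_from_edgelist(pairs, directed = FALSE)
}

randomGraph <- function(n, p, seed, connected = FALSE) {
    withr::with_seed(seed, {
        repeat {
            g <- igraph::sample_gnp(n, p)
            if (!connected || igraph::is_connected(g)) break
        }
        igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
        g
    })
}

# number of shortest s->t paths from the distance matrix, by recursion
# over predecessors (layered DAG)
pathCountMatrix <- function(g) {
    n <- igraph::gorder(g)
    d <- igraph::distances(g)
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
    sigma <- matrix(0, n, n)
    diag(sigma) <- 1
    for (s in seq_len(n)) {
        reach <- which(is.finite(d[s, ]))
        for (t in reach[order(d[s, reach])]) {
            if (t == s) next
            preds <- which(adj[, t] & d[s, ] == d[s, t] - 1)
            sigma[s, t] <- sum(sigma[s, preds])
        }
    }
    list(d = d, sigma = sigma)
}

oracleGeodesics <- function(g) {
    n <- igraph::gorder(g)
    pc <- pathCountMatrix(g)
    d <- pc$d; sigma <- pc$sigma
    closeness <- numeric(n); ecc <- numeric(n); radial <- numeric(n)
    betw <- numeric(n); stressv <- numeric(n)
    for (v in seq_len(n)) {
        dv <- d[v, ]; dv[v] <- Inf
        reach <- which(is.finite(dv))
        if (length(reach)) {
            closeness[v] <- sum(1 / dv[reach])
            ecc[v] <- max(dv[reach])
        }
    }
    comp <- igraph::components(g)
    for (ci in seq_len(comp$no)) {
        mem <- which(comp$membership == ci)
        if (length(mem) < 2) next
        diam <- max(d[mem, mem])
        for (v in mem)
            radial[v] <- sum(diam + 1 - d[v, setdiff(mem, v)]) / (length(mem) - 1)
    }
    for (v in seq_len(n)) {
        for (s in seq_len(n)) {
            if (s == v) next
            for (t in seq_len(n)) {
                if (t <= s || t == v) next
                if (!is.finite(d[s, t])) next
                if (d[s, v] + d[v, t] == d[s, t]) {
                    onPath <- sigma[s, v] * sigma[v, t]
                    betw[v] <- betw[v] + onPath / sigma[s, t]
                    stressv[v] <- stressv[v] + onPath
                }
            }
        }
    }
    nm <- igraph::V(g)$name
    list(closeness = stats::setNames(closeness, nm),
        eccentricity = stats::setNames(ecc, nm),
        radiality = stats::setNames(radial, nm),
        betweenness = stats::setNames(betw, nm),
        stress = stats::setNames(stressv, nm))
}

# all-subset maximal clique enumeration (n <= 12), factorial weights
oracleMCC <- function(g) {
    n <- igraph::gorder(g)
    stopifnot(n <= 12)
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
    scores <- numeric(n)
    isClique <- function(idx) {
        if (length(idx) < 2) return(FALSE)
        all(adj[t(utils::combn(idx, 2))])
    }
    for (code in seq_len(2^n - 1)) {
        idx <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
        if (!isClique(idx)) next
        # maximal iff no outside vertex adjacent to all members
        outside <- setdiff(seq_len(n), idx)
        maximal <- !any(vapply(outside, function(o) all(adj[o, idx]), TRUE))
        if (maximal)
            scores[idx] <- scores[idx] + factorial(length(idx) - 1)
    }
    stats::setNames(scores, igraph::V(g)$name)
}

# two-group log-rank chi-square from first principles (no survival pkg)
oracleLogrank <- function(time, event, group) {
    lv <- sort(unique(group))
    stopifnot(length(lv) == 2)
    ts <- sort(unique(time[event == 1]))
    O1 <- 0; E1 <- 0; V <- 0
    for (t in ts) {
        atRisk <- time >= t
        n <- sum(atRisk)
        n1 <- sum(atRisk & group == lv[1])
        dTot <- sum(time == t & event == 1)
        d1 <- sum(time == t & event == 1 & group == lv[1])
        O1 <- O1 + d1
        E1 <- E1 + dTot * n1 / n
        if (n > 1)
            V <- V + dTot * (n1 / n) * (1 - n1 / n) * (n - dTot) / (n - 1)
    }
    (O1 - E1)^2 / V
}

# local unordered-pair key (mirror of the package-internal convention)
pk <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
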