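test_that("degree scores count neighbors, including isolated nodes", {
    star <- edgeGraph("C-L1", "C-L2", "C-L3", "C-L4")
    expect_equal(degreeScores(star)[["C"]], 4)
    g <- igraph::add_vertices(star, 1)
    igraph::V(g)$name[6] <- "ISO"
    expect_equal(degreeScores(g)[["ISO"]], 0)
})

test_that("MNC/DMNC match closed forms on star, triangle and K5", {
    star <- edgeGraph("C-L1", "C-L2", "C-L3", "C-L4")
    md <- mncDmncScores(star)
    expect_equal(md$MNC[["C"]], 1)
    expect_equal(md$DMNC[["C"]], 0)
    tri <- igraph::make_full_graph(3)
    mdt <- mncDmncScores(tri)
    expect_equal(unname(mdt$MNC), rep(2, 3))
    expect_equal(unname(mdt$DMNC), rep(1 / 2^1.7, 3))
    k5 <- igraph::make_full_graph(5)
    mdk <- mncDmncScores(k5)
    expect_equal(unname(mdk$MNC), rep(4, 5))
    expect_equal(unname(mdk$DMNC), rep(6 / 4^1.7, 5))
    # the exponent is configurable
    expect_equal(unname(mncDmncScores(tri, epsilon = 1)$DMNC), rep(0.5, 3))
})

test_that("MCC matches hand-enumerated clique structures", {
    tri <- igraph::make_full_graph(3)
    expect_equal(unname(mccScores(tri)), rep(2, 3))
    star <- edgeGraph("C-L1", "C-L2", "C-L3", "C-L4")
    expect_equal(mccScores(star)[["C"]], 4)
    # two triangles sharing edge b-c
    bowtie <- edgeGraph("A-B", "A-C", "B-C", "B-D", "C-D")
    mcc <- mccScores(bowtie)
    expect_equal(mcc[["B"]], 4)
    expect_equal(mcc[["A"]], 2)
})

test_that("MCC equals the all-subset clique oracle on small random graphs", {
    for (sd in 1:10) {
        g <- randomGraph(10, 0.35, seed = sd)
        expect_equal(mccScores(g), oracleMCC(g))
    }
})

test_that("MCC enumeration refuses oversized problems with advice", {
    g <- randomGraph(30, 0.2, seed = 1)
    expect_error(mccScores(g, maxNodes = 10), "decompose")
})

test_that("EPC matches its analytic expectation and is seed-stable", {
    pair <- edgeGraph("A-B")
    e <- epcScores(pair, iterations = 20000, seed = 3)
    expect_lt(abs(e[["A"]] - 1.5), 3 * attr(e, "se")[["A"]])
    # isolated nodes score exactly 1
    iso <- igraph::add_vertices(pair, 1)
    igraph::V(iso)$name[3] <- "Z"
    expect_equal(epcScores(iso, iterations = 50, seed = 1)[["Z"]], 1)
    # reproducibility
    expect_identical(epcScores(pair, iterations = 200, seed = 7),
        epcScores(pair, iterations = 200, seed = 7))
    expect_false(identical(epcScores(pair, iterations = 200, seed = 7),
        epcScores(pair, iterations = 200, seed = 8)))
})

test_that("EPC respects vertex symmetry on complete graphs", {
    k5 <- igraph::make_full_graph(5)
    e <- epcScores(k5, iterations = 10000, seed = 5)
    se <- attr(e, "se")
    for (i in 2:5)
        expect_lt(abs(e[[i]] - e[[1]]), 3 * sqrt(se[[i]]^2 + se[[1]]^2))
})

test_that("BottleNeck reproduces hand-traced trees", {
    star <- edgeGraph("C-L1", "C-L2", "C-L3", "C-L4")
    bn <- bottleneckScores(star)
    expect_equal(bn[["C"]], 4)
    expect_equal(unname(bn[c("L1", "L2", "L3", "L4")]), rep(0, 4))
    k4 <- igraph::make_full_graph(4)
    expect_equal(unname(bottleneckScores(k4)), rep(0, 4))
    p3 <- edgeGraph("A-B", "B-C")
    expect_equal(bottleneckScores(p3)[["B"]], 2)
})

test_that("geodesic measures match hand enumeration on P3 and the star", {
    p3 <- edgeGraph("A-B", "B-C")
    geo <- geodesicScores(p3)
    expect_equal(geo$closeness[["B"]], 2)
    expect_equal(geo$eccentricity[["B"]], 1)
    expect_equal(geo$radiality[["B"]], 2)
    expect_equal(geo$radiality[["A"]], 1.5)
    expect_equal(geo$betweenness[["B"]], 1)
    expect_equal(geo$stress[["B"]], 1)
    star <- edgeGraph("C-L1", "C-L2", "C-L3", "C-L4")
    gs <- geodesicScores(star)
    expect_equal(gs$betweenness[["C"]], 6)
    expect_equal(gs$stress[["C"]], 6)
})

test_that("isolated nodes take the degenerate-component convention", {
    g <- igraph::add_vertices(edgeGraph("A-B"), 1)
    igraph::V(g)$name[3] <- "ISO"
    geo <- geodesicScores(g)
    for (msr in names(geo)) expect_equal(geo[[msr]][["ISO"]], 0)
})

test_that("geodesic measures equal the exhaustive oracle on random graphs", {
    for (sd in 1:15) {
        n <- 8 + (sd %% 5) * 3
        g <- randomGraph(n, 0.25, seed = sd)
        got <- geodesicScores(g)
        want <- oracleGeodesics(g)
        for (msr in names(want)) expect_equal(got[[msr]], want[[msr]])
        # independent cross-check of betweenness against igraph
        expect_equal(unname(got$betweenness),
            unname(igraph::betweenness(g, directed = FALSE)))
    }
})

test_that("vertex-transitive graphs score uniformly on deterministic measures", {
    for (g in list(igraph::make_ring(7), igraph::make_full_graph(5))) {
        igraph::V(g)$name <- LETTERS[seq_len(igraph::gorder(g))]
        ct <- centralityTable(g, epcIterations = 50, epcSeed = 1)
        s <- centralityScores(ct)
        det <- setdiff(colnames(s), "EPC")
        for (msr in det)
            expect_equal(unname(s[, msr]), rep(s[1, msr], nrow(s)))
    }
})

test_that("adding an edge never decreases degree or MCC of its endpoints", {
    for (sd in 1:5) {
        g <- randomGraph(9, 0.3, seed = sd)
        nonEdges <- which(!(igraph::as_adjacency_matrix(g, sparse = FALSE) > 0) &
            upper.tri(matrix(TRUE, 9, 9)), arr.ind = TRUE)
        if (nrow(nonEdges) == 0) next
        ij <- nonEdges[1, ]
        g2 <- igraph::add_edges(g, igraph::V(g)$name[ij])
        for (f in list(degreeScores, mccScores)) {
            before <- f(g); after <- f(g2)
            expect_gte(after[[ij[1]]], before[[ij[1]]])
            expect_gte(after[[ij[2]]], before[[ij[2]]])
        }
    }
})

test_that("the centrality table assembles all eleven measures with metadata", {
    g <- randomGraph(12, 0.3, seed = 4)
    ct <- centralityTable(g, epcIterations = 100, epcSeed = 9)
    s <- centralityScores(ct)
    expect_equal(colnames(s), c("degree", "MNC", "DMNC", "MCC", "EPC",
        "bottleneck", "eccentricity", "closeness", "radiality",
        "betweenness", "stress"))
    expect_true(all(is.finite(s)))
    expect_true(all(s >= 0))
    # integer-valued measures
    for (msr in c("degree", "MNC", "bottleneck", "stress"))
        expect_equal(s[, msr], round(s[, msr]))
    expect_equal(ct@params$epcSeed, 9L)
    f <- tempfile(fileext = ".tsv")
    writeCentralityTable(ct, f)
    back <- utils::read.delim(f, check.names = FALSE)
    expect_equal(back$node, rownames(s))
    expect_equal(back$MCC, unname(s[, "MCC"]))
})

test_that("hub ranking honors directions, ties and clamping", {
    g <- randomGraph(12, 0.3, seed = 6)
    ct <- centralityTable(g, epcIterations = 100, epcSeed = 6)
    expect_warning(hr <- rankHubs(ct, k = 50, minMeasures = 1), "clamped")
    expect_equal(hr@params$k, 12L)
    # k = n: every node in every top list; consensus ranks all nodes
    expect_equal(nrow(consensusHubs(hr)), 12)
    expect_setequal(hr@topNodes$degree, rownames(centralityScores(ct)))
    # eccentricity list is ascending in score
    s <- centralityScores(ct)
    eccTop <- rankHubs(ct, k = 3, minMeasures = 1)@topNodes$eccentricity
    expect_true(all(s[eccTop, "eccentricity"] <= sort(s[, "eccentricity"])[3]))
    expect_error(rankHubs(ct, k = 5, minMeasures = 20), "minMeasures")
})

test_that("hub ranking is deterministic on degenerate tie-heavy graphs", {
    # disjoint edges: every measure is constant across nodes
    g <- edgeGraph("A-B", "C-D", "E-F", "G-H", "I-J", "K-L")
    ct1 <- centralityTable(g, epcIterations = 100, epcSeed = 1)
    ct2 <- centralityTable(g, epcIterations = 100, epcSeed = 1)
    expect_identical(rankHubs(ct1)@consensus, rankHubs(ct2)@consensus)
    expect_identical(rankHubs(ct1)@topNodes, rankHubs(ct2)@topNodes)
})

test_that("a planted hub is recovered by the consensus ranking", {
    sim <- simulateInteractomeSources(100, nPlantedHubs = 1, seed = 5)
    hub <- sim$truth@plantedHubs
    ct <- centralityTable(sim$union, epcIterations = 500, epcSeed = 5)
    hr <- rankHubs(ct, k = 10, minMeasures = 6)
    supp <- sum(vapply(hr@topNodes, function(tn) hub %in% tn, TRUE))
    expect_gte(supp, 9)
    expect_equal(consensusHubs(hr)$node[1], hub)
})
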