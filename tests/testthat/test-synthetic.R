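test_that("interactome sources are byte-identical under the same seed", {
    d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
    s1 <- simulateInteractomeSources(30, nSources = 2, overlapFrac = 0.3,
        nPlantedHubs = 1, seed = 7, dir = d1)
    s2 <- simulateInteractomeSources(30, nSources = 2, overlapFrac = 0.3,
        nPlantedHubs = 1, seed = 7, dir = d2)
    for (i in seq_along(s1$files))
        expect_identical(readLines(s1$files[i]), readLines(s2$files[i]))
    expect_identical(s1$sources, s2$sources)
})

test_that("the union of emitted sources equals the generated graph", {
    sim <- simulateInteractomeSources(40, nSources = 3, overlapFrac = 0.25,
        nPlantedHubs = 1, seed = 3)
    prov <- edgeProvenance(sim$union)
    expect_setequal(pk(prov$from, prov$to), sim$truth@params$unionEdges)
    # every edge carries >= 1 source; the requested fraction carries >= 2
    nSrc <- lengths(prov$sources)
    expect_true(all(nSrc >= 1))
    expect_equal(sum(nSrc >= 2), round(0.25 * nEdges(sim$union)))
})

test_that("a single source with no overlap is its own union", {
    sim <- simulateInteractomeSources(20, nSources = 1, overlapFrac = 0,
        nPlantedHubs = 0, seed = 1)
    expect_length(sim$sources, 1)
    expect_setequal(pk(sim$sources[[1]]$geneA, sim$sources[[1]]$geneB),
        sim$truth@params$unionEdges)
})

test_that("planted hubs dominate the degree distribution", {
    for (sd in c(1, 9)) {
        sim <- simulateInteractomeSources(100, nPlantedHubs = 1, seed = sd)
        deg <- degreeScores(sim$union)
        hub <- sim$truth@plantedHubs
        expect_identical(names(which.max(deg)), hub)
        # contract: hub wired to at least 20% of all nodes
        expect_gte(deg[[hub]], 0.2 * 100)
    }
})

test_that("interactome generator rejects bad parameters", {
    expect_error(simulateInteractomeSources(30, overlapFrac = 1.2, seed = 1),
        "overlapFrac")
    expect_error(simulateInteractomeSources(5, seed = 1))
})

test_that("noiseless expression reproduces planted ratios exactly", {
    sim <- simulateExpressionStudy(10, c(tumor = 4, normal = 4),
        plantedLog2FC = c(GENE0001 = 2), noiseSD = 0, refGroup = "normal",
        seed = 2)
    prof <- meanProfiles(sim$se)
    expect_equal(prof["GENE0001", "tumor"] / prof["GENE0001", "normal"], 4)
    expect_equal(prof["GENE0002", "tumor"] / prof["GENE0002", "normal"], 1)
    expect_true(all(SummarizedExperiment::assay(sim$se) > 0))
    expect_error(simulateExpressionStudy(10, c(a = 2, b = 2),
        noiseSD = -1, refGroup = "b", seed = 1), "noiseSD")
})

test_that("the fold-change estimator is unbiased under noise", {
    ests <- vapply(1:200, function(i) {
        sim <- simulateExpressionStudy(1, c(case = 20, ref = 20),
            plantedLog2FC = c(GENE0001 = 2), noiseSD = 0.25,
            refGroup = "ref", seed = i)
        prof <- meanProfiles(sim$se)
        log2(prof[1, "case"] / prof[1, "ref"])
    }, numeric(1))
    expect_lt(abs(mean(ests) - 2), 0.05)
})

test_that("Cq tables recover planted fold changes through 2^-ddCq", {
    noiseless <- simulateCqTable(c("G1", "G2"), c(case = 3, ref = 3),
        plantedLog2FC = c(G1 = 3), jitterSD = 0, refGroup = "ref", seed = 4)
    fc <- ddcqFoldChange(noiseless$cq, "case", "ref")
    expect_equal(fc$foldChange[fc$gene == "G1"], 8)
    expect_equal(fc$foldChange[fc$gene == "G2"], 1)
    # housekeeping Cq constant across groups when jitter = 0
    hk <- noiseless$cq[noiseless$cq$gene == "ACTB", ]
    expect_equal(length(unique(hk$cq)), 1)
    # jittered pipeline: median recovered fold change within 5% of planted
    fcs <- vapply(1:150, function(i) {
        s <- simulateCqTable("G1", c(case = 3, ref = 3), c(G1 = 3),
            jitterSD = 0.1, refGroup = "ref", seed = i)
        ddcqFoldChange(s$cq, "case", "ref")$foldChange
    }, numeric(1))
    expect_lt(abs(stats::median(fcs) - 8) / 8, 0.05)
    expect_error(simulateCqTable(character(0), c(a = 1, b = 1),
        refGroup = "b", seed = 1), "non-empty")
})

test_that("perfectly correlated latents give identical marker intensities", {
    sim <- simulateIHCCohort(50, latentRho = 1, gradeShift = 0, seed = 5)
    expect_identical(sim$cohort$SELENOS, sim$cohort$VCP)
})

test_that("independent latents give near-zero ordinal correlation", {
    sim <- simulateIHCCohort(10000, latentRho = 0, gradeShift = 0, seed = 6)
    expect_lt(abs(stats::cor(sim$cohort$SELENOS, sim$cohort$VCP)), 0.05)
})

test_that("ordinal correlation is attenuated relative to the latent one", {
    rs <- vapply(1:300, function(i)
        stats::cor(simulateIHCCohort(30, latentRho = 0.85, gradeShift = 0,
            seed = i)$cohort[, c("SELENOS", "VCP")])[1, 2], numeric(1))
    expect_gte(mean(rs), 0.6)
    expect_lte(mean(rs), 0.85)
})

test_that("IHC cohort structure and parameter validation hold", {
    sim <- simulateIHCCohort(30, seed = 1)
    expect_true(all(sim$cohort$grade %in% c(2, 3)))
    expect_true(all(sim$cohort$SELENOS %in% 1:3))
    expect_true(all(sim$cohort$ki67 >= 0 & sim$cohort$ki67 <= 100))
    expect_error(simulateIHCCohort(30, thresholds = c(1, 1), seed = 1),
        "increasing")
    expect_error(simulateIHCCohort(30, latentRho = 2, seed = 1))
})

test_that("survival cohorts honor censoring and the planted hazard ratio", {
    noCens <- simulateSurvivalCohort(100, censorRate = 0, seed = 7)
    expect_true(all(noCens$surv$event == 1))
    expect_true(all(noCens$surv$time > 0))
    # recovered split equals generator truth
    grp <- combinedSplit(noCens$surv, c("SELENOS", "VCP"))
    expect_identical(as.character(grp),
        as.character(noCens$truth@params$group))
    # planted HR 2.5: high group dies earlier in nearly all cohorts
    worse <- vapply(1:100, function(i) {
        s <- simulateSurvivalCohort(200, hazardRatio = 2.5, censorRate = 0,
            seed = i)
        g <- s$truth@params$group
        stats::median(s$surv$time[g == "high"]) <
            stats::median(s$surv$time[g == "low"])
    }, logical(1))
    expect_gte(mean(worse), 0.95)
    expect_error(simulateSurvivalCohort(100, censorRate = 1, seed = 1),
        "censorRate")
    expect_error(simulateSurvivalCohort(100, hazardRatio = -1, seed = 1),
        "hazardRatio")
})

test_that("a null hazard ratio leaves groups exchangeable", {
    ps <- vapply(1:60, function(i) {
        s <- simulateSurvivalCohort(100, hazardRatio = 1, censorRate = 0,
            seed = i)
        kmLogrank(s$surv, s$truth@params$group)$pValue
    }, numeric(1))
    # p-values roughly uniform under the null: no excess of small p
    expect_lt(mean(ps < 0.05), 0.15)
    expect_gt(mean(ps), 0.3)
})

test_that("all simulators are reproducible from their seed", {
    expect_identical(simulateExpressionStudy(5, c(a = 2, b = 2),
            refGroup = "b", seed = 9),
        simulateExpressionStudy(5, c(a = 2, b = 2), refGroup = "b", seed = 9))
    expect_identical(simulateCqTable("G1", c(a = 2, b = 2), refGroup = "b",
            seed = 9)$cq,
        simulateCqTable("G1", c(a = 2, b = 2), refGroup = "b", seed = 9)$cq)
    expect_identical(simulateIHCCohort(20, seed = 9)$cohort,
        simulateIHCCohort(20, seed = 9)$cohort)
    expect_identical(simulateSurvivalCohort(20, seed = 9)$surv,
        simulateSurvivalCohort(20, seed = 9)$surv)
})
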