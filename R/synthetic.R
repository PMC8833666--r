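#' Simulate a multi-source interactome with planted hubs
#'
#' Generates one scale-free (preferential-attachment) backbone graph,
#' strengthens `nPlantedHubs` randomly chosen nodes by wiring each of
#' them to a fraction `hubWireFrac` of all nodes (at least 20%), and
#' splits the union edge set across `nSources` overlapping "database"
#' sources: every edge is assigned to one primary source and a fraction
#' `overlapFrac` of edges to a second source, emulating the partial
#' redundancy of real interaction databases.
#'
#' The union of the emitted sources equals the generated graph exactly,
#' and the returned [SyntheticTruth-class] records the hub identities and
#' the exact union edge set, so merge and hub-recovery code can be tested
#' against ground truth.  A given `seed` reproduces the output exactly.
#'
#' @param nNodes number of nodes (>= 10).
#' @param attach edges attached per new node in the preferential-attachment
#'   backbone (>= 1).
#' @param nSources number of sources to emit (>= 1).
#' @param overlapFrac fraction of edges assigned to a second source, in
#'   \[0, 1\].
#' @param nPlantedHubs number of planted hub nodes.
#' @param hubWireFrac fraction of all nodes each hub is wired to,
#'   uniformly at random (default 0.4; must be >= 0.2).
#' @param seed integer RNG seed (fully determines the output).
#' @param dir optional directory; when given, each source is written as a
#'   two-column TSV (`<dir>/source<i>.tsv`) and the truth as
#'   `<dir>/truth.json`.
#' @return list with `sources` (named list of record data.frames with
#'   columns `geneA`, `geneB`, `source`), `union` (an
#'   [Interactome-class]), `truth` (a [SyntheticTruth-class]) and
#'   `files` (paths written, or NULL).
#' @examples
#' sim <- simulateInteractomeSources(50, nSources = 2, overlapFrac = 0.3,
#'     nPlantedHubs = 1, seed = 7)
#' sim$truth@plantedHubs
#' @export
simulateInteractomeSources <- function(nNodes, attach = 2L, nSources = 3L,
                                       overlapFrac = 0.2, nPlantedHubs = 1L,
                                       hubWireFrac = 0.4, seed, dir = NULL) {
    stopifnot(nNodes >= 10, attach >= 1, nSources >= 1, nPlantedHubs >= 0)
    assertScalarNumber(overlapFrac, "overlapFrac", 0, 1)
    assertScalarNumber(hubWireFrac, "hubWireFrac", 0.2, 1)

    res <- withSeed(seed, {
        g <- igraph::sample_pa(nNodes, m = attach, directed = FALSE)
        # labels are shuffled so that label order carries no information
        # about backbone attachment order (symbol tie-breaks downstream
        # must not systematically favor or punish any node class)
        labels <- sample(sprintf("G%04d", seq_len(nNodes)))
        igraph::V(g)$name <- labels
        hubs <- character(0)
        if (nPlantedHubs > 0) {
            hubs <- sort(sample(labels, nPlantedHubs))
            nWire <- ceiling(hubWireFrac * nNodes)
            for (h in hubs) {
                targets <- sample(setdiff(labels, h), nWire)
                g <- igraph::add_edges(g, rbind(h, targets))
            }
        }
        g <- igraph::simplify(g)

        el <- igraph::as_edgelist(g)
        # canonical edge order: sorted unordered-pair keys
        key <- pairKey(el[, 1], el[, 2])
        ord <- order(key)
        el <- el[ord, , drop = FALSE]; key <- key[ord]
        nE <- nrow(el)

        primary <- sample.int(nSources, nE, replace = TRUE)
        secondary <- rep(NA_integer_, nE)
        nOverlap <- round(overlapFrac * nE)
        if (nOverlap > 0) {
            if (nSources < 2)
                warning("overlapFrac > 0 requires >= 2 sources; no overlap generated",
                    call. = FALSE)
            else {
                ovIdx <- sample.int(nE, nOverlap)
                secondary[ovIdx] <- vapply(primary[ovIdx], function(p)
                    sample(setdiff(seq_len(nSources), p), 1L), 1L)
            }
        }
        list(el = el, key = key, primary = primary, secondary = secondary,
            hubs = hubs)
    })

    srcNames <- sprintf("source%d", seq_len(nSources))
    sources <- stats::setNames(lapply(seq_len(nSources), function(s) {
        inS <- res$primary == s | (!is.na(res$secondary) & res$secondary == s)
        data.frame(geneA = res$el[inS, 1], geneB = res$el[inS, 2],
            source = srcNames[s], stringsAsFactors = FALSE)
    }), srcNames)

    union <- mergeInteractomes(sources)
    truth <- SyntheticTruth(plantedHubs = res$hubs, seed = seed,
        params = list(nNodes = nNodes, attach = attach, nSources = nSources,
            overlapFrac = overlapFrac, nPlantedHubs = nPlantedHubs,
            hubWireFrac = hubWireFrac, unionEdges = res$key))

    files <- NULL
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        files <- file.path(dir, c(paste0(srcNames, ".tsv"), "truth.json"))
        for (s in seq_len(nSources))
            utils::write.table(sources[[s]][, c("geneA", "geneB")], files[s],
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
        jsonlite::write_json(list(plantedHubs = truth@plantedHubs,
            seed = seed, params = truth@params),
            files[length(files)], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    list(sources = sources, union = union, truth = truth, files = files)
}

#' Simulate a gene-by-sample expression study with planted fold changes
#'
#' Emits a linear-scale, strictly positive expression matrix for one
#' reference group and one or more case groups.  Each gene has a
#' log-uniform baseline; planted genes are multiplied by
#' `2^log2fc` in every non-reference sample; multiplicative log-normal
#' noise with standard deviation `noiseSD` (log2 units) is applied to
#' every value, so with `noiseSD = 0` the ratio of group means recovers
#' the planted fold change exactly.
#'
#' @param nGenes number of genes (ignored when `genes` is given).
#' @param groupSizes named integer vector of samples per group,
#'   e.g. `c(TNBC = 20, normal = 20)`.
#' @param plantedLog2FC named numeric vector of planted log2 fold changes;
#'   names must be a subset of the gene symbols.
#' @param noiseSD multiplicative noise standard deviation in log2 units
#'   (>= 0).
#' @param refGroup name of the reference group (must be in
#'   `names(groupSizes)`).
#' @param genes optional explicit gene symbols (default `GENE0001`, ...).
#' @param seed integer RNG seed.
#' @return list with `se` (a
#'   [SummarizedExperiment::SummarizedExperiment-class] with assay
#'   `exprs` and column data `group`) and `truth`
#'   (a [SyntheticTruth-class]).
#' @examples
#' sim <- simulateExpressionStudy(50, c(tumor = 5, normal = 5),
#'     plantedLog2FC = c(GENE0001 = 2), noiseSD = 0, refGroup = "normal",
#'     seed = 1)
#' @export
simulateExpressionStudy <- function(nGenes, groupSizes,
                                    plantedLog2FC = numeric(),
                                    noiseSD = 0.25, refGroup, genes = NULL,
                                    seed) {
    stopifnot(is.numeric(groupSizes), !is.null(names(groupSizes)),
        all(groupSizes >= 1))
    if (!refGroup %in% names(groupSizes))
        stop("refGroup '", refGroup, "' is not among the group names", call. = FALSE)
    if (!is.numeric(noiseSD) || noiseSD < 0)
        stop("noiseSD must be a non-negative number", call. = FALSE)
    if (is.null(genes)) genes <- sprintf("GENE%04d", seq_len(nGenes))
    nGenes <- length(genes)
    if (length(plantedLog2FC) &&
        !all(names(plantedLog2FC) %in% genes))
        stop("planted genes must be a subset of the gene set", call. = FALSE)

    groups <- rep(names(groupSizes), times = groupSizes)
    samples <- unlist(lapply(names(groupSizes), function(gr)
        sprintf("%s_%02d", gr, seq_len(groupSizes[[gr]]))))
    lfc <- stats::setNames(numeric(nGenes), genes)
    lfc[names(plantedLog2FC)] <- plantedLog2FC

    mat <- withSeed(seed, {
        baseline <- 2^stats::runif(nGenes, 3, 8)
        isCase <- groups != refGroup
        m <- baseline * 2^(outer(lfc, as.numeric(isCase)))
        if (noiseSD > 0)
            m <- m * exp(matrix(stats::rnorm(nGenes * length(groups),
                sd = noiseSD * log(2)), nGenes))
        m
    })
    dimnames(mat) <- list(genes, samples)

    truth <- SyntheticTruth(plantedLog2FC = plantedLog2FC, seed = seed,
        params = list(groupSizes = as.list(groupSizes), refGroup = refGroup,
            noiseSD = noiseSD))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = mat),
        colData = S4Vectors::DataFrame(group = groups, row.names = samples),
        metadata = list(truth = truth))
    list(se = se, truth = truth)
}

#' Simulate a qPCR Cq table with planted fold changes
#'
#' Emits replicate quantification-cycle (Cq) values for target genes and
#' a housekeeping gene over case/reference samples.  Target Cq values in
#' case samples are lowered by the planted log2 fold change (one cycle
#' per doubling), the housekeeping gene is constant across groups up to
#' jitter, so the downstream `2^-ddCq` pipeline recovers the planted
#' fold change (exactly when `jitterSD = 0`).
#'
#' @param genes character vector of target gene symbols (non-empty).
#' @param groupSizes named integer vector of samples per group.
#' @param plantedLog2FC named numeric vector (subset of `genes`).
#' @param replicates technical replicates per (sample, gene) (>= 1).
#' @param jitterSD Cq measurement noise standard deviation in cycles.
#' @param refGroup reference group name.
#' @param housekeeping housekeeping gene symbol (default `"ACTB"`,
#'   beta-actin); added to the emitted table automatically.
#' @param seed integer RNG seed.
#' @return list with `cq` (data.frame `sample`, `group`, `gene`,
#'   `replicate`, `cq`, with attribute `housekeeping`) and `truth`.
#' @examples
#' sim <- simulateCqTable(c("SELENOS", "GPX1"), c(case = 3, control = 3),
#'     plantedLog2FC = c(SELENOS = 3), jitterSD = 0, refGroup = "control",
#'     seed = 2)
#' @export
simulateCqTable <- function(genes, groupSizes, plantedLog2FC = numeric(),
                            replicates = 3L, jitterSD = 0.1, refGroup,
                            housekeeping = "ACTB", seed) {
    if (!length(genes)) stop("gene list must be non-empty", call. = FALSE)
    stopifnot(replicates >= 1, jitterSD >= 0)
    if (!refGroup %in% names(groupSizes))
        stop("refGroup '", refGroup, "' is not among the group names", call. = FALSE)
    genes <- setdiff(genes, housekeeping)
    allGenes <- c(genes, housekeeping)
    lfc <- stats::setNames(numeric(length(allGenes)), allGenes)
    lfc[names(plantedLog2FC)] <- plantedLog2FC
    lfc[housekeeping] <- 0

    groups <- rep(names(groupSizes), times = groupSizes)
    samples <- unlist(lapply(names(groupSizes), function(gr)
        sprintf("%s_%02d", gr, seq_len(groupSizes[[gr]]))))

    grid <- expand.grid(replicate = seq_len(replicates), gene = allGenes,
        sample = samples, stringsAsFactors = FALSE)[, c("sample", "gene", "replicate")]
    grid$group <- groups[match(grid$sample, samples)]

    cq <- withSeed(seed, {
        cq0 <- stats::setNames(c(stats::runif(length(genes), 22, 30),
            stats::runif(1, 18, 20)), allGenes)
        base <- cq0[grid$gene] - lfc[grid$gene] * (grid$group != refGroup)
        as.numeric(base) + if (jitterSD > 0)
            stats::rnorm(nrow(grid), sd = jitterSD) else 0
    })
    out <- data.frame(sample = grid$sample, group = grid$group,
        gene = grid$gene, replicate = grid$replicate, cq = cq,
        stringsAsFactors = FALSE)
    attr(out, "housekeeping") <- housekeeping
    truth <- SyntheticTruth(plantedLog2FC = plantedLog2FC, seed = seed,
        params = list(groupSizes = as.list(groupSizes), refGroup = refGroup,
            replicates = replicates, jitterSD = jitterSD,
            housekeeping = housekeeping))
    list(cq = out, truth = truth)
}

#' Simulate an IHC cohort with correlated ordinal marker intensities
#'
#' Each patient carries two latent marker scores drawn from a bivariate
#' standard normal with correlation `latentRho`; grade-3 patients receive
#' an additive `gradeShift` on both latents (tumor grade raises staining
#' intensity of both markers).  Latents are discretized by the two
#' `thresholds` into ordinal intensities 1 (weak), 2 (moderate),
#' 3 (strong), and Ki67 percentages are drawn with grade-dependent mean
#' and standard deviation, truncated to \[0, 100\].
#'
#' The default Ki67 parameters and the 1:2 grade-2:grade-3 composition
#' mirror a 30-patient TNBC cohort (grade 2: mean 28.9, SD 13.3; grade 3:
#' mean 44.9, SD 15.8).  With the default `latentRho = 0.9` and
#' `gradeShift = 1.5` the ordinal marker-marker Pearson correlation is
#' approximately 0.77.
#'
#' @param nPatients cohort size.
#' @param latentRho latent correlation in \[-1, 1\].
#' @param gradeShift additive latent shift for grade-3 patients.
#' @param thresholds strictly increasing pair of cut points on the latent
#'   scale.
#' @param ki67Params list with elements `grade2` and `grade3`, each
#'   `c(mean =, sd =)` in percent.
#' @param markers names of the two marker intensity columns.
#' @param grade3Frac fraction of grade-3 patients (deterministic split).
#' @param seed integer RNG seed.
#' @return list with `cohort` (data.frame `patient`, `grade`, `ki67`, and
#'   one 1/2/3 intensity column per marker) and `truth`.
#' @examples
#' sim <- simulateIHCCohort(30, seed = 3)
#' table(sim$cohort$grade, sim$cohort$SELENOS)
#' @export
simulateIHCCohort <- function(nPatients = 30L, latentRho = 0.9,
                              gradeShift = 1.5, thresholds = c(-1.8, 1.0),
                              ki67Params = list(
                                  grade2 = c(mean = 28.9, sd = 13.3),
                                  grade3 = c(mean = 44.9, sd = 15.8)),
                              markers = c("SELENOS", "VCP"),
                              grade3Frac = 2 / 3, seed) {
    assertScalarNumber(latentRho, "latentRho", -1, 1)
    if (length(thresholds) != 2L || diff(thresholds) <= 0)
        stop("thresholds must be two strictly increasing values", call. = FALSE)
    stopifnot(length(markers) == 2L, nPatients >= 1)

    nG3 <- round(grade3Frac * nPatients)
    grade <- c(rep(2L, nPatients - nG3), rep(3L, nG3))

    sim <- withSeed(seed, {
        z1 <- stats::rnorm(nPatients)
        z2 <- latentRho * z1 + sqrt(1 - latentRho^2) * stats::rnorm(nPatients)
        shift <- gradeShift * (grade == 3L)
        ki <- numeric(nPatients)
        for (gr in c(2L, 3L)) {
            p <- ki67Params[[paste0("grade", gr)]]
            idx <- grade == gr
            ki[idx] <- stats::rnorm(sum(idx), p[["mean"]], p[["sd"]])
        }
        list(l1 = z1 + shift, l2 = z2 + shift, ki67 = pmin(100, pmax(0, ki)))
    })
    toIntensity <- function(z)
        as.integer(cut(z, c(-Inf, thresholds, Inf), labels = FALSE))

    cohort <- data.frame(patient = sprintf("P%03d", seq_len(nPatients)),
        grade = grade, ki67 = sim$ki67, stringsAsFactors = FALSE)
    cohort[[markers[1]]] <- toIntensity(sim$l1)
    cohort[[markers[2]]] <- toIntensity(sim$l2)

    truth <- SyntheticTruth(latentRho = latentRho, seed = seed,
        params = list(gradeShift = gradeShift, thresholds = thresholds,
            ki67Params = ki67Params, markers = markers,
            grade3Frac = grade3Frac))
    list(cohort = cohort, truth = truth)
}

#' Simulate a survival cohort with a planted hazard ratio
#'
#' Draws two correlated expression values per patient, splits the cohort
#' by the combined-expression median rule of [combinedSplit()] (mean of
#' per-gene z-scores, above-median = "high"), and gives the high group
#' exponentially distributed event times with hazard multiplied by
#' `hazardRatio`.  A fraction `censorRate` of patients (independent of
#' group) is right-censored at a uniform time before their event.
#'
#' @param nPatients cohort size (>= 4).
#' @param hazardRatio hazard multiplier of the high group (> 0).
#' @param censorRate expected censored fraction in \[0, 1).
#' @param expressionRho correlation of the two expression values.
#' @param baseMedianMonths median survival of the low group in months.
#' @param genes names of the two expression columns.
#' @param seed integer RNG seed.
#' @return list with `surv` (data.frame `patient`, `time`, `event`, one
#'   column per gene) and `truth` (whose `params$group` records the true
#'   high/low assignment).
#' @examples
#' sim <- simulateSurvivalCohort(100, hazardRatio = 2.5, seed = 4)
#' @export
simulateSurvivalCohort <- function(nPatients, hazardRatio = 2.5,
                                   censorRate = 0.2, expressionRho = 0.77,
                                   baseMedianMonths = 60,
                                   genes = c("SELENOS", "VCP"), seed) {
    stopifnot(nPatients >= 4, length(genes) == 2L)
    if (!is.numeric(hazardRatio) || hazardRatio <= 0)
        stop("hazardRatio must be positive", call. = FALSE)
    if (!is.numeric(censorRate) || censorRate < 0 || censorRate >= 1)
        stop("censorRate must be in [0, 1)", call. = FALSE)
    assertScalarNumber(expressionRho, "expressionRho", -1, 1)

    out <- withSeed(seed, {
        z1 <- stats::rnorm(nPatients)
        z2 <- expressionRho * z1 + sqrt(1 - expressionRho^2) * stats::rnorm(nPatients)
        e1 <- 10 + 2 * z1
        e2 <- 10 + 2 * z2
        tbl <- data.frame(patient = sprintf("P%03d", seq_len(nPatients)),
            time = 1, event = 1L, stringsAsFactors = FALSE)
        tbl[[genes[1]]] <- e1
        tbl[[genes[2]]] <- e2
        group <- combinedSplit(tbl, genes)
        rate <- log(2) / baseMedianMonths * hazardRatio^(group == "high")
        evTime <- stats::rexp(nPatients, rate)
        censored <- stats::runif(nPatients) < censorRate
        obsTime <- ifelse(censored, stats::runif(nPatients, 0, evTime), evTime)
        tbl$time <- obsTime
        tbl$event <- as.integer(!censored)
        list(tbl = tbl, group = group)
    })

    truth <- SyntheticTruth(hazardRatio = hazardRatio,
        latentRho = expressionRho, seed = seed,
        params = list(censorRate = censorRate,
            baseMedianMonths = baseMedianMonths, genes = genes,
            group = out$group))
    list(surv = out$tbl, truth = truth)
}
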