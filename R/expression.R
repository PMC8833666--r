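#' Build an expression study container
#'
#' Wraps a non-negative, linear-scale gene-by-sample matrix and its
#' sample group labels in a
#' [SummarizedExperiment::SummarizedExperiment-class] (assay `exprs`,
#' column data `group`), the container all expression operations accept.
#'
#' @param values numeric matrix, genes in rows (unique rownames),
#'   samples in columns; finite and >= 0.
#' @param groups character vector (or named vector matching colnames) of
#'   group labels, one per sample.
#' @return a `SummarizedExperiment`.
#' @export
ExpressionMatrix <- function(values, groups) {
    stopifnot(is.matrix(values), is.numeric(values))
    if (any(!is.finite(values)) || any(values < 0))
        stop("expression values must be finite and non-negative", call. = FALSE)
    if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
        stop("gene rownames must be present and unique", call. = FALSE)
    if (!is.null(names(groups)))
        groups <- groups[colnames(values)]
    if (length(groups) != ncol(values) || anyNA(groups))
        stop("every sample must carry a group label", call. = FALSE)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values),
        colData = S4Vectors::DataFrame(group = as.character(groups),
            row.names = colnames(values)))
}

#' Read an expression TSV plus sample-group file
#'
#' Expression file: tab-separated, genes in rows, first column = gene
#' symbol, header = sample identifiers.  Group file: two tab-separated
#' columns `sample`, `group` (no header required).
#'
#' @param exprFile,groupFile paths.
#' @return a `SummarizedExperiment` (see [ExpressionMatrix()]).
#' @export
readExpressionTSV <- function(exprFile, groupFile) {
    tab <- utils::read.delim(exprFile, check.names = FALSE)
    mat <- as.matrix(tab[, -1, drop = FALSE])
    rownames(mat) <- normalizeSymbols(tab[[1]])
    gtab <- utils::read.delim(groupFile, header = FALSE,
        col.names = c("sample", "group"))
    if (tolower(gtab$sample[1]) == "sample") gtab <- gtab[-1, , drop = FALSE]
    ExpressionMatrix(mat, stats::setNames(gtab$group, gtab$sample))
}

exprAssay <- function(m) {
    if (is(m, "SummarizedExperiment")) {
        list(values = SummarizedExperiment::assay(m, "exprs"),
            groups = SummarizedExperiment::colData(m)$group)
    } else stop("expected a SummarizedExperiment (see ExpressionMatrix())",
        call. = FALSE)
}

#' Per-group mean expression profiles
#'
#' Arithmetic mean of linear-scale expression per gene per group (means
#' are taken on the linear scale because downstream fold changes ratio
#' group means).
#'
#' @param m a `SummarizedExperiment` from [ExpressionMatrix()].
#' @param groups groups to profile (default: all groups present).
#' @return numeric matrix, genes x groups.
#' @export
meanProfiles <- function(m, groups = NULL) {
    a <- exprAssay(m)
    if (is.null(groups)) groups <- unique(a$groups)
    missing <- setdiff(groups, a$groups)
    if (length(missing))
        stop("unknown group(s): ", paste(missing, collapse = ", "), call. = FALSE)
    out <- vapply(groups, function(gr)
        rowMeans(a$values[, a$groups == gr, drop = FALSE]),
        numeric(nrow(a$values)))
    matrix(out, nrow = nrow(a$values),
        dimnames = list(rownames(a$values), groups))
}

#' Direction of mean expression between two groups
#'
#' Compares per-gene group means with a relative tolerance: genes whose
#' means differ by no more than `tol * max(|means|)` are called
#' `"equal"`, otherwise `"higher"` / `"lower"` (case vs reference).
#'
#' @param profiles gene x group mean matrix from [meanProfiles()].
#' @param caseGroup,refGroup column names to compare.
#' @param tol relative tolerance (default 1e-9).
#' @return named character vector, values in `higher`/`lower`/`equal`.
#' @export
directionTable <- function(profiles, caseGroup, refGroup, tol = 1e-9) {
    stopifnot(caseGroup %in% colnames(profiles), refGroup %in% colnames(profiles))
    a <- profiles[, caseGroup]; b <- profiles[, refGroup]
    eps <- tol * pmax(abs(a), abs(b))
    out <- ifelse(abs(a - b) <= eps, "equal", ifelse(a > b, "higher", "lower"))
    stats::setNames(out, rownames(profiles))
}

#' Select differentially expressed genes by fold-change ratio
#'
#' Computes per-gene `log2fc = log2((meanCase + pseudocount) /
#' (meanRef + pseudocount))` from linear-scale group means and labels
#' each gene `up` (log2fc >= threshold), `down` (<= -threshold),
#' `unchanged`, or `undefined` (a zero mean with pseudocount 0, warned).
#'
#' @param m a `SummarizedExperiment` from [ExpressionMatrix()].
#' @param caseGroup,refGroup group labels (both non-empty).
#' @param log2Threshold absolute log2 fold-change cutoff (default 1, the
#'   +/-1 log2 significance rule).
#' @param pseudocount added to both means before the ratio (default 0).
#' @return data.frame (one row per gene, original order) with columns
#'   `gene`, `meanCase`, `meanRef`, `log2fc`, `status`; attributes `up`
#'   and `down` hold the selected symbols sorted by |log2fc| decreasing
#'   then symbol.
#' @examples
#' sim <- simulateExpressionStudy(20, c(case = 3, ref = 3),
#'     plantedLog2FC = c(GENE0001 = 2), noiseSD = 0, refGroup = "ref", seed = 1)
#' fc <- selectDEGenes(sim$se, "case", "ref")
#' attr(fc, "up")
#' @export
selectDEGenes <- function(m, caseGroup, refGroup, log2Threshold = 1,
                          pseudocount = 0) {
    stopifnot(pseudocount >= 0, log2Threshold >= 0)
    prof <- meanProfiles(m, c(caseGroup, refGroup))
    mc <- prof[, caseGroup] + pseudocount
    mr <- prof[, refGroup] + pseudocount
    log2fc <- ifelse(mc > 0 & mr > 0, log2(mc / mr), NA_real_)
    status <- ifelse(is.na(log2fc), "undefined",
        ifelse(log2fc >= log2Threshold, "up",
            ifelse(log2fc <= -log2Threshold, "down", "unchanged")))
    if (any(status == "undefined"))
        warning(sum(status == "undefined"),
            " gene(s) have a zero group mean with pseudocount 0; status 'undefined'",
            call. = FALSE)
    out <- data.frame(gene = rownames(prof),
        meanCase = prof[, caseGroup], meanRef = prof[, refGroup],
        log2fc = log2fc, status = status,
        row.names = NULL, stringsAsFactors = FALSE)
    sel <- function(st) {
        d <- out[out$status == st & !is.na(out$log2fc), ]
        d$gene[order(-abs(d$log2fc), d$gene)]
    }
    attr(out, "up") <- sel("up")
    attr(out, "down") <- sel("down")
    attr(out, "log2Threshold") <- log2Threshold
    out
}

#' Consensus direction call across datasets
#'
#' A gene receives consensus `"up"`/`"down"` iff at least `minAgreement`
#' tables agree on that direction and no table reports the opposite
#' direction; genes with opposing calls are `"discordant"` and genes with
#' too few agreeing calls `"insufficient"`.  The result does not depend
#' on the order of the tables.
#'
#' @param tables list of named character vectors; values may be
#'   `up`/`down` (status tables) or `higher`/`lower` (direction tables);
#'   any other value is a non-vote.
#' @param minAgreement minimum number of agreeing tables
#'   (<= `length(tables)`).
#' @return named character vector over the union of genes, values in
#'   `up`/`down`/`discordant`/`insufficient`.
#' @export
consensusDirection <- function(tables, minAgreement) {
    stopifnot(length(tables) >= 1, minAgreement >= 1,
        minAgreement <= length(tables))
    norm <- lapply(tables, function(t) {
        v <- ifelse(t %in% c("up", "higher"), "up",
            ifelse(t %in% c("down", "lower"), "down", NA_character_))
        stats::setNames(v, names(t))
    })
    genes <- sort(unique(unlist(lapply(norm, names))))
    out <- vapply(genes, function(g) {
        votes <- unlist(lapply(norm, function(t) t[g]))
        nUp <- sum(votes == "up", na.rm = TRUE)
        nDown <- sum(votes == "down", na.rm = TRUE)
        if (nUp > 0 && nDown > 0) "discordant"
        else if (nUp >= minAgreement) "up"
        else if (nDown >= minAgreement) "down"
        else "insufficient"
    }, "")
    stats::setNames(out, genes)
}

#' Relative quantification by the 2^-ddCq method
#'
#' For each target gene: per-group delta-Cq is the group mean target Cq
#' minus the group mean housekeeping Cq (replicates averaged per sample
#' first); `ddCq = dCq(case) - dCq(ref)`; `foldChange = 2^-ddCq`.  A
#' fold change is flagged significant when `|log2(foldChange)| >=
#' log2Threshold` (the +/-1 log2 rule by default).
#'
#' @param cq Cq table as produced by [simulateCqTable()] or read from a
#'   TSV with columns `sample`, `group`, `gene`, `replicate`, `cq`.
#' @param caseGroup,refGroup group labels present in `cq$group`.
#' @param log2Threshold significance cutoff on |log2 fold change|.
#' @param housekeeping housekeeping gene symbol; defaults to the table's
#'   `housekeeping` attribute, else `"ACTB"`.
#' @return data.frame with one row per target gene: `gene`, `dCqCase`,
#'   `dCqRef`, `ddCq`, `foldChange`, `log2fc`, `significant`.
#' @examples
#' sim <- simulateCqTable(c("SELENOS"), c(case = 3, control = 3),
#'     plantedLog2FC = c(SELENOS = 3), jitterSD = 0, refGroup = "control",
#'     seed = 1)
#' ddcqFoldChange(sim$cq, "case", "control")
#' @export
ddcqFoldChange <- function(cq, caseGroup, refGroup, log2Threshold = 1,
                           housekeeping = NULL) {
    stopifnot(all(c("sample", "group", "gene", "replicate", "cq") %in% names(cq)))
    housekeeping <- housekeeping %||% attr(cq, "housekeeping") %||% "ACTB"
    if (!all(c(caseGroup, refGroup) %in% cq$group))
        stop("both groups must be present in the Cq table", call. = FALSE)
    hkSamples <- unique(cq$sample[cq$gene == housekeeping])
    missingHk <- setdiff(unique(cq$sample), hkSamples)
    if (length(missingHk))
        stop("housekeeping gene '", housekeeping, "' missing for sample(s): ",
            paste(missingHk, collapse = ", "), call. = FALSE)

    # replicate mean per (sample, gene), then group means
    agg <- stats::aggregate(cq ~ sample + group + gene, data = cq, FUN = mean)
    groupMean <- function(gene, grp) {
        v <- agg$cq[agg$gene == gene & agg$group == grp]
        mean(v)
    }
    targets <- setdiff(unique(cq$gene), housekeeping)
    res <- lapply(targets, function(g) {
        dCase <- groupMean(g, caseGroup) - groupMean(housekeeping, caseGroup)
        dRef <- groupMean(g, refGroup) - groupMean(housekeeping, refGroup)
        dd <- dCase - dRef
        data.frame(gene = g, dCqCase = dCase, dCqRef = dRef, ddCq = dd,
            foldChange = 2^(-dd), log2fc = -dd,
            significant = abs(dd) >= log2Threshold,
            stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}
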