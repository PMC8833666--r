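#' Parse an interaction edge list
#'
#' Reads physical-interaction records from one of three plain-text
#' dialects and normalizes gene identifiers (trim + uppercase, optional
#' synonym table).  Supported dialects:
#'
#' * `sif`: Cytoscape simple interaction format,
#'   `source <relation> target [target2 ...]`; a line `A pp B C` yields the
#'   pairs A-B and A-C.  The relation token is ignored (interactions are
#'   undirected and untyped here).
#' * `tsv2`: two (or more) tab-separated columns; the first two columns are
#'   the interacting symbols.
#' * `mitab_min`: minimal tab-separated MITAB-like dialect; the columns
#'   holding the two gene symbols are chosen with `cols` (default 1 and 2).
#'   Full PSI-MI controlled-vocabulary parsing is out of scope.
#'
#' Blank lines and lines starting with `#` are skipped; malformed lines
#' (too few fields) are skipped and reported with their line numbers.
#'
#' @param input path to a file, or a character vector of lines.
#' @param dialect one of `"sif"`, `"tsv2"`, `"mitab_min"`.
#' @param source source identifier stored with every record.
#' @param cols for `mitab_min`, integer vector of length 2: columns holding
#'   the two interactor symbols.
#' @param synonyms optional named character vector mapping input symbols to
#'   replacement symbols (applied after normalization).
#' @return data.frame with columns `geneA`, `geneB`, `source`, `lineNo`;
#'   attributes `skipped` (blank/comment count), `malformed`
#'   (integer vector of offending line numbers) and `isolated`
#'   (SIF lines naming a single node).
#' @examples
#' parseInteractions(c("A\tB", "b\ta"), dialect = "tsv2")
#' parseInteractions("A pp B C", dialect = "sif")
#' @export
parseInteractions <- function(input, dialect = c("sif", "tsv2", "mitab_min"),
                              source = "source1", cols = c(1L, 2L),
                              synonyms = NULL) {
    dialect <- match.arg(dialect)
    lines <- if (length(input) == 1L && file.exists(input)) readLines(input, warn = FALSE)
             else as.character(input)
    if (length(lines) == 0L) stop("empty input stream", call. = FALSE)

    lineNo <- seq_along(lines)
    blank <- !nzchar(trimws(lines)) | startsWith(trimws(lines), "#")
    keep <- which(!blank)

    recA <- character(); recB <- character(); recLine <- integer()
    malformed <- integer(); isolated <- integer()

    for (i in keep) {
        ln <- lines[i]
        if (dialect == "sif") {
            # tab-delimited if any tab present, else whitespace-delimited
            toks <- if (grepl("\t", ln, fixed = TRUE))
                strsplit(ln, "\t", fixed = TRUE)[[1]]
            else strsplit(trimws(ln), "[[:space:]]+")[[1]]
            toks <- toks[nzchar(trimws(toks))]
            if (length(toks) == 1L) { isolated <- c(isolated, i); next }
            if (length(toks) == 2L) { malformed <- c(malformed, i); next }
            src <- toks[1]; targets <- toks[-(1:2)]
            recA <- c(recA, rep(src, length(targets)))
            recB <- c(recB, targets)
            recLine <- c(recLine, rep(i, length(targets)))
        } else {
            toks <- strsplit(ln, "\t", fixed = TRUE)[[1]]
            idx <- if (dialect == "tsv2") c(1L, 2L) else as.integer(cols)
            if (length(toks) < max(idx) ||
                any(!nzchar(trimws(toks[idx])))) {
                malformed <- c(malformed, i); next
            }
            recA <- c(recA, toks[idx[1]]); recB <- c(recB, toks[idx[2]])
            recLine <- c(recLine, i)
        }
    }

    if (length(recA) == 0L)
        stop("no parseable interaction lines in input (dialect '", dialect, "')",
            call. = FALSE)
    if (length(malformed))
        warning(length(malformed), " malformed line(s) skipped: lines ",
            paste(utils::head(malformed, 10), collapse = ", "),
            if (length(malformed) > 10) ", ..." else "", call. = FALSE)

    out <- data.frame(
        geneA = normalizeSymbols(recA, synonyms),
        geneB = normalizeSymbols(recB, synonyms),
        source = source, lineNo = recLine,
        stringsAsFactors = FALSE)
    attr(out, "skipped") <- sum(blank)
    attr(out, "malformed") <- malformed
    attr(out, "isolated") <- isolated
    out
}

#' Merge interaction record lists into one Interactome
#'
#' Reproduces the database-union step used to build an "entire
#' interactome" from several interaction databases: the union of
#' unordered symbol pairs over all sources, with self-loops dropped
#' (counted), duplicates collapsed, and per-edge provenance recording
#' every source that reported the edge.  The merge is order-invariant
#' and idempotent.
#'
#' @param recordLists a list of record data.frames as returned by
#'   [parseInteractions()] (a single data.frame is also accepted).
#'   If the list is named and a data.frame lacks a `source` column, the
#'   list name is used as its source identifier.
#' @return an [Interactome-class].
#' @examples
#' s1 <- parseInteractions(c("A\tB", "B\tC"), dialect = "tsv2", source = "s1")
#' s2 <- parseInteractions(c("B\tA", "C\tD"), dialect = "tsv2", source = "s2")
#' mergeInteractomes(list(s1, s2))
#' @export
mergeInteractomes <- function(recordLists) {
    if (is.data.frame(recordLists)) recordLists <- list(recordLists)
    if (!length(recordLists)) stop("need at least one source record list", call. = FALSE)
    for (i in seq_along(recordLists)) {
        rl <- recordLists[[i]]
        stopifnot(is.data.frame(rl), all(c("geneA", "geneB") %in% names(rl)))
        if (is.null(rl$source))
            recordLists[[i]]$source <- names(recordLists)[i] %||% paste0("source", i)
    }
    rec <- do.call(rbind, lapply(recordLists, function(d)
        d[, c("geneA", "geneB", "source")]))
    nInput <- nrow(rec)

    loops <- rec$geneA == rec$geneB
    nLoops <- sum(loops)
    rec <- rec[!loops, , drop = FALSE]

    if (nrow(rec) == 0L) {
        warning("merged interactome is empty", call. = FALSE)
        g <- igraph::make_empty_graph(0, directed = FALSE)
        return(new("Interactome", graph = g,
            log = list(nInputRecords = nInput, droppedSelfLoops = nLoops,
                duplicateRecords = 0L)))
    }

    key <- pairKey(rec$geneA, rec$geneB)
    prov <- lapply(split(rec$source, key), function(s) sort(unique(s)))
    ukey <- names(prov)
    ends <- strsplit(ukey, "|", fixed = TRUE)
    from <- vapply(ends, `[`, "", 1L)
    to <- vapply(ends, `[`, "", 2L)

    nodes <- sort(unique(c(from, to)))
    g <- igraph::graph_from_data_frame(
        data.frame(from = from, to = to,
            sources = vapply(prov, paste, "", collapse = "|")),
        directed = FALSE, vertices = nodes)

    new("Interactome", graph = g,
        log = list(nInputRecords = nInput, droppedSelfLoops = nLoops,
            duplicateRecords = nInput - nLoops - length(ukey)))
}

#' Small-world topology statistics of a network
#'
#' Computes the global statistics used to characterize interaction
#' networks: density, average number of neighbors, degree heterogeneity
#' (coefficient of variation of the degree distribution, population
#' standard deviation), characteristic path length (mean shortest-path
#' distance over all unordered connected node pairs) and component count.
#'
#' For networks with at most `pathLengthExactLimit` nodes the path length
#' is exact (breadth-first search from every node); above the limit it is
#' estimated from `sampleSources` uniformly sampled source nodes and the
#' sampling seed and size are recorded in the result.
#'
#' @param g an [Interactome-class], [Subnetwork-class] or igraph.
#' @param pathLengthExactLimit exact-BFS node-count limit (default 3000).
#' @param sampleSources number of sampled sources above the limit.
#' @param seed RNG seed for source sampling.
#' @return a list with elements `nNodes`, `nEdges`, `density`,
#'   `avgNeighbors`, `charPathLength`, `heterogeneity`, `nComponents`,
#'   and (when sampling was used) `pathLengthSampling`.
#' @examples
#' g <- igraph::make_full_graph(4)
#' igraph::V(g)$name <- LETTERS[1:4]
#' networkStats(g)
#' @export
networkStats <- function(g, pathLengthExactLimit = 3000L,
                         sampleSources = 1000L, seed = 1L) {
    graph <- if (is(g, "Interactome")) g@graph else g
    stopifnot(igraph::is_igraph(graph))
    n <- igraph::gorder(graph)
    if (n < 2L) stop("network statistics are undefined for graphs with < 2 nodes",
        call. = FALSE)
    m <- igraph::gsize(graph)
    deg <- igraph::degree(graph)
    mdeg <- mean(deg)
    het <- if (mdeg == 0) 0 else sqrt(mean((deg - mdeg)^2)) / mdeg

    sampling <- NULL
    if (n <= pathLengthExactLimit) {
        cpl <- igraph::mean_distance(graph, directed = FALSE, unconnected = TRUE)
    } else {
        src <- withSeed(seed, sample.int(n, min(sampleSources, n)))
        d <- igraph::distances(graph, v = src)
        d[!is.finite(d)] <- NA
        d[cbind(seq_along(src), src)] <- NA   # drop self pairs
        cpl <- mean(d, na.rm = TRUE)
        sampling <- list(nSources = length(src), seed = as.integer(seed))
    }

    out <- list(nNodes = n, nEdges = m,
        density = 2 * m / (n * (n - 1)),
        avgNeighbors = 2 * m / n,
        charPathLength = cpl,
        heterogeneity = het,
        nComponents = igraph::components(graph)$no)
    if (!is.null(sampling)) out$pathLengthSampling <- sampling
    out
}

#' Read / write an interactome
#'
#' `readInteractome` reads a merged graph from SIF or GraphML;
#' `writeInteractome` writes one.  GraphML IO is delegated to igraph;
#' the `sources` provenance edge attribute round-trips through both
#' formats (in SIF it is stored as the relation token).
#'
#' @param file path.
#' @param format `"sif"` or `"graphml"`.
#' @param x an [Interactome-class] or [Subnetwork-class].
#' @return `readInteractome`: an [Interactome-class];
#'   `writeInteractome`: the path, invisibly.
#' @export
readInteractome <- function(file, format = c("sif", "graphml")) {
    format <- match.arg(format)
    if (format == "graphml") {
        g <- igraph::read_graph(file, format = "graphml")
        g <- igraph::as_undirected(g, mode = "collapse")
        if (is.null(igraph::edge_attr(g, "sources")))
            igraph::E(g)$sources <- "file"
        return(new("Interactome", graph = g, log = list()))
    }
    lines <- readLines(file, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    rec <- list()
    for (ln in lines) {
        toks <- if (grepl("\t", ln, fixed = TRUE))
            strsplit(ln, "\t", fixed = TRUE)[[1]]
        else strsplit(trimws(ln), "[[:space:]]+")[[1]]
        toks <- toks[nzchar(toks)]
        if (length(toks) < 3L) next
        for (tgt in toks[-(1:2)])
            rec[[length(rec) + 1L]] <- data.frame(geneA = toks[1], geneB = tgt,
                source = gsub("^sources:", "", toks[2]))
    }
    if (!length(rec)) stop("no edges found in SIF file", call. = FALSE)
    rec <- do.call(rbind, rec)
    # split multi-source relation tokens back into one record per source
    srcs <- strsplit(rec$source, "|", fixed = TRUE)
    rec <- data.frame(
        geneA = rep(rec$geneA, lengths(srcs)),
        geneB = rep(rec$geneB, lengths(srcs)),
        source = unlist(srcs))
    mergeInteractomes(rec)
}

#' @rdname readInteractome
#' @export
writeInteractome <- function(x, file, format = c("sif", "graphml")) {
    format <- match.arg(format)
    g <- if (is(x, "Interactome")) x@graph else x
    if (format == "graphml") {
        igraph::write_graph(g, file, format = "graphml")
    } else {
        el <- igraph::as_edgelist(g)
        rel <- paste0("sources:", igraph::E(g)$sources %||% rep("NA", nrow(el)))
        writeLines(paste(el[, 1], rel, el[, 2], sep = "\t"), file)
    }
    invisible(file)
}
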