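#' The 25 human selenoprotein gene symbols
#'
#' The selenoprotein family: five glutathione peroxidases, three
#' iodothyronine deiodinases, three thioredoxin reductases, MSRB1,
#' SEPHS2 and the SELENO* members.  Shipped so pipeline demonstrations
#' can use the family as a seed list.
#'
#' @return character vector of 25 gene symbols.
#' @export
selenoproteins <- function() {
    f <- system.file("extdata", "selenoproteins.txt", package = "SelenoNet")
    readLines(f)
}

#' Published TNBC IHC staining marginal counts for SELENOS and VCP/p97
#'
#' Grade-by-intensity marginal counts from a 30-patient TNBC cohort
#' (10 grade-2, 20 grade-3 tumors): for SELENOS, grade 2 showed 9
#' moderate and 1 strong staining, grade 3 showed 2 moderate and 18
#' strong; for VCP/p97, grade 2 showed 2 weak, 7 moderate, 1 strong and
#' grade 3 showed 1 weak, 5 moderate, 14 strong.
#'
#' @return named list of two 2 x 3 integer matrices (`SELENOS`, `VCP`),
#'   rows `grade2`/`grade3`, columns `weak`/`moderate`/`strong`.
#' @export
tnbcStainingCounts <- function() {
    dn <- list(c("grade2", "grade3"), c("weak", "moderate", "strong"))
    list(
        SELENOS = matrix(c(0L, 0L, 9L, 2L, 1L, 18L), 2, 3, dimnames = dn),
        VCP = matrix(c(2L, 1L, 7L, 5L, 1L, 14L), 2, 3, dimnames = dn))
}

#' Build an IHC cohort data.frame from grade-by-intensity counts
#'
#' Expands marginal count matrices (as from [tnbcStainingCounts()]) into
#' a per-patient cohort.  With more than one marker the joint assignment
#' within each grade pairs intensities in increasing order for every
#' marker, a deterministic convention: only the marginals are
#' reproduced, the joint distribution is synthetic.
#'
#' @param counts named list of 2 x 3 count matrices, one per marker; all
#'   must have equal row sums (patients per grade).
#' @return data.frame with `patient`, `grade` and one intensity column
#'   per marker.
#' @export
cohortFromCounts <- function(counts) {
    stopifnot(is.list(counts), length(counts) >= 1)
    rs <- vapply(counts, rowSums, numeric(2))
    if (any(rs != rs[, 1]))
        stop("all markers must have identical patients-per-grade totals",
            call. = FALSE)
    grade <- rep(c(2L, 3L), times = rs[, 1])
    out <- data.frame(patient = sprintf("P%03d", seq_along(grade)),
        grade = grade, stringsAsFactors = FALSE)
    for (mk in names(counts)) {
        m <- counts[[mk]]
        out[[mk]] <- c(rep(1:3, times = m[1, ]), rep(1:3, times = m[2, ]))
    }
    out
}
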