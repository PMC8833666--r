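#' Staining intensity distribution by tumor grade
#'
#' Contingency table of ordinal IHC intensities (1 weak, 2 moderate,
#' 3 strong) per tumor grade (2, 3) for one marker.  Row sums equal the
#' number of patients per grade.
#'
#' @param cohort IHC cohort data.frame with columns `grade` and one
#'   intensity column per marker (see [simulateIHCCohort()]).
#' @param marker marker column name.
#' @return 2 x 3 integer matrix, rows `grade2`/`grade3`, columns
#'   `weak`/`moderate`/`strong`.
#' @export
stainingDistribution <- function(cohort, marker) {
    if (!marker %in% names(cohort))
        stop("unknown marker '", marker, "'", call. = FALSE)
    out <- matrix(0L, 2, 3,
        dimnames = list(c("grade2", "grade3"), c("weak", "moderate", "strong")))
    if (nrow(cohort)) {
        tab <- table(factor(cohort$grade, levels = c(2, 3)),
            factor(cohort[[marker]], levels = 1:3))
        out[] <- as.integer(tab)
    }
    out
}

#' Pearson correlation with two-sided t-test p-value
#'
#' Product-moment correlation; the p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom,
#' two-sided (the classical test, computed via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length (n >= 3, both with
#'   nonzero variance).
#' @return list with `r`, `n`, `pValue`, `method = "pearson"`.
#' @examples
#' pearsonCorrelation(c(1, 2, 3, 4), c(1, 3, 2, 4))$r   # 0.8
#' @export
pearsonCorrelation <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("correlation undefined: zero variance", call. = FALSE)
    ct <- stats::cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), n = length(x),
        pValue = ct$p.value, method = "pearson")
}

#' Split a cohort by combined two-gene expression
#'
#' Combined signature score = mean of the two per-gene z-scores; patients
#' above the cohort median are `"high"`, all others (including exact
#' median ties, resolved deterministically toward low) are `"low"`.
#'
#' @param s survival/expression data.frame with one numeric column per
#'   gene (see [simulateSurvivalCohort()]); n >= 4.
#' @param genes character vector of the two gene column names.
#' @return character vector (`"high"`/`"low"`) per patient, with
#'   attribute `nTies` counting exact-median assignments.
#' @export
combinedSplit <- function(s, genes) {
    stopifnot(length(genes) == 2L)
    if (!all(genes %in% names(s)))
        stop("gene column(s) missing: ",
            paste(setdiff(genes, names(s)), collapse = ", "), call. = FALSE)
    if (nrow(s) < 4) stop("need at least 4 patients", call. = FALSE)
    z <- vapply(genes, function(g) {
        v <- s[[g]]
        sdv <- stats::sd(v)
        if (sdv == 0) stop("zero variance in gene '", g, "'", call. = FALSE)
        (v - mean(v)) / sdv
    }, numeric(nrow(s)))
    score <- rowMeans(z)
    if (stats::sd(score) < 1e-8)
        warning("combined score is (nearly) constant; the median split is degenerate",
            call. = FALSE)
    med <- stats::median(score)
    out <- ifelse(score > med, "high", "low")
    attr(out, "nTies") <- sum(score == med)
    out
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group and the standard two-group
#' log-rank statistic (observed vs expected events over distinct event
#' times with hypergeometric variance; chi-square with 1 df), computed
#' with the survival package.
#'
#' @param s survival data.frame with columns `time` (> 0) and `event`
#'   (0/1).
#' @param groups group label per patient (two non-empty groups), e.g.
#'   from [combinedSplit()].
#' @return list with `curves` (data.frame `group`, `time`, `nRisk`,
#'   `nEvent`, `survival`), `chisq`, `pValue`, and the underlying
#'   `survfit` object as `fit`.
#' @examples
#' sim <- simulateSurvivalCohort(60, hazardRatio = 2.5, seed = 8)
#' grp <- combinedSplit(sim$surv, c("SELENOS", "VCP"))
#' kmLogrank(sim$surv, grp)$pValue
#' @export
kmLogrank <- function(s, groups) {
    stopifnot(all(c("time", "event") %in% names(s)))
    groups <- as.character(groups)
    if (length(groups) != nrow(s))
        stop("one group label per patient required", call. = FALSE)
    lv <- unique(groups)
    if (length(lv) != 2 || any(table(groups) == 0))
        stop("exactly two non-empty groups required", call. = FALSE)
    dat <- data.frame(time = s$time, event = s$event, group = groups)
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
    sm <- summary(fit)
    strata <- if (is.null(sm$strata)) rep(lv[1], length(sm$time))
              else sub("^group=", "", as.character(sm$strata))
    curves <- data.frame(group = strata, time = sm$time, nRisk = sm$n.risk,
        nEvent = sm$n.event, survival = sm$surv)
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
    chisq <- unname(sd$chisq)
    list(curves = curves, chisq = chisq,
        pValue = stats::pchisq(chisq, df = 1, lower.tail = FALSE), fit = fit)
}
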