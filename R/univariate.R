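#' Two-sided Wilcoxon rank-sum test
#'
#' Exact mode enumerates the rank-sum null distribution (no ties, combined
#' sample size at most \code{exactLimit}); normal mode uses midranks with
#' the tie-corrected variance and a continuity correction. \code{"auto"}
#' picks the exact test whenever it is applicable.
#'
#' @param case,control numeric vectors, each non-empty.
#' @param mode \code{"auto"}, \code{"exact"} or \code{"normal"}.
#' @param exactLimit maximum combined sample size for the exact test
#'   (default 30).
#' @return the two-sided p-value.
#' @examples
#' wilcoxonTest(c(1, 2, 3), c(4, 5, 6), mode = "exact")  # 0.1
#' @export
wilcoxonTest <- function(case, control, mode = c("auto", "exact", "normal"),
                         exactLimit = 30) {
    mode <- match.arg(mode)
    if (!length(case) || !length(control))
        stop("both groups must contain at least one value")
    ties <- anyDuplicated(c(case, control)) > 0
    n <- length(case) + length(control)
    if (mode == "exact") {
        if (ties) stop("exact mode requires tie-free data")
        if (n > exactLimit)
            stop("exact mode limited to combined n <= ", exactLimit)
    }
    if (mode == "auto") mode <- if (!ties && n <= exactLimit) "exact" else "normal"
    if (mode == "exact")
        stats::wilcox.test(case, control, exact = TRUE)$p.value
    else
        suppressWarnings(
            stats::wilcox.test(case, control, exact = FALSE,
                               correct = TRUE)$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classical step-up FDR adjustment: with p-values sorted ascending,
#' q_(i) = min over k >= i of p_(k) * m / k, capped at 1 and returned in the
#' input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted q-values.
#' @export
bhAdjust <- function(p) {
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1] and be non-missing")
    stats::p.adjust(p, method = "BH")
}

#' Median-ratio fold change
#'
#' Fold change as the ratio of the case-group median to the control-group
#' median, computed on raw-scale (drift-corrected, untransformed)
#' intensities. The effective fold change folds decreases as the
#' reciprocal, so a halving and a doubling are equally extreme.
#'
#' @param case,control numeric vectors with positive medians.
#' @return list with \code{fc}, \code{direction} (\code{"up"} iff fc > 1),
#'   and \code{effective_fc} = max(fc, 1/fc).
#' @export
foldChange <- function(case, control) {
    mc <- stats::median(case)
    mk <- stats::median(control)
    if (!is.finite(mc) || !is.finite(mk) || mc <= 0 || mk <= 0)
        stop("group medians must be positive")
    fc <- mc / mk
    list(fc = fc, direction = if (fc > 1) "up" else "down",
         effective_fc = max(fc, 1 / fc))
}

#' Per-feature univariate statistics
#'
#' For every requested feature: the median-ratio fold change on raw-scale
#' drift-corrected intensities, the two-sided Wilcoxon rank-sum p-value
#' (case vs control study samples) and the Benjamini-Hochberg q-value
#' across the requested features.
#'
#' @param table a \linkS4class{MetaboExperiment}, typically drift-corrected.
#' @param features feature identifiers to test (default: all).
#' @param exactLimit combined sample size up to which the exact Wilcoxon
#'   test is used (default 30).
#' @return a [S4Vectors::DataFrame] with columns \code{feature_id},
#'   \code{fc}, \code{direction}, \code{effective_fc}, \code{p}, \code{q}.
#' @export
univariateStats <- function(table, features = rownames(table),
                            exactLimit = 30) {
    role <- colData(table)$role
    x <- assay(table, "intensity")[features, , drop = FALSE]
    caseIdx <- role == "case"
    ctrlIdx <- role == "control"
    if (!any(caseIdx) || !any(ctrlIdx))
        stop("table must contain both case and control study samples")
    res <- lapply(features, function(f) {
        ca <- x[f, caseIdx]; co <- x[f, ctrlIdx]
        fcr <- foldChange(ca, co)
        p <- wilcoxonTest(ca, co, mode = "auto", exactLimit = exactLimit)
        c(fc = fcr$fc, effective_fc = fcr$effective_fc, p = p)
    })
    res <- do.call(rbind, res)
    S4Vectors::DataFrame(
        feature_id = features,
        fc = res[, "fc"],
        direction = ifelse(res[, "fc"] > 1, "up", "down"),
        effective_fc = res[, "effective_fc"],
        p = res[, "p"],
        q = bhAdjust(res[, "p"]),
        row.names = features)
}

#' Univariate feature selection
#'
#' Selects features with q-value strictly below \code{qMax} and effective
#' fold change strictly above \code{fcMin} (the threshold applies to
#' max(FC, 1/FC), so decreases count via the reciprocal).
#'
#' @param stats a DataFrame/data.frame with columns \code{feature_id},
#'   \code{q} and \code{effective_fc} (as returned by [univariateStats()]).
#' @param qMax FDR threshold (default 0.05, strict).
#' @param fcMin effective fold-change threshold (default 1.5, strict).
#' @return character vector of selected feature identifiers.
#' @export
selectUnivariate <- function(stats, qMax = 0.05, fcMin = 1.5) {
    if (!nrow(stats)) return(character(0))
    sel <- !is.na(stats$q) & stats$q < qMax &
        !is.na(stats$effective_fc) & stats$effective_fc > fcMin
    as.character(stats$feature_id[sel])
}
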