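#' LOESS drift correction against pooled-QC injections
#'
#' Per feature, fits a LOESS curve of the QC intensities versus injection
#' order (degree 1) and divides every sample's intensity by the fitted value
#' at its own injection order, re-anchoring to the per-feature QC median so
#' corrected intensities stay on the original scale. QC and study samples
#' are both corrected. Features whose fitted curve is non-positive or
#' undefined anywhere, whose QC values are constant zero, or which have
#' fewer than \code{minQC} observed QC values are flagged and passed through
#' uncorrected.
#'
#' @param table a \linkS4class{MetaboExperiment}.
#' @param span LOESS span (default 0.75).
#' @param minQC minimum number of QC injections required (default 5).
#' @return a corrected \linkS4class{MetaboExperiment}; flagged features are
#'   listed in \code{metadata(.)$drift_correction$flagged}.
#' @export
correctDrift <- function(table, span = 0.75, minQC = 5) {
    role <- colData(table)$role
    qcIdx <- which(role == "qc")
    if (length(qcIdx) < minQC)
        stop("drift correction requires at least ", minQC,
             " QC samples (found ", length(qcIdx), ")")
    ord <- colData(table)$injection_order
    x <- assay(table, "intensity")
    out <- x
    flagged <- character(0)
    for (j in seq_len(nrow(x))) {
        q <- x[j, qcIdx]
        ok <- !is.na(q)
        if (sum(ok) < minQC || all(q[ok] == 0)) {
            flagged <- c(flagged, rownames(x)[j])
            next
        }
        qo <- ord[qcIdx][ok]
        qv <- q[ok]
        med <- stats::median(qv)
        if (stats::sd(qv) == 0) next   # constant QC: fit is flat, ratio 1
        ## "direct" surface evaluation warns about pseudoinverse use in
        ## sparse local neighbourhoods; that is its documented fallback
        fit <- tryCatch(suppressWarnings(
            stats::loess(qv ~ qo, span = span, degree = 1,
                         control = stats::loess.control(surface = "direct"))),
            error = function(e) NULL)
        pred <- if (is.null(fit)) NULL else suppressWarnings(
            stats::predict(fit, newdata = data.frame(qo = ord)))
        if (is.null(pred) || anyNA(pred) || any(pred <= 0)) {
            flagged <- c(flagged, rownames(x)[j])
            next
        }
        out[j, ] <- x[j, ] / pred * med
    }
    SummarizedExperiment::assay(table, "intensity") <- out
    md <- S4Vectors::metadata(table)
    md$drift_correction <- list(span = span, minQC = minQC, flagged = flagged)
    S4Vectors::metadata(table) <- md
    table
}

.emptyFilterStats <- function(ids) {
    S4Vectors::DataFrame(
        feature_id = ids,
        qc_cv = NA_real_, dilution_r2 = NA_real_, complete = NA,
        retained = TRUE, reason_dropped = "none", row.names = ids)
}

.asFilterReport <- function(st, thresholds) {
    st$reason_dropped <- as.character(st$reason_dropped)
    st$retained <- st$reason_dropped == "none"
    new("FilterReport", stats = st, thresholds = thresholds)
}

#' Pooled-QC coefficient-of-variation filter
#'
#' Computes, per feature, the coefficient of variation (sample standard
#' deviation / mean) across the pooled-QC injections. A feature is retained
#' only when its QC CV is strictly below \code{maxCv}; features with zero QC
#' mean are dropped with reason \code{"cv"}.
#'
#' @param table a \linkS4class{MetaboExperiment} with at least two QC
#'   samples.
#' @param maxCv CV threshold, default 0.30 (strict inequality).
#' @return a \linkS4class{FilterReport}.
#' @export
qcCvFilter <- function(table, maxCv = 0.30) {
    qcIdx <- which(colData(table)$role == "qc")
    if (length(qcIdx) < 2)
        stop("qcCvFilter requires at least 2 QC samples")
    x <- assay(table, "intensity")[, qcIdx, drop = FALSE]
    st <- .emptyFilterStats(rownames(table))
    cv <- apply(x, 1, function(v) {
        v <- v[!is.na(v)]
        if (length(v) < 2) return(NA_real_)
        m <- mean(v)
        if (m == 0) return(Inf)
        stats::sd(v) / m
    })
    st$qc_cv <- ifelse(is.finite(cv), cv, NA_real_)
    fail <- is.na(cv) | !is.finite(cv) | cv >= maxCv
    st$reason_dropped[fail] <- "cv"
    .asFilterReport(st, list(max_cv = maxCv))
}

#' Dilution-series linearity filter
#'
#' Per feature, the r-squared of an ordinary least-squares fit of intensity
#' versus dilution factor over the QC dilution series (factors 1, 1/2, 1/4).
#' Features are retained when r-squared >= \code{minR2} (inclusive). A
#' constant response across dilutions has zero regression sum of squares and
#' is assigned r-squared 0, hence dropped.
#'
#' @param table a \linkS4class{MetaboExperiment} with at least 3 dilution
#'   samples at distinct factors.
#' @param minR2 threshold, default 0.8 (inclusive).
#' @return a \linkS4class{FilterReport}.
#' @export
dilutionLinearityFilter <- function(table, minR2 = 0.8) {
    dilIdx <- which(colData(table)$role == "dilution")
    fac <- colData(table)$dilution_factor[dilIdx]
    if (length(dilIdx) < 3 || length(unique(fac)) < 3)
        stop("dilutionLinearityFilter requires >= 3 dilution samples with distinct factors")
    x <- assay(table, "intensity")[, dilIdx, drop = FALSE]
    st <- .emptyFilterStats(rownames(table))
    r2 <- apply(x, 1, function(v) {
        ok <- !is.na(v)
        if (sum(ok) < 3) return(0)
        yv <- v[ok]; xv <- fac[ok]
        sst <- sum((yv - mean(yv))^2)
        if (sst == 0) return(0)
        fit <- stats::lm.fit(cbind(1, xv), yv)
        1 - sum(fit$residuals^2) / sst
    })
    st$dilution_r2 <- r2
    st$reason_dropped[r2 < minR2] <- "linearity"
    .asFilterReport(st, list(min_r2 = minR2))
}

#' Completeness filter
#'
#' Retains only features observed (non-missing) in every sample -- study,
#' QC and dilution alike.
#'
#' @param table a \linkS4class{MetaboExperiment}.
#' @return a \linkS4class{FilterReport}.
#' @export
completenessFilter <- function(table) {
    x <- assay(table, "intensity")
    st <- .emptyFilterStats(rownames(table))
    st$complete <- !apply(x, 1, anyNA)
    st$reason_dropped[!st$complete] <- "missing"
    .asFilterReport(st, list())
}

#' Combined feature-quality filtering
#'
#' Applies the QC-CV, dilution-linearity and completeness filters (three
#' independent per-feature predicates) and combines them into one report. A
#' feature is retained only if it passes all three; \code{reason_dropped}
#' records the first failing filter in the order cv, linearity, missing.
#'
#' @param table a \linkS4class{MetaboExperiment}.
#' @param maxCv QC CV threshold (strict, default 0.30).
#' @param minR2 dilution linearity threshold (inclusive, default 0.8).
#' @param excludeFeatures optional character vector of features to drop
#'   up-front (e.g. known isomer redundancies); they are removed from the
#'   report entirely.
#' @return a \linkS4class{FilterReport}.
#' @export
filterFeatures <- function(table, maxCv = 0.30, minR2 = 0.8,
                           excludeFeatures = character(0)) {
    if (length(excludeFeatures))
        table <- table[setdiff(rownames(table), excludeFeatures), ]
    cvR <- filterStats(qcCvFilter(table, maxCv))
    liR <- filterStats(dilutionLinearityFilter(table, minR2))
    coR <- filterStats(completenessFilter(table))
    st <- .emptyFilterStats(rownames(table))
    st$qc_cv <- cvR$qc_cv
    st$dilution_r2 <- liR$dilution_r2
    st$complete <- coR$complete
    st$reason_dropped[coR$reason_dropped == "missing"] <- "missing"
    st$reason_dropped[liR$reason_dropped == "linearity"] <- "linearity"
    st$reason_dropped[cvR$reason_dropped == "cv"] <- "cv"
    .asFilterReport(st, list(max_cv = maxCv, min_r2 = minR2,
                             excluded = excludeFeatures))
}

#' @rdname FilterReport
#' @export
setMethod("filterStats", "FilterReport", function(object) object@stats)

#' @rdname FilterReport
#' @export
setMethod("retainedFeatures", "FilterReport",
          function(object) object@stats$feature_id[object@stats$retained])

setMethod("show", "FilterReport", function(object) {
    st <- object@stats
    cat("FilterReport:", nrow(st), "features,", sum(st$retained), "retained\n")
    tab <- table(st$reason_dropped[!st$retained])
    if (length(tab))
        cat("  dropped:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

#' Log transformation and Pareto scaling
#'
#' Builds the statistical matrix from the study (case/control) samples of
#' the retained features: per feature, intensities are log-transformed,
#' mean-centred and divided by the square root of the log-scale standard
#' deviation (Pareto scaling). After scaling each column has mean zero and
#' variance equal to its log-scale standard deviation. QC and dilution
#' samples are excluded. Zero or negative intensities raise an error naming
#' the feature; zero-variance features are dropped with a warning.
#'
#' @param table a \linkS4class{MetaboExperiment} (typically drift-corrected).
#' @param report optional \linkS4class{FilterReport}; only retained features
#'   enter the matrix.
#' @param base log base: \code{"natural"} (default), \code{"log2"} or
#'   \code{"log10"}.
#' @return a \linkS4class{ProcessedMatrix}.
#' @export
logParetoTransform <- function(table, report = NULL,
                               base = c("natural", "log2", "log10")) {
    base <- match.arg(base)
    keep <- if (is.null(report)) rownames(table) else retainedFeatures(report)
    study <- studySamples(table)
    x <- t(assay(table, "intensity")[keep, study, drop = FALSE])
    if (anyNA(x) || any(x <= 0)) {
        bad <- colnames(x)[apply(x, 2, function(v) anyNA(v) || any(v <= 0))]
        stop("non-positive or missing study intensities in feature(s): ",
             paste(bad, collapse = ", "))
    }
    lx <- switch(base, natural = log(x), log2 = log2(x), log10 = log10(x))
    m <- colMeans(lx)
    s <- apply(lx, 2, stats::sd)
    zeroVar <- s == 0
    if (any(zeroVar)) {
        warning("dropping zero-variance feature(s): ",
                paste(colnames(x)[zeroVar], collapse = ", "))
        lx <- lx[, !zeroVar, drop = FALSE]
        m <- m[!zeroVar]; s <- s[!zeroVar]
    }
    z <- sweep(sweep(lx, 2, m, "-"), 2, sqrt(s), "/")
    cls <- factor(colData(table)$role[study], levels = c("control", "case"))
    new("ProcessedMatrix", values = z, logBase = base,
        featureMeans = m, featureSds = s, sampleClass = cls,
        provenance = list(
            filter_report = report, log_base = base,
            dropped_zero_variance = colnames(x)[zeroVar]))
}

setMethod("show", "ProcessedMatrix", function(object) {
    cat("ProcessedMatrix:", nrow(object@values), "study samples x",
        ncol(object@values), "features (", object@logBase,
        "log, Pareto scaled )\n")
})
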