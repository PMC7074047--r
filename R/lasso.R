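#' Construct a stability-selection configuration
#'
#' Defaults follow the published procedure: 1000 stratified ~2/3 train / 1/3
#' test splits, test AUC >= 0.8 defining good models and >= 0.9 excellent
#' ones, and group thresholds expressed as fractions of the excellent-model
#' count (250/303 and 100/303, the study's absolute cut-offs rescaled so the
#' procedure works at any number of splits).
#'
#' @param nSplits,trainFraction,aucGood,aucExcellent,thrI,thrII,lambdaRule,nFoldsInner,seed
#'   see \linkS4class{StabilityConfig}.
#' @return a \linkS4class{StabilityConfig}.
#' @export
stabilityConfig <- function(nSplits = 1000, trainFraction = 2 / 3,
                            aucGood = 0.8, aucExcellent = 0.9,
                            thrI = 250 / 303, thrII = 100 / 303,
                            lambdaRule = c("1se", "min"),
                            nFoldsInner = 5, seed = 1) {
    new("StabilityConfig", nSplits = as.integer(nSplits),
        trainFraction = trainFraction, aucGood = aucGood,
        aucExcellent = aucExcellent, thrI = thrI, thrII = thrII,
        lambdaRule = match.arg(lambdaRule),
        nFoldsInner = as.integer(nFoldsInner), seed = as.integer(seed))
}

#' Resampled-LASSO stability selection
#'
#' Repeatedly splits the cohort into stratified training (~2/3 of each
#' class) and test sets, fits an L1-penalised logistic regression on each
#' training set (penalty chosen by internal cross-validation on the training
#' set only), and scores the held-out test set by AUC. If the median test
#' AUC falls below \code{aucGood} the whole selection is marked invalid.
#' Otherwise, over the excellent models (test AUC >= \code{aucExcellent}),
#' each feature's selection frequency F (models with a non-zero coefficient)
#' and median coefficient C are computed, and features are assigned to
#' group I (F >= thrI * nExcellent), II (thrII * nExcellent <= F < thrI *
#' nExcellent) or III.
#'
#' One child seed is spawned per split from the master seed, so results are
#' reproducible and invariant to feature column order.
#'
#' @param x samples-by-features matrix or \linkS4class{ProcessedMatrix}.
#' @param y class factor (ignored for a ProcessedMatrix).
#' @param config a \linkS4class{StabilityConfig}.
#' @param positiveClass class coded 1 in the logistic model, so positive
#'   coefficients mean higher values in that class.
#' @return a \linkS4class{StabilityResult}.
#' @export
runStabilitySelection <- function(x, y = NULL, config = stabilityConfig(),
                                  positiveClass = NULL) {
    if (is(x, "ProcessedMatrix")) {
        y <- x@sampleClass
        if (is.null(positiveClass)) positiveClass <- "case"
        x <- x@values
    }
    x <- as.matrix(x)
    if (is.null(colnames(x))) colnames(x) <- sprintf("X%03d", seq_len(ncol(x)))
    validObject(config)
    cc <- .codeClasses(y, positiveClass)
    y <- cc$y
    if (min(table(y)) < 4) stop("each class needs at least 4 samples")
    ## glmnet's binomial family models the second level
    y2 <- factor(as.character(y),
                 levels = c(setdiff(levels(y), cc$positive), cc$positive))

    set.seed(config@seed)
    childSeeds <- sample.int(.Machine$integer.max - 1L, config@nSplits)
    J <- ncol(x)
    aucs <- numeric(config@nSplits)
    coefs <- matrix(0, config@nSplits, J, dimnames = list(NULL, colnames(x)))
    for (s in seq_len(config@nSplits)) {
        set.seed(childSeeds[s])
        tr <- integer(0)
        for (lv in levels(y2)) {
            cl <- which(y2 == lv)
            tr <- c(tr, sample(cl, round(config@trainFraction * length(cl))))
        }
        te <- setdiff(seq_len(nrow(x)), tr)
        foldId <- .stratifiedFolds(y2[tr], config@nFoldsInner)
        ## tight convergence threshold so the selected support does not
        ## depend on the coordinate-descent iterate order (= column order)
        cvfit <- glmnet::cv.glmnet(
            x[tr, , drop = FALSE], y2[tr], family = "binomial",
            alpha = 1, foldid = foldId, standardize = TRUE, thresh = 1e-10)
        lam <- if (config@lambdaRule == "1se") cvfit$lambda.1se else
            cvfit$lambda.min
        beta <- as.numeric(stats::coef(cvfit, s = lam))[-1]
        pred <- stats::predict(cvfit, x[te, , drop = FALSE], s = lam,
                               type = "link")
        aucs[s] <- rocAuc(drop(pred), y2[te], positiveClass = cc$positive)
        coefs[s, ] <- beta
    }
    exc <- which(aucs >= config@aucExcellent)
    nExc <- length(exc)
    Fcnt <- if (nExc) as.integer(colSums(coefs[exc, , drop = FALSE] != 0))
            else integer(J)
    Cmed <- if (nExc) apply(coefs[exc, , drop = FALSE], 2, stats::median)
            else rep(NA_real_, J)
    grp <- rep("III", J)
    if (nExc) {
        grp[Fcnt >= config@thrII * nExc] <- "II"
        grp[Fcnt >= config@thrI * nExc] <- "I"
    }
    valid <- stats::median(aucs) >= config@aucGood && nExc > 0
    new("StabilityResult",
        featureIds = colnames(x),
        freq = setNames(Fcnt, colnames(x)),
        coefMedian = setNames(Cmed, colnames(x)),
        group = factor(grp, levels = c("I", "II", "III")),
        splitAuc = aucs,
        nGood = sum(aucs >= config@aucGood),
        nExcellent = as.integer(nExc),
        medianAuc = stats::median(aucs), meanAuc = mean(aucs),
        valid = valid,
        excellentCoefs = coefs[exc, , drop = FALSE],
        config = config)
}

#' @rdname StabilityResult
#' @export
setMethod("selectionFrequency", "StabilityResult", function(object) object@freq)

#' @rdname StabilityResult
#' @export
setMethod("medianCoefficient", "StabilityResult", function(object) object@coefMedian)

#' @rdname StabilityResult
#' @export
setMethod("stabilityGroup", "StabilityResult",
          function(object) setNames(object@group, object@featureIds))

setMethod("show", "StabilityResult", function(object) {
    cat("StabilityResult:", length(object@splitAuc), "splits;",
        "median test AUC", round(object@medianAuc, 3), "\n")
    cat("  good models:", object@nGood, "; excellent:", object@nExcellent,
        if (!object@valid) "; selection INVALID (good-model gate failed)" else "",
        "\n")
    if (object@valid)
        print(table(object@group))
})

#' Y-plot coordinates
#'
#' One row per feature: the median coefficient C (x axis), the selection
#' frequency F (y axis), the stability group, and the direction implied by
#' the coefficient sign (\code{"up"}/\code{"down"}/\code{"null"}). The
#' vertical branch of the Y collects features with null median
#' coefficients; the left and right upper branches carry the decreased and
#' increased features.
#'
#' @param result a valid \linkS4class{StabilityResult}.
#' @return [S4Vectors::DataFrame] with columns \code{feature_id}, \code{C},
#'   \code{F}, \code{group}, \code{direction}.
#' @export
yplotData <- function(result) {
    if (!result@valid)
        stop("stability selection is invalid (good-model gate failed)")
    S4Vectors::DataFrame(
        feature_id = result@featureIds,
        C = result@coefMedian, F = result@freq, group = result@group,
        direction = ifelse(result@coefMedian > 0, "up",
                           ifelse(result@coefMedian < 0, "down", "null")),
        row.names = result@featureIds)
}

#' Final LASSO-branch feature selection
#'
#' Restricts the group-I features (most frequently selected among excellent
#' models) by the OPLS-DA importance and the univariate significance:
#' selected = group I with VIP >= \code{vipMin} (inclusive) and q <
#' \code{qMax}.
#'
#' @param result a \linkS4class{StabilityResult}, or directly a character
#'   vector of group-I feature identifiers.
#' @param stats per-feature statistics with columns \code{feature_id} and
#'   \code{q} (e.g. from [univariateStats()]); must cover every group-I
#'   feature.
#' @param vip named numeric vector of VIP values covering group I.
#' @param vipMin VIP threshold (default 1.3, inclusive).
#' @param qMax q-value threshold (default 0.05, strict).
#' @return character vector of selected feature identifiers.
#' @export
selectLassoFeatures <- function(result, stats, vip, vipMin = 1.3,
                                qMax = 0.05) {
    groupI <- if (is(result, "StabilityResult")) {
        if (!result@valid)
            stop("stability selection is invalid (good-model gate failed)")
        result@featureIds[result@group == "I"]
    } else as.character(result)
    if (!length(groupI)) return(character(0))
    q <- setNames(stats$q, stats$feature_id)
    missQ <- setdiff(groupI, names(q))
    missV <- setdiff(groupI, names(vip))
    if (length(missQ) || length(missV))
        stop("missing statistics for group-I feature(s): ",
             paste(unique(c(missQ, missV)), collapse = ", "))
    ok <- !is.na(vip[groupI]) & vip[groupI] >= vipMin &
        !is.na(q[groupI]) & q[groupI] < qMax
    groupI[ok]
}
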