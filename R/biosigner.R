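## Internal single-component PLS1 classifier used by the wrapper.
.pls1Train <- function(x, y, positiveClass) {
    cc <- .codeClasses(y, positiveClass)
    xm <- colMeans(x)
    Xc <- sweep(x, 2, xm, "-")
    yc <- cc$num - mean(cc$num)
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    w <- if (nw > 0) w / nw else w
    t <- drop(Xc %*% w)
    b <- if (sum(t^2) > 0) sum(t * yc) / sum(t^2) else 0
    list(w = w, b = b, xm = xm, ym = mean(cc$num),
         positive = cc$positive, levels = levels(cc$y))
}

.pls1Predict <- function(fit, x) {
    yhat <- fit$b * drop(sweep(x, 2, fit$xm, "-") %*% fit$w) + fit$ym
    other <- setdiff(fit$levels, fit$positive)
    factor(ifelse(yhat > 0, fit$positive, other), levels = fit$levels)
}

.trainClassifier <- function(kind, x, y, positiveClass, ntree) {
    switch(kind,
        plsda = .pls1Train(x, y, positiveClass),
        rf = randomForest::randomForest(x = x, y = y, ntree = ntree),
        svm = e1071::svm(x = x, y = y, kernel = "linear", scale = FALSE))
}

.predictClassifier <- function(kind, fit, x) {
    if (kind == "plsda") return(.pls1Predict(fit, x))
    stats::predict(fit, x)
}

.importance <- function(kind, fit, x, y, positiveClass) {
    switch(kind,
        plsda = abs(fit$w),
        rf = fit$importance[, "MeanDecreaseGini"],
        svm = {
            w <- drop(crossprod(fit$coefs, fit$SV))
            abs(w)[colnames(x)]
        })
}

#' Balanced classification accuracy
#'
#' Mean of the per-class accuracies over the classes present in
#' \code{truth}; robust to unequal class sizes.
#'
#' @param truth,pred factors of true and predicted labels.
#' @return balanced accuracy in [0, 1].
#' @export
balancedAccuracy <- function(truth, pred) {
    truth <- as.factor(truth)
    lv <- unique(as.character(truth))
    mean(vapply(lv, function(l)
        mean(as.character(pred)[truth == l] == l), numeric(1)))
}

## Stratified bootstrap: per class, sample with replacement to the class size.
.stratifiedBootstrap <- function(y) {
    idx <- integer(0)
    for (lv in levels(y)) {
        cl <- which(y == lv)
        idx <- c(idx, sample(cl, length(cl), replace = TRUE))
    }
    idx
}

## Paired permutation p-value: fraction of resamplings in which the
## permuted-data accuracy matches or exceeds the observed accuracy (add-one
## correction). Draw-level comparison keeps the test calibrated: the
## bootstraps all share the one dataset, so pooling them as independent
## evidence (e.g. a sign test) would let small dataset-level chance
## patterns reach significance on pure-noise data.
.permTestP <- function(accObs, accPerm) {
    ok <- !is.na(accObs) & !is.na(accPerm)
    if (!any(ok)) return(1)
    (1 + sum(accPerm[ok] >= accObs[ok])) / (1 + sum(ok))
}

#' Bootstrapped wrapper feature selection (S tier)
#'
#' For each of three classifiers (single-component PLS-DA, random forest,
#' linear SVM), runs an iterative selection wrapped around stratified
#' bootstrap resampling: features are ranked by the classifier's importance
#' averaged over bootstraps, and a binary search over the ranked list finds
#' the smallest prefix whose out-of-bag accuracy significantly exceeds the
#' accuracy obtained after randomly permuting those features' intensities
#' within the out-of-bag samples (paired permutation p-value across
#' bootstraps at \code{pThreshold}; with 50 bootstraps the smallest
#' attainable p is 1/51, so a prefix must dominate its permuted counterpart
#' in essentially every resampling). The search repeats on the surviving
#' subset until it stops shrinking; the fixed point is the classifier's S
#' tier. When even the full feature set does not beat its permuted version,
#' the tier is empty.
#'
#' @param x samples-by-features matrix or \linkS4class{ProcessedMatrix}.
#' @param y class factor (ignored for a ProcessedMatrix).
#' @param nBoot bootstrap draws per evaluation (>= 10, default 50).
#' @param pThreshold significance threshold of the permutation comparison
#'   (default 0.05).
#' @param seed RNG seed; identical seeds give identical tiers.
#' @param classifiers subset of \code{c("plsda", "rf", "svm")}.
#' @param positiveClass class treated as positive.
#' @param ntree random-forest tree count (default 100).
#' @param maxRounds safety bound on selection rounds.
#' @return a \linkS4class{BiosignerResult}.
#' @export
biosignerSelect <- function(x, y = NULL, nBoot = 50, pThreshold = 0.05,
                            seed = 1, classifiers = c("plsda", "rf", "svm"),
                            positiveClass = NULL, ntree = 100,
                            maxRounds = 10) {
    if (is(x, "ProcessedMatrix")) {
        y <- x@sampleClass
        if (is.null(positiveClass)) positiveClass <- "case"
        x <- x@values
    }
    x <- as.matrix(x)
    if (is.null(colnames(x))) colnames(x) <- sprintf("X%03d", seq_len(ncol(x)))
    if (nBoot < 10) stop("nBoot must be >= 10")
    cc <- .codeClasses(y, positiveClass)
    y <- cc$y
    if (min(table(y)) < 4) stop("each class needs at least 4 samples")
    classifiers <- match.arg(classifiers, several.ok = TRUE)
    set.seed(seed)

    tiers <- list()
    acc <- setNames(rep(NA_real_, length(classifiers)), classifiers)
    for (kind in classifiers) {
        feats <- colnames(x)
        converged <- FALSE
        for (round in seq_len(maxRounds)) {
            boots <- replicate(nBoot, .stratifiedBootstrap(y), simplify = FALSE)
            oobPerm <- lapply(boots, function(b) {
                oob <- setdiff(seq_len(nrow(x)), unique(b))
                list(oob = oob, perm = sample(oob))
            })
            ## importance averaged over the bootstraps
            impSum <- numeric(length(feats))
            for (b in boots) {
                fit <- .trainClassifier(kind, x[b, feats, drop = FALSE],
                                        y[b], cc$positive, ntree)
                impSum <- impSum +
                    .importance(kind, fit, x[b, feats, drop = FALSE],
                                y[b], cc$positive)
            }
            ranked <- feats[order(impSum, decreasing = TRUE)]

            evalPrefix <- function(k) {
                sub <- ranked[seq_len(k)]
                accObs <- accPerm <- rep(NA_real_, nBoot)
                for (i in seq_len(nBoot)) {
                    b <- boots[[i]]
                    op <- oobPerm[[i]]
                    if (length(op$oob) < 2 ||
                        length(unique(y[op$oob])) < 2) next
                    fit <- .trainClassifier(kind, x[b, sub, drop = FALSE],
                                            y[b], cc$positive, ntree)
                    xo <- x[op$oob, sub, drop = FALSE]
                    accObs[i] <- balancedAccuracy(
                        y[op$oob], .predictClassifier(kind, fit, xo))
                    xp <- x[op$perm, sub, drop = FALSE]
                    rownames(xp) <- rownames(xo)
                    accPerm[i] <- balancedAccuracy(
                        y[op$oob], .predictClassifier(kind, fit, xp))
                }
                .permTestP(accObs, accPerm)
            }

            if (evalPrefix(length(ranked)) >= pThreshold) {
                feats <- character(0)
                converged <- TRUE
                break
            }
            lo <- 1L; hi <- length(ranked)
            while (lo < hi) {
                mid <- (lo + hi) %/% 2L
                if (evalPrefix(mid) < pThreshold) hi <- mid else lo <- mid + 1L
            }
            keep <- ranked[seq_len(hi)]
            if (length(keep) == length(feats)) {
                feats <- keep
                converged <- TRUE
                break
            }
            feats <- keep
        }
        if (!converged) {
            warning("wrapper selection did not converge for ", kind,
                    "; returning empty tier")
            feats <- character(0)
        }
        tiers[[kind]] <- feats
    }
    res <- new("BiosignerResult", tiers = tiers, accuracies = acc,
               featureIds = colnames(x), nBoot = as.integer(nBoot),
               pThreshold = pThreshold, seed = as.integer(seed))
    res@accuracies <- signatureAccuracy(res, x, y, ntree = ntree)
    res
}

#' Out-of-bag accuracy of the S-tier signature
#'
#' Refits each classifier on its S-tier features over stratified bootstrap
#' draws and reports the mean out-of-bag balanced accuracy. Classifiers with
#' an empty tier are reported as \code{NA}.
#'
#' @param result a \linkS4class{BiosignerResult}.
#' @param x,y the data the selection ran on.
#' @param nBoot bootstrap draws (default: the selection's setting).
#' @param ntree random-forest tree count.
#' @return named numeric vector of per-classifier accuracies.
#' @export
signatureAccuracy <- function(result, x, y, nBoot = result@nBoot,
                              ntree = 100) {
    if (is(x, "ProcessedMatrix")) {
        y <- x@sampleClass
        x <- x@values
    }
    cc <- .codeClasses(y)
    y <- cc$y
    out <- setNames(rep(NA_real_, length(result@tiers)), names(result@tiers))
    set.seed(result@seed + 1L)
    for (kind in names(result@tiers)) {
        sub <- result@tiers[[kind]]
        if (!length(sub)) next
        accs <- rep(NA_real_, nBoot)
        for (i in seq_len(nBoot)) {
            b <- .stratifiedBootstrap(y)
            oob <- setdiff(seq_len(nrow(x)), unique(b))
            if (length(oob) < 2 || length(unique(y[oob])) < 2) next
            fit <- .trainClassifier(kind, x[b, sub, drop = FALSE],
                                    y[b], cc$positive, ntree)
            accs[i] <- balancedAccuracy(
                y[oob],
                .predictClassifier(kind, fit, x[oob, sub, drop = FALSE]))
        }
        out[kind] <- mean(accs, na.rm = TRUE)
    }
    out
}

#' @rdname BiosignerResult
#' @export
setMethod("tiers", "BiosignerResult", function(object) object@tiers)

setMethod("show", "BiosignerResult", function(object) {
    cat("BiosignerResult (", object@nBoot, "bootstraps, p <",
        object@pThreshold, ")\n")
    for (k in names(object@tiers)) {
        s <- object@tiers[[k]]
        cat(sprintf("  %-6s S tier: %s", k,
                    if (length(s)) paste(s, collapse = ", ") else "(empty)"))
        if (!is.na(object@accuracies[k]))
            cat(sprintf("  [balanced accuracy %.3f]", object@accuracies[k]))
        cat("\n")
    }
})
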