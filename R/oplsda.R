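## Numeric class coding: +1 for the positive class, -1 otherwise.
.codeClasses <- function(y, positiveClass = NULL) {
    y <- droplevels(as.factor(y))
    if (nlevels(y) != 2)
        stop("exactly two classes are required (got ", nlevels(y), ")")
    if (is.null(positiveClass)) positiveClass <- levels(y)[2]
    if (!positiveClass %in% levels(y))
        stop("positiveClass '", positiveClass, "' not a level of y")
    list(y = y, positive = positiveClass,
         num = ifelse(y == positiveClass, 1, -1))
}

## Core fit on a centred matrix; returns the raw component bookkeeping.
.oplsCore <- function(Xc, yc, nOrth) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop("class code is uncorrelated with every feature")
    w <- w / nw
    J <- ncol(Xc)
    Wo <- matrix(0, J, nOrth)
    Po <- matrix(0, J, nOrth)
    To <- matrix(0, nrow(Xc), nOrth)
    E <- Xc
    for (a in seq_len(nOrth)) {
        t <- drop(E %*% w)
        p <- drop(crossprod(E, t)) / sum(t^2)
        wo <- p - sum(w * p) * w
        nwo <- sqrt(sum(wo^2))
        if (nwo < 1e-12)
            stop("no orthogonal variation left at component ", a)
        wo <- wo / nwo
        to <- drop(E %*% wo)
        po <- drop(crossprod(E, to)) / sum(to^2)
        E <- E - tcrossprod(to, po)
        Wo[, a] <- wo; Po[, a] <- po; To[, a] <- to
    }
    t <- drop(E %*% w)
    p <- drop(crossprod(E, t)) / sum(t^2)
    b <- sum(t * yc) / sum(t^2)
    list(w = w, p = p, t = t, b = b, Wo = Wo, Po = Po, To = To)
}

.fitOplsdaMatrix <- function(x, y, nOrth = 1, positiveClass = NULL) {
    x <- as.matrix(x)
    if (is.null(colnames(x))) colnames(x) <- sprintf("X%03d", seq_len(ncol(x)))
    cc <- .codeClasses(y, positiveClass)
    if (min(table(cc$y)) < 3)
        stop("each class needs at least 3 samples")
    nOrth <- as.integer(nOrth)
    rk <- qr(scale(x, scale = FALSE))$rank
    if (nOrth >= rk)
        stop("nOrth (", nOrth, ") must be smaller than rank(X) = ", rk)
    xMeans <- colMeans(x)
    Xc <- sweep(x, 2, xMeans, "-")
    yMean <- mean(cc$num)
    yc <- cc$num - yMean
    fit <- .oplsCore(Xc, yc, nOrth)
    ## canonical sign: predictive score positively correlated with the class code
    if (fit$b < 0) {
        fit$w <- -fit$w; fit$p <- -fit$p; fit$t <- -fit$t; fit$b <- -fit$b
    }
    res <- yc - fit$b * fit$t
    R2Y <- 1 - sum(res^2) / sum(yc^2)
    J <- ncol(x)
    vip <- sqrt(J) * abs(fit$w)   # single predictive component, ||w|| = 1
    sdT <- stats::sd(fit$t)
    p1 <- drop(crossprod(Xc, fit$t)) / (nrow(x) - 1)
    sdX <- apply(Xc, 2, stats::sd)
    pcorr1 <- ifelse(sdX > 0 & sdT > 0, p1 / (sdT * sdX), 0)
    splot <- S4Vectors::DataFrame(feature_id = colnames(x),
                                  p1 = p1, pcorr1 = pcorr1,
                                  row.names = colnames(x))
    new("OplsdaModel",
        weights = setNames(fit$w, colnames(x)),
        loadings = setNames(fit$p, colnames(x)),
        scores = setNames(fit$t, rownames(x)),
        orthoWeights = fit$Wo, orthoLoadings = fit$Po, orthoScores = fit$To,
        b = fit$b, yMean = yMean, xMeans = xMeans,
        R2Y = max(0, min(1, R2Y)), vip = setNames(vip, colnames(x)),
        splot = splot, nOrth = nOrth, X = x, y = cc$y,
        positiveClass = cc$positive)
}

#' @rdname fitOplsda
#' @param y class factor (matrix method).
#' @param nOrth number of orthogonal components (default 1; 0 reduces the
#'   model to single-component PLS1).
#' @param positiveClass factor level coded +1.
#' @export
setMethod("fitOplsda", "matrix",
          function(x, y, nOrth = 1, positiveClass = NULL, ...)
              .fitOplsdaMatrix(x, y, nOrth, positiveClass))

#' @rdname fitOplsda
#' @export
setMethod("fitOplsda", "ProcessedMatrix",
          function(x, nOrth = 1, positiveClass = "case", ...)
              .fitOplsdaMatrix(x@values, x@sampleClass, nOrth, positiveClass))

#' @rdname OplsdaModel
#' @param ... unused.
#' @export
setMethod("vip", "OplsdaModel", function(object, ...) object@vip)

#' @rdname OplsdaModel
#' @export
setMethod("splotData", "OplsdaModel", function(object) object@splot)

setMethod("show", "OplsdaModel", function(object) {
    cat("OplsdaModel: 1 predictive +", object@nOrth,
        "orthogonal component(s) on", nrow(object@X), "samples x",
        ncol(object@X), "features\n")
    cat(sprintf("  R2Y = %.3f; positive class: %s\n",
                object@R2Y, object@positiveClass))
})

#' Variable importance in the projection
#'
#' VIP over the predictive component: VIP_j = sqrt(J) * |w_j| with the
#' weight vector normalised to unit length, so the squared VIPs average to
#' one across the J features. \code{mode = "total"} additionally spreads the
#' orthogonal components' X-variance over their weights (a common OPLS
#' extension); the predictive mode is the default since only the predictive
#' component carries class information.
#'
#' @param model an \linkS4class{OplsdaModel}.
#' @param mode \code{"predictive"} or \code{"total"}.
#' @return named numeric vector of VIP scores.
#' @export
computeVip <- function(model, mode = c("predictive", "total")) {
    mode <- match.arg(mode)
    if (mode == "predictive") return(model@vip)
    J <- length(model@weights)
    Xc <- sweep(model@X, 2, model@xMeans, "-")
    ssxTot <- sum(Xc^2)
    ssx <- c(sum(tcrossprod(model@scores, model@loadings)^2),
             if (model@nOrth > 0)
                 vapply(seq_len(model@nOrth), function(a)
                     sum(tcrossprod(model@orthoScores[, a],
                                    model@orthoLoadings[, a])^2),
                     numeric(1)))
    W <- cbind(model@weights, model@orthoWeights)
    w2 <- sweep(W^2, 2, colSums(W^2), "/")
    v <- sqrt(J * drop(w2 %*% ssx) / sum(ssx))
    setNames(v, names(model@weights))
}

#' Predict scores and class codes for new samples
#'
#' Centres the new data with the training means, strips the orthogonal
#' components, and projects onto the predictive component.
#'
#' @param model an \linkS4class{OplsdaModel}.
#' @param newdata samples-by-features matrix with the training features.
#' @return list with \code{t} (predictive scores), \code{yhat} (predicted
#'   class code) and \code{class} (predicted labels).
#' @export
predictOplsda <- function(model, newdata) {
    Xn <- sweep(as.matrix(newdata)[, names(model@weights), drop = FALSE],
                2, model@xMeans, "-")
    if (model@nOrth > 0)
        for (a in seq_len(model@nOrth)) {
            to <- drop(Xn %*% model@orthoWeights[, a])
            Xn <- Xn - tcrossprod(to, model@orthoLoadings[, a])
        }
    t <- drop(Xn %*% model@weights)
    yhat <- model@b * t + model@yMean
    lv <- levels(model@y)
    other <- setdiff(lv, model@positiveClass)
    cls <- factor(ifelse(yhat > 0, model@positiveClass, other), levels = lv)
    list(t = t, yhat = yhat, class = cls)
}

## Stratified fold assignment; consumes the current RNG stream.
.stratifiedFolds <- function(y, folds) {
    y <- as.factor(y)
    if (any(table(y) < folds) && folds > 2)
        folds <- min(folds, min(table(y)))
    id <- integer(length(y))
    for (lv in levels(y)) {
        idx <- which(y == lv)
        id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    id
}

#' Cross-validated Q2 and CV-ANOVA
#'
#' Stratified k-fold cross-validation of the OPLS-DA model:
#' Q2 = 1 - PRESS / SSY over held-out class-code predictions. The CV-ANOVA
#' p-value comes from an F-test comparing the cross-validated residual sum
#' of squares of the model against the residuals about the class-code mean,
#' with one degree of freedom per fitted component.
#'
#' @param model an \linkS4class{OplsdaModel}.
#' @param folds number of stratified folds (default 7, must be >= 2).
#' @param seed seed for the fold assignment.
#' @return list with \code{Q2}, \code{cvAnovaP}, \code{press}, \code{ssy}.
#' @export
crossValidateOplsda <- function(model, folds = 7, seed = 1) {
    if (folds < 2) stop("folds must be >= 2")
    set.seed(seed)
    y <- model@y
    foldId <- .stratifiedFolds(y, folds)
    cc <- .codeClasses(y, model@positiveClass)
    press <- 0
    for (k in unique(foldId)) {
        tr <- foldId != k
        if (length(unique(y[tr])) < 2)
            stop("a training fold lost one class; reduce folds")
        m <- .fitOplsdaMatrix(model@X[tr, , drop = FALSE], y[tr],
                              model@nOrth, model@positiveClass)
        pr <- predictOplsda(m, model@X[!tr, , drop = FALSE])
        press <- press + sum((cc$num[!tr] - pr$yhat)^2)
    }
    ssy <- sum((cc$num - mean(cc$num))^2)
    Q2 <- 1 - press / ssy
    dfModel <- 1 + model@nOrth
    dfResid <- length(y) - dfModel - 1
    Fstat <- ((ssy - press) / dfModel) / (press / dfResid)
    p <- if (Fstat <= 0) 1 else
        stats::pf(Fstat, dfModel, dfResid, lower.tail = FALSE)
    list(Q2 = Q2, cvAnovaP = p, press = press, ssy = ssy)
}

#' Permutation test of the OPLS-DA model
#'
#' Refits the model on \code{nPerm} random label permutations, records each
#' permuted fit's R2Y and cross-validated Q2 together with the absolute
#' correlation between the permuted and original class codes, and reports
#' the intercepts (at correlation zero) of straight lines fitted through the
#' permuted points plus the unpermuted model at correlation one.
#'
#' @param model an \linkS4class{OplsdaModel}.
#' @param nPerm number of permutations (>= 20, default 200).
#' @param folds folds for the Q2 of each permuted fit.
#' @param seed RNG seed.
#' @return list with \code{permR2Intercept}, \code{permQ2Intercept},
#'   \code{trueQ2}, \code{trueR2Y} and the per-permutation table
#'   \code{perms}.
#' @export
permutationTestOplsda <- function(model, nPerm = 200, folds = 7, seed = 1) {
    if (nPerm < 20) stop("nPerm must be >= 20")
    set.seed(seed)
    cc <- .codeClasses(model@y, model@positiveClass)
    trueCv <- crossValidateOplsda(model, folds = folds, seed = seed)
    r2 <- q2 <- rho <- numeric(nPerm)
    for (i in seq_len(nPerm)) {
        yp <- sample(model@y)
        m <- .fitOplsdaMatrix(model@X, yp, model@nOrth, model@positiveClass)
        cv <- crossValidateOplsda(m, folds = folds, seed = seed + i)
        ccp <- .codeClasses(yp, model@positiveClass)
        r2[i] <- m@R2Y
        q2[i] <- cv$Q2
        rho[i] <- abs(stats::cor(cc$num, ccp$num))
    }
    xs <- c(rho, 1)
    fitR2 <- stats::lm.fit(cbind(1, xs), c(r2, model@R2Y))
    fitQ2 <- stats::lm.fit(cbind(1, xs), c(q2, trueCv$Q2))
    list(permR2Intercept = unname(fitR2$coefficients[1]),
         permQ2Intercept = unname(fitQ2$coefficients[1]),
         trueQ2 = trueCv$Q2, trueR2Y = model@R2Y,
         perms = data.frame(cor = rho, R2Y = r2, Q2 = q2))
}

#' Jack-knife confidence intervals for the predictive loadings
#'
#' Refits the model on each cross-validation training set, aligns the signs
#' of the per-round predictive loadings with the full-model loadings, and
#' reports a t-based confidence interval per feature. A feature whose
#' interval spans zero is flagged unstable.
#'
#' @param model an \linkS4class{OplsdaModel}.
#' @param folds number of cross-validation rounds (default 7).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed for the fold assignment.
#' @return [S4Vectors::DataFrame] with \code{loading}, \code{lower},
#'   \code{upper}, \code{stable}.
#' @export
jackknifeLoadings <- function(model, folds = 7, level = 0.95, seed = 1) {
    if (folds < 2) stop("folds must be >= 2")
    set.seed(seed)
    foldId <- .stratifiedFolds(model@y, folds)
    L <- matrix(NA_real_, length(unique(foldId)), length(model@loadings))
    for (k in seq_along(unique(foldId))) {
        tr <- foldId != unique(foldId)[k]
        m <- .fitOplsdaMatrix(model@X[tr, , drop = FALSE], model@y[tr],
                              model@nOrth, model@positiveClass)
        pl <- m@loadings
        if (sum(pl * model@loadings) < 0) pl <- -pl
        L[k, ] <- pl
    }
    mu <- colMeans(L)
    g <- nrow(L)
    ## delete-d jackknife variance over the g leave-group-out refits: the
    ## rounds share most of the data, so the naive sd/sqrt(g) would badly
    ## understate the loading uncertainty
    se <- sqrt((g - 1) / g * colSums(sweep(L, 2, mu, "-")^2))
    tq <- stats::qt(1 - (1 - level) / 2, df = g - 1)
    lower <- mu - tq * se
    upper <- mu + tq * se
    S4Vectors::DataFrame(
        feature_id = names(model@loadings),
        loading = mu, lower = lower, upper = upper,
        stable = lower > 0 | upper < 0,
        row.names = names(model@loadings))
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive-class score exceeds a
#' randomly chosen negative-class score, ties counting one half
#' (Mann-Whitney convention). Computed from midranks.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels class labels (factor or character).
#' @param positiveClass the positive level (default: last factor level).
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels, positiveClass = NULL) {
    cc <- .codeClasses(labels, positiveClass)
    pos <- cc$num > 0
    n1 <- sum(pos); n0 <- sum(!pos)
    r <- rank(scores)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' OPLS-DA feature selection
#'
#' Selects putative biomarkers by combining the three OPLS-DA reliability
#' criteria: VIP strictly greater than \code{vipMin}; the S-plot
#' correlation-loading criterion |p(corr)| >= \code{pcorrMin} (0.4 is the
#' customary cut-off for calling a feature influential on an S-plot; set to
#' 0 to disable); and, when \code{requireStable}, a jack-knife loading
#' confidence interval excluding zero.
#'
#' @param model an \linkS4class{OplsdaModel}.
#' @param vipMin VIP threshold (default 1.3, strict).
#' @param pcorrMin S-plot |p(corr)| threshold (default 0.4, inclusive).
#' @param requireStable require jack-knife-stable loadings (default TRUE).
#' @param folds,seed forwarded to [jackknifeLoadings()].
#' @return character vector of selected feature identifiers.
#' @export
selectOplsda <- function(model, vipMin = 1.3, pcorrMin = 0.4,
                         requireStable = TRUE, folds = 7, seed = 1) {
    sel <- model@vip > vipMin
    if (pcorrMin > 0)
        sel <- sel & abs(model@splot$pcorr1) >= pcorrMin
    if (requireStable) {
        jk <- jackknifeLoadings(model, folds = folds, seed = seed)
        sel <- sel & jk$stable
    }
    names(model@vip)[sel]
}
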