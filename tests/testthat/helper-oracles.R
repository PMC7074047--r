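# Independent oracles used to cross-check the package implementations.

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of the
# C(n1+n2, n1) rank assignments (tie-free data only).
enumWilcoxonP <- function(case, control) {
    n1 <- length(case)
    n <- n1 + length(control)
    r <- rank(c(case, control))
    wObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U
    u <- apply(utils::combn(n, n1), 2,
               function(ix) sum(ix) - n1 * (n1 + 1) / 2)
    lower <- mean(u <= wObs)
    upper <- mean(u >= wObs)
    min(1, 2 * min(lower, upper))
}

# Step-up FDR adjustment written directly from the definition.
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    prev <- 1
    for (i in m:1) {
        prev <- min(prev, p[o[i]] * m / i)
        q[o[i]] <- prev
    }
    q
}

# AUC by brute-force pair counting (ties count one half).
aucPairOracle <- function(scores, labels, positive) {
    sPos <- scores[labels == positive]
    sNeg <- scores[labels != positive]
    tot <- 0
    for (a in sPos) for (b in sNeg)
        tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(sPos) * length(sNeg))
}

# Independent single-component NIPALS PLS1: iterate t/w updates from a
# random start until convergence (distinct code path from the package's
# direct covariance solution).
nipalsPls1 <- function(X, y) {
    Xc <- scale(X, scale = FALSE)
    yc <- y - mean(y)
    u <- yc
    wOld <- rep(0, ncol(Xc))
    for (it in 1:500) {
        w <- drop(crossprod(Xc, u)) / sum(u^2)
        w <- w / sqrt(sum(w^2))
        t <- drop(Xc %*% w)
        q <- sum(yc * t) / sum(t^2)
        u <- yc * q
        if (sum((w - wOld)^2) < 1e-14) break
        wOld <- w
    }
    list(w = w, t = t, b = sum(t * yc) / sum(t^2))
}

# Small cohorts used across tests.
smallCohort <- function(seed = 1, ...) {
    args <- list(nCase = 10, nControl = 10, nFeatures = 20, nJunkFeatures = 6,
                 seed = seed)
    over <- list(...)
    args[names(over)] <- over
    generateCohort(do.call(cohortSpec, args))
}

nullSpec <- function(seed, ...) {
    cohortSpec(plantedEffects = data.frame(feature = integer(0),
                                           fc = numeric(0)),
               seed = seed, ...)
}

processedFrom <- function(me) {
    logParetoTransform(suppressWarnings(correctDrift(me)), filterFeatures(me))
}

# Selections derived from the packaged published selection table.
table1Selections <- function(tbl = loadTable1Fixture()) {
    list(univariate = selectUnivariate(tbl),
         oplsda = as.character(tbl$feature_id[tbl$flag_oplsda]),
         biosigner = as.character(tbl$feature_id[tbl$flag_biosigner]),
         lasso = as.character(tbl$feature_id[tbl$flag_lasso]))
}
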