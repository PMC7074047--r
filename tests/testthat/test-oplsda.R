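test_that("with no orthogonal component the fit reduces to NIPALS PLS1", {
    set.seed(1)
    for (i in 1:5) {
        n <- 16; J <- 8
        X <- matrix(rnorm(n * J), n, J)
        y <- factor(rep(c("control", "case"), each = n / 2),
                    levels = c("control", "case"))
        m <- fitOplsda(X, y, nOrth = 0)
        yn <- ifelse(y == "case", 1, -1)
        o <- nipalsPls1(X, yn)
        s <- sign(sum(o$w * m@weights))
        expect_lt(max(abs(s * o$w - unname(m@weights))), 1e-8)
        expect_lt(max(abs(s * o$t - unname(m@scores))), 1e-8)
        expect_lt(abs(abs(o$b) - m@b), 1e-8)
    }
})

test_that("a rank-1 separable problem is fit perfectly", {
    y <- factor(rep(c("control", "case"), each = 5),
                levels = c("control", "case"))
    X <- cbind(f1 = ifelse(y == "case", 2, -2),
               f2 = rep(1, 10), f3 = rep(0, 10))
    m <- fitOplsda(X, y, nOrth = 0)
    expect_equal(m@R2Y, 1)
    expect_equal(unname(abs(m@splot["f1", "pcorr1"])), 1)
    expect_equal(unname(m@splot["f2", "pcorr1"]), 0) # zero-variance: defined 0
})

test_that("predictive scores are orthogonal to every orthogonal score", {
    me <- smallCohort(seed = 5)
    pm <- processedFrom(me)
    for (k in 1:2) {
        m <- fitOplsda(pm, nOrth = k)
        ip <- abs(crossprod(m@scores, m@orthoScores))
        expect_true(all(ip < 1e-8))
    }
})

test_that("swapping the class coding flips scores but not VIP, R2Y or AUC", {
    me <- smallCohort(seed = 6)
    pm <- processedFrom(me)
    a <- fitOplsda(pm@values, pm@sampleClass, nOrth = 1,
                   positiveClass = "case")
    b <- fitOplsda(pm@values, pm@sampleClass, nOrth = 1,
                   positiveClass = "control")
    expect_equal(a@vip, b@vip, tolerance = 1e-10)
    expect_equal(a@R2Y, b@R2Y, tolerance = 1e-10)
    expect_equal(unname(a@scores), -unname(b@scores), tolerance = 1e-10)
    expect_equal(a@splot$pcorr1, -b@splot$pcorr1, tolerance = 1e-10)
    aucA <- rocAuc(a@scores, pm@sampleClass, positiveClass = "case")
    aucB <- rocAuc(-b@scores, pm@sampleClass, positiveClass = "case")
    expect_equal(aucA, aucB)
})

test_that("model fitting enforces its preconditions", {
    X <- matrix(rnorm(40), 10, 4)
    expect_error(fitOplsda(X, factor(rep("case", 10))), "two classes")
    y <- factor(rep(c("a", "b"), 5))
    expect_error(fitOplsda(X, y, nOrth = 10), "rank")
})

test_that("VIP has its normalisation fixed points", {
    y <- factor(rep(c("control", "case"), each = 6),
                levels = c("control", "case"))
    set.seed(7)
    # single feature: VIP is forced to 1
    X1 <- matrix(ifelse(y == "case", 1, -1) + rnorm(12, sd = 0.1), ncol = 1)
    expect_equal(unname(vip(fitOplsda(X1, y, nOrth = 0))), 1)
    # two features with identical information: VIP = (1, 1)
    base <- ifelse(y == "case", 1, -1)
    X2 <- cbind(base + rnorm(12, sd = 1e-6), base + rnorm(12, sd = 1e-6))
    expect_equal(unname(vip(fitOplsda(X2, y, nOrth = 0))), c(1, 1),
                 tolerance = 1e-3)
    # random model: mean squared VIP is exactly 1
    X3 <- matrix(rnorm(120), 12, 10)
    m <- fitOplsda(X3, y, nOrth = 1)
    expect_equal(mean(vip(m)^2), 1, tolerance = 1e-12)
    expect_equal(mean(computeVip(m, "total")^2), 1, tolerance = 1e-8)
})

test_that("cross-validation separates signal from noise", {
    # noiseless separable data: Q2 close to 1
    y <- factor(rep(c("control", "case"), each = 8),
                levels = c("control", "case"))
    set.seed(8)
    sig <- ifelse(y == "case", 1, -1)
    X <- cbind(sig + rnorm(16, sd = 0.02),
               0.5 * sig + rnorm(16, sd = 0.02),
               matrix(rnorm(16 * 3, sd = 0.05), 16))
    m <- fitOplsda(X, y, nOrth = 0)
    cv <- crossValidateOplsda(m, folds = 4, seed = 1)
    expect_gt(cv$Q2, 0.9)
    expect_lt(cv$cvAnovaP, 1e-6)
    expect_error(crossValidateOplsda(m, folds = 1), "folds")

    # label-independent data: Q2 non-positive in >= 90% of seeds
    neg <- 0L
    set.seed(99)
    for (s in 1:100) {
        Xn <- matrix(rnorm(64 * 60), 64, 60)
        yn <- factor(rep(c("control", "case"), c(30, 34)))
        mn <- fitOplsda(Xn, yn, nOrth = 0)
        if (crossValidateOplsda(mn, folds = 7, seed = s)$Q2 <= 0)
            neg <- neg + 1L
    }
    expect_gte(neg, 90L)
})

test_that("Q2 on training data never exceeds R2Y on planted cohorts", {
    for (s in 1:5) {
        pm <- processedFrom(smallCohort(seed = 500 + s))
        m <- fitOplsda(pm, nOrth = 1)
        cv <- crossValidateOplsda(m, folds = 5, seed = s)
        expect_lte(cv$Q2, m@R2Y + 1e-8)
    }
})

test_that("permuted labels score worse than the true model", {
    pm <- processedFrom(smallCohort(seed = 9, nCase = 12, nControl = 12))
    m <- fitOplsda(pm, nOrth = 0)
    pt <- permutationTestOplsda(m, nPerm = 40, folds = 5, seed = 2)
    expect_gte(mean(pt$perms$Q2 < pt$trueQ2), 0.95)
    expect_lt(pt$permQ2Intercept, pt$trueQ2)
    expect_error(permutationTestOplsda(m, nPerm = 10), "nPerm")
})

test_that("jack-knife intervals flag signal as stable and noise as unstable", {
    y <- factor(rep(c("control", "case"), each = 8),
                levels = c("control", "case"))
    set.seed(10)
    X <- cbind(sig = ifelse(y == "case", 1, -1) + rnorm(16, sd = 0.05),
               matrix(rnorm(16 * 4), 16,
                      dimnames = list(NULL, paste0("n", 1:4))))
    m <- fitOplsda(X, y, nOrth = 0)
    jk <- jackknifeLoadings(m, folds = 4, seed = 1)
    expect_true(jk["sig", "stable"])

    # null features span zero in nearly all seeds
    spans <- 0L
    for (s in 1:30) {
        Xn <- matrix(rnorm(20 * 6), 20, 6)
        yn <- factor(rep(c("control", "case"), each = 10))
        mn <- fitOplsda(Xn, yn, nOrth = 0)
        jkn <- jackknifeLoadings(mn, folds = 2, seed = s)  # minimal folds run
        spans <- spans + (!jkn$stable[1])
    }
    expect_gte(spans, 27L)
})

test_that("ROC AUC follows the Mann-Whitney pair-counting definition", {
    lab <- factor(c("case", "case", "control", "control"),
                  levels = c("control", "case"))
    expect_equal(rocAuc(c(3, 4, 1, 2), lab, "case"), 1)
    expect_equal(rocAuc(c(1, 1, 1, 1), lab, "case"), 0.5)
    expect_equal(rocAuc(c(0.9, 0.3, 0.5, 0.1), lab, "case"), 0.75)
    expect_error(rocAuc(1:3, factor(rep("case", 3))), "two classes")
    set.seed(11)
    for (i in 1:25) {
        n <- sample(6:20, 1)
        lab <- factor(sample(c("control", "case"), n, replace = TRUE))
        if (nlevels(droplevels(lab)) < 2) next
        sc <- sample(round(rnorm(n), 1))  # ties likely
        expect_equal(rocAuc(sc, lab, "case"), aucPairOracle(sc, lab, "case"))
    }
})

test_that("OPLS-DA selection applies the strict VIP gate", {
    pm <- processedFrom(smallCohort(seed = 12))
    m <- fitOplsda(pm, nOrth = 1)
    sel <- selectOplsda(m, requireStable = FALSE, pcorrMin = 0)
    expect_true(all(vip(m)[sel] > 1.3))
    # a threshold at the maximum VIP selects nothing (strict inequality)
    expect_equal(selectOplsda(m, vipMin = max(vip(m)), requireStable = FALSE,
                              pcorrMin = 0), character(0))
})
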