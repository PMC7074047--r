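# Small, fast settings for the wrapper: the selection behaviour under test
# does not depend on the cohort being full-sized.
bioArgs <- list(nBoot = 40, ntree = 50)

test_that("a perfectly separating feature lands in every classifier's S tier", {
    set.seed(1)
    # 16 + 16 samples: the out-of-bag subsets are large enough that a random
    # permutation almost never reproduces the class alignment by chance
    y <- factor(rep(c("control", "case"), each = 16),
                levels = c("control", "case"))
    X <- cbind(sep = ifelse(y == "case", 1, -1),
               matrix(rnorm(32 * 9), 32,
                      dimnames = list(NULL, paste0("n", 1:9))))
    res <- do.call(biosignerSelect, c(list(X, y, seed = 3), bioArgs))
    for (k in c("plsda", "rf", "svm"))
        expect_true("sep" %in% tiers(res)[[k]], info = k)
    acc <- signatureAccuracy(res, X, y, nBoot = 40, ntree = 50)
    expect_true(all(acc > 0.9))
})

test_that("identical seeds give identical tiers", {
    pm <- processedFrom(smallCohort(seed = 2))
    a <- do.call(biosignerSelect, c(list(pm, seed = 7), bioArgs))
    b <- do.call(biosignerSelect, c(list(pm, seed = 7), bioArgs))
    expect_identical(tiers(a), tiers(b))
    expect_identical(a@accuracies, b@accuracies)
})

test_that("pure-noise data yields empty tiers in nearly all seeds", {
    nonEmpty <- 0L
    for (s in 1:15) {
        set.seed(s)
        X <- matrix(rnorm(24 * 30), 24, 30)
        y <- factor(rep(c("control", "case"), each = 12),
                    levels = c("control", "case"))
        res <- do.call(biosignerSelect, c(list(X, y, seed = s), bioArgs))
        if (any(lengths(tiers(res)) > 0)) nonEmpty <- nonEmpty + 1L
    }
    expect_lte(nonEmpty, 1L)   # >= 90% empty
})

test_that("S-tier features discriminate on the full data (AUC above one half)", {
    pm <- processedFrom(smallCohort(seed = 4, nCase = 12, nControl = 12))
    res <- do.call(biosignerSelect, c(list(pm, seed = 4), bioArgs))
    sel <- unique(unlist(tiers(res)))
    y <- pm@sampleClass
    for (f in sel) {
        auc <- rocAuc(pm@values[, f], y, positiveClass = "case")
        expect_gt(max(auc, 1 - auc), 0.5)
    }
})

test_that("stronger planted effects never lose the planted feature", {
    # one planted feature at increasing effect size; S-tier membership must
    # be monotone in the effect (small seed-level slack for resampling noise)
    grid <- c(2, 3.5, 6)
    viol <- 0L
    for (s in 1:8) {
        inTier <- logical(length(grid))
        for (g in seq_along(grid)) {
            pe <- data.frame(feature = 1L, fc = grid[g])
            me <- generateCohort(cohortSpec(
                nCase = 10, nControl = 10, nFeatures = 15, nJunkFeatures = 0,
                plantedEffects = pe, driftModel = "none", noiseCv = 0.25,
                seed = 600 + s))
            pm <- logParetoTransform(me)
            res <- do.call(biosignerSelect,
                           c(list(pm, seed = s, classifiers = "plsda"),
                             bioArgs))
            inTier[g] <- "M001" %in% tiers(res)$plsda
        }
        if (any(diff(inTier) < 0)) viol <- viol + 1L
    }
    expect_lte(viol, 1L)
})

test_that("signature accuracy is near chance when labels carry no information", {
    set.seed(5)
    accs <- numeric(10)
    for (s in 1:10) {
        X <- matrix(rnorm(20 * 5), 20, 5,
                    dimnames = list(NULL, paste0("f", 1:5)))
        y <- factor(rep(c("control", "case"), each = 10),
                    levels = c("control", "case"))
        res <- new("BiosignerResult",
                   tiers = list(plsda = "f1"),
                   accuracies = c(plsda = NA_real_),
                   featureIds = colnames(X), nBoot = 30L,
                   pThreshold = 0.05, seed = as.integer(s))
        accs[s] <- signatureAccuracy(res, X, y, nBoot = 30)["plsda"]
    }
    expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("signature accuracy does not depend on feature column order", {
    set.seed(6)
    y <- factor(rep(c("control", "case"), each = 8),
                levels = c("control", "case"))
    X <- cbind(sig = ifelse(y == "case", 1, -1) + rnorm(16, sd = 0.3),
               matrix(rnorm(16 * 4), 16,
                      dimnames = list(NULL, paste0("n", 1:4))))
    res <- new("BiosignerResult", tiers = list(plsda = "sig"),
               accuracies = c(plsda = NA_real_), featureIds = colnames(X),
               nBoot = 25L, pThreshold = 0.05, seed = 9L)
    a <- signatureAccuracy(res, X, y, nBoot = 25)
    Xp <- X[, c(4, 2, 5, 1, 3)]
    res@featureIds <- colnames(Xp)
    b <- signatureAccuracy(res, Xp, y, nBoot = 25)
    expect_equal(a, b)
})

test_that("degenerate inputs are rejected", {
    X <- matrix(rnorm(16), 8, 2)
    expect_error(biosignerSelect(X, factor(rep(c("a", "b"), each = 4)),
                                 nBoot = 5), "nBoot")
    expect_error(biosignerSelect(X, factor(rep(c("a", "b"), c(7, 1)))),
                 "at least 4")
})
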