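# A compact planted cohort shared across the stability tests.
plantedStability <- function(seed, nSplits = 120) {
    pe <- data.frame(feature = c(1L, 2L), fc = c(2.0, 0.5))
    me <- generateCohort(cohortSpec(nCase = 34, nControl = 30,
                                    nFeatures = 40, nJunkFeatures = 0,
                                    plantedEffects = pe, driftModel = "none",
                                    noiseCv = 0.2, seed = seed))
    pm <- logParetoTransform(me)
    runStabilitySelection(pm, config = stabilityConfig(nSplits = nSplits,
                                                       seed = seed))
}

test_that("planted features reach group I and null features have zero median coefficients", {
    res <- plantedStability(seed = 7, nSplits = 200)
    expect_true(res@valid)
    grp <- stabilityGroup(res)
    expect_equal(unname(as.character(grp[c("M001", "M002")])), c("I", "I"))
    C <- medianCoefficient(res)
    expect_gt(C["M001"], 0)    # planted up-regulated
    expect_lt(C["M002"], 0)    # planted down-regulated
    nulls <- setdiff(res@featureIds, c("M001", "M002"))
    expect_true(all(C[nulls] == 0))
})

test_that("the same configuration and seed reproduce the result exactly", {
    a <- plantedStability(seed = 8, nSplits = 40)
    b <- plantedStability(seed = 8, nSplits = 40)
    expect_identical(selectionFrequency(a), selectionFrequency(b))
    expect_identical(medianCoefficient(a), medianCoefficient(b))
    expect_identical(stabilityGroup(a), stabilityGroup(b))
})

test_that("label-independent data fails the good-model gate", {
    me <- generateCohort(nullSpec(9, nCase = 16, nControl = 16,
                                  nFeatures = 30, nJunkFeatures = 0,
                                  driftModel = "none"))
    pm <- logParetoTransform(me)
    res <- runStabilitySelection(pm, config = stabilityConfig(nSplits = 60,
                                                              seed = 9))
    expect_false(res@valid)
    expect_lt(abs(res@medianAuc - 0.5), 0.2)
    expect_error(yplotData(res), "invalid")
    expect_error(selectLassoFeatures(res, S4Vectors::DataFrame(), numeric(0)),
                 "invalid")
})

test_that("selection frequencies are invariant to feature column order", {
    pe <- data.frame(feature = 1L, fc = 2.0)
    me <- generateCohort(cohortSpec(nCase = 16, nControl = 16,
                                    nFeatures = 12, nJunkFeatures = 0,
                                    plantedEffects = pe, driftModel = "none",
                                    noiseCv = 0.2, seed = 10))
    pm <- logParetoTransform(me)
    cfg <- stabilityConfig(nSplits = 50, seed = 10)
    a <- runStabilitySelection(pm@values, pm@sampleClass, cfg,
                               positiveClass = "case")
    perm <- sample(ncol(pm@values))
    b <- runStabilitySelection(pm@values[, perm], pm@sampleClass, cfg,
                               positiveClass = "case")
    ids <- colnames(pm@values)
    expect_identical(selectionFrequency(a)[ids], selectionFrequency(b)[ids])
    # coefficients agree up to glmnet's coordinate-descent tolerance, whose
    # iterate order follows the column order
    expect_equal(medianCoefficient(a)[ids], medianCoefficient(b)[ids],
                 tolerance = 1e-3)
})

test_that("yplot rows cover every feature with coherent directions", {
    res <- plantedStability(seed = 11, nSplits = 60)
    yp <- yplotData(res)
    expect_equal(nrow(yp), length(res@featureIds))
    expect_true(all(yp$direction[yp$C > 0] == "up"))
    expect_true(all(yp$direction[yp$C < 0] == "down"))
    expect_true(all(yp$direction[yp$C == 0] == "null"))
    never <- yp[yp$F == 0, ]
    expect_true(all(never$C == 0) && all(never$group == "III"))
})

test_that("the group-I intersection filter reproduces the published outcome", {
    tbl <- loadTable1Fixture()
    groupI <- c("Uracil", "Arginine", "N-acetylputrescine", "Nicotinamide",
                "Cortisone", "5,6-dihydrouracil")
    sel <- selectLassoFeatures(groupI, stats = tbl,
                               vip = setNames(tbl$vip, tbl$feature_id))
    expect_setequal(sel, c("Nicotinamide", "Arginine"))
    expect_equal(selectLassoFeatures(character(0), tbl,
                                     setNames(tbl$vip, tbl$feature_id)),
                 character(0))
    # VIP gate is inclusive at the threshold
    st <- S4Vectors::DataFrame(feature_id = "x", q = 0.01)
    expect_equal(selectLassoFeatures("x", st, c(x = 1.3)), "x")
    expect_error(selectLassoFeatures(c("x", "y"), st, c(x = 1.3)), "y")
})

test_that("stability configuration rejects incoherent settings", {
    expect_error(stabilityConfig(trainFraction = 1), "trainFraction")
    expect_error(stabilityConfig(aucGood = 0.9, aucExcellent = 0.8),
                 "aucExcellent")
    expect_error(stabilityConfig(thrI = 0.1, thrII = 0.5), "thrI")
})
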