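test_that("drift correction is the identity when QC intensities are constant", {
    me <- generateCohort(cohortSpec(nCase = 5, nControl = 5, nFeatures = 6,
                                    nJunkFeatures = 0, driftModel = "none",
                                    noiseCv = 0, qcNoiseCv = 0, seed = 1))
    out <- correctDrift(me)
    expect_equal(intensityMatrix(out), intensityMatrix(me))
})

test_that("planted linear drift is removed exactly at zero noise", {
    me <- generateCohort(cohortSpec(nCase = 8, nControl = 8, nFeatures = 5,
                                    nJunkFeatures = 0, driftModel = "none",
                                    noiseCv = 0, qcNoiseCv = 0, seed = 2))
    dr <- injectDrift(me, model = "linear", amplitude = 0.15)
    out <- correctDrift(dr)
    qcIdx <- sampleRole(out) == "qc"
    qc <- intensityMatrix(out)[, qcIdx]
    med <- apply(qc, 1, median)
    expect_true(all(abs(sweep(qc, 1, med, "/") - 1) < 1e-6))
})

test_that("drift correction is idempotent at zero noise", {
    me <- generateCohort(cohortSpec(nCase = 8, nControl = 8, nFeatures = 5,
                                    nJunkFeatures = 0, driftModel = "linear",
                                    driftAmplitude = 0.1,
                                    noiseCv = 0, qcNoiseCv = 0, seed = 3))
    once <- correctDrift(me)
    twice <- correctDrift(once)
    expect_equal(intensityMatrix(twice), intensityMatrix(once),
                 tolerance = 1e-9)
})

test_that("drift correction refuses to run with too few QC injections", {
    me <- generateCohort(cohortSpec(nCase = 5, nControl = 5, nFeatures = 4,
                                    nJunkFeatures = 0, nQC = 3, seed = 4))
    expect_error(correctDrift(me, minQC = 5), "QC samples")
})

test_that("QC CV filter applies the strict 30% threshold", {
    x <- matrix(c(100, 100, 100,
                  50, 100, 150,
                  70, 100, 130), nrow = 3, byrow = TRUE,
                dimnames = list(c("const", "wide", "edge"), NULL))
    me <- MetaboExperiment(x, role = rep("qc", 3), injectionOrder = 1:3)
    st <- filterStats(qcCvFilter(me, maxCv = 0.30))
    expect_equal(unname(st["const", "qc_cv"]), 0)
    expect_true(st["const", "retained"])
    expect_equal(unname(st["wide", "qc_cv"]), 0.5)        # sd 50, mean 100
    expect_false(st["wide", "retained"])
    expect_equal(unname(st["edge", "qc_cv"]), 0.30)       # exactly at threshold
    expect_false(st["edge", "retained"])          # "below 30%" is strict
    expect_equal(unique(st$reason_dropped[!st$retained]), "cv")
})

test_that("dilution linearity filter matches an OLS oracle and drops flat responses", {
    x <- rbind(lin = c(100, 50, 25),
               flat = c(80, 80, 80),
               bent = c(100, 60, 10))
    me <- MetaboExperiment(x, role = rep("dilution", 3),
                           injectionOrder = 1:3,
                           dilutionFactor = c(1, 0.5, 0.25))
    st <- filterStats(dilutionLinearityFilter(me, minR2 = 0.8))
    expect_equal(unname(st["lin", "dilution_r2"]), 1)
    expect_true(st["lin", "retained"])
    expect_equal(unname(st["flat", "dilution_r2"]), 0)
    expect_false(st["flat", "retained"])
    r2 <- summary(lm(c(100, 60, 10) ~ c(1, 0.5, 0.25)))$r.squared
    expect_equal(unname(st["bent", "dilution_r2"]), r2)
    expect_equal(unname(st["bent", "retained"]), r2 >= 0.8)
})

test_that("completeness filter drops any feature with a missing value", {
    x <- rbind(full = c(1, 2, 3, 4), hole = c(1, NA, 3, 4))
    me <- MetaboExperiment(x, role = c("case", "case", "control", "qc"),
                           injectionOrder = 1:4)
    st <- filterStats(completenessFilter(me))
    expect_true(st["full", "retained"])
    expect_false(st["hole", "retained"])
    expect_equal(unname(st["hole", "reason_dropped"]), "missing")
})

test_that("the combined retained set is the intersection of the three predicates", {
    for (s in 1:20) {
        me <- generateCohort(cohortSpec(nCase = 6, nControl = 6,
                                        nFeatures = 12, nJunkFeatures = 9,
                                        seed = 300 + s))
        cv <- filterStats(qcCvFilter(me))$retained
        li <- filterStats(dilutionLinearityFilter(me))$retained
        co <- filterStats(completenessFilter(me))$retained
        all3 <- filterStats(filterFeatures(me))$retained
        expect_identical(all3, cv & li & co)
    }
})

test_that("log/Pareto transform has the documented fixed point and identities", {
    # log values 1, 2, 3: mean 2, sd 1, sqrt(sd) 1 -> scaled -1, 0, 1
    x <- matrix(exp(c(1, 2, 3)), nrow = 1, dimnames = list("f", NULL))
    me <- MetaboExperiment(rbind(f = exp(c(1, 2, 3))),
                           role = c("case", "control", "case"),
                           injectionOrder = 1:3)
    pm <- logParetoTransform(me)
    expect_equal(unname(pm@values[, "f"]), c(-1, 0, 1))

    # Pareto identity on a random cohort: column mean 0, column var = log sd
    me2 <- smallCohort(seed = 11)
    pm2 <- processedFrom(me2)
    expect_true(max(abs(colMeans(pm2@values))) < 1e-9)
    expect_equal(unname(apply(pm2@values, 2, var)), unname(pm2@featureSds),
                 tolerance = 1e-12)
})

test_that("log/Pareto transform rejects non-positive intensities and drops constants", {
    me <- MetaboExperiment(rbind(bad = c(0, 2, 3), fine = c(1, 2, 3)),
                           role = c("case", "control", "case"),
                           injectionOrder = 1:3)
    expect_error(logParetoTransform(me), "bad")
    me2 <- MetaboExperiment(rbind(const = c(2, 2, 2), fine = c(1, 2, 3)),
                            role = c("case", "control", "case"),
                            injectionOrder = 1:3)
    expect_warning(pm <- logParetoTransform(me2), "const")
    expect_equal(colnames(pm@values), "fine")
})

test_that("default cohorts keep the quality features and shed the junk", {
    me <- generateCohort(cohortSpec(seed = 42))
    st <- filterStats(filterFeatures(me))
    kept <- st$feature_id[st$retained]
    expect_equal(sum(grepl("^M", kept)), 160)
    expect_gte(sum(grepl("^J", st$feature_id) & !st$retained), 38) # >= 95%
})
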