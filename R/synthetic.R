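#' Fold changes of the nine-metabolite glaucoma plasma signature
#'
#' Raw-scale case/control fold changes of the nine consensus signature
#' metabolites (decreases are values below 1). Used as the default planted
#' effects of the cohort generator so simulated cohorts carry effect sizes
#' in the published range.
#'
#' @return named numeric vector of fold changes.
#' @export
signatureFoldChanges <- function() {
    c("Nicotinamide" = 0.643,
      "Arginine" = 1.312,
      "N-acetyl-L-leucine" = 1.846,
      "Hypoxanthine" = 0.558,
      "1-methyl-6,7-dihydroxy-1,2,3,4-tetrahydroisoquinoline" = 0.469,
      "Xanthine" = 0.727,
      "Rac-glycerol 1-myristate" = 1.316,
      "Cystathionine" = 1.656,
      "1-oleoyl-rac-glycerol" = 1.608)
}

.defaultPlanted <- function(nFeatures) {
    fc <- signatureFoldChanges()
    # small cohorts get the strongest members of the default panel
    k <- min(length(fc), nFeatures)
    if (k < length(fc))
        fc <- fc[order(pmax(fc, 1 / fc), decreasing = TRUE)][seq_len(k)]
    # spread planted features across the feature index range
    idx <- unique(round(seq(1, nFeatures, length.out = k)))
    data.frame(feature = idx[seq_len(k)], fc = unname(fc),
               label = names(fc), stringsAsFactors = FALSE)
}

#' Construct a cohort specification
#'
#' Defaults emulate the study design: 34 cases vs 30 controls, 160
#' retained-quality features (nine of which carry the published signature
#' fold changes), 40 junk features built to fail the QC filters, 10 pooled
#' QC injections spread across the run, one 1/0.5/0.25 dilution triple, 25%
#' biological-plus-analytical noise on study samples, 10% analytical noise
#' on QC injections and a smooth +/-10% instrumental drift.
#'
#' @param nCase,nControl study group sizes.
#' @param nFeatures,nJunkFeatures quality / junk feature counts.
#' @param nQC,qcSpacing pooled-QC injections and their spacing (\code{NA} =
#'   spread evenly).
#' @param plantedEffects data.frame with columns \code{feature} and
#'   \code{fc}; \code{NULL} keeps the default nine-effect panel, an empty
#'   data.frame plants nothing (null cohort).
#' @param driftModel,driftAmplitude instrumental drift shape and relative
#'   amplitude.
#' @param noiseCv,qcNoiseCv lognormal coefficients of variation for study
#'   samples and for repeated QC/dilution injections.
#' @param missingRate per-value missing probability on missing-kind junk
#'   features.
#' @param seed integer RNG seed.
#' @return a \linkS4class{CohortSpec}.
#' @export
cohortSpec <- function(nCase = 34, nControl = 30, nFeatures = 160,
                       nJunkFeatures = 40, nQC = 10, qcSpacing = NA,
                       plantedEffects = NULL,
                       driftModel = c("smooth", "none", "linear"),
                       driftAmplitude = 0.1,
                       noiseCv = 0.25, qcNoiseCv = 0.1,
                       missingRate = 0.1, seed = 1) {
    driftModel <- match.arg(driftModel)
    if (is.null(plantedEffects))
        plantedEffects <- .defaultPlanted(nFeatures)
    plantedEffects <- as.data.frame(plantedEffects)
    new("CohortSpec",
        nCase = as.integer(nCase), nControl = as.integer(nControl),
        nFeatures = as.integer(nFeatures),
        nJunkFeatures = as.integer(nJunkFeatures),
        nQC = as.integer(nQC), qcSpacing = as.integer(qcSpacing),
        plantedEffects = plantedEffects,
        driftModel = driftModel, driftAmplitude = driftAmplitude,
        noiseCv = noiseCv, qcNoiseCv = qcNoiseCv,
        missingRate = missingRate, seed = as.integer(seed))
}

# lognormal sigma giving a target coefficient of variation
.cvToSigma <- function(cv) sqrt(log(1 + cv^2))

#' Generate a synthetic LC-HRMS cohort
#'
#' Draws a feature-intensity table with the statistical structure the
#' downstream pipeline assumes. Intensities are lognormal around a
#' feature-specific median; case medians are the control medians times the
#' planted fold change (1 when unplanted); pooled-QC injections share one
#' pool median per feature (the case/control mixture) with analytical noise
#' only; the dilution triple scales the pool median by 1, 1/2 and 1/4. Junk
#' features cycle through three failure modes: QC coefficient of variation
#' well above 30%, missing values, and a flat (saturated) dilution response.
#' Instrumental drift, when requested, multiplies every intensity by a
#' strictly positive function of the injection order via [injectDrift()].
#'
#' The RNG is consumed feature-level parameters first, then sample values,
#' so enlarging the cohort does not reshuffle feature parameters. Identical
#' seeds give bit-identical tables.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @return a \linkS4class{MetaboExperiment}; the planted ground truth is
#'   available through [plantedEffects()].
#' @examples
#' me <- generateCohort(cohortSpec(nCase = 5, nControl = 5, nFeatures = 20,
#'                                 nJunkFeatures = 6, seed = 42))
#' me
#' @export
generateCohort <- function(spec) {
    validObject(spec)
    set.seed(spec@seed)
    J <- spec@nFeatures
    K <- spec@nJunkFeatures
    Jtot <- J + K
    featIds <- c(sprintf("M%03d", seq_len(J)),
                 if (K) sprintf("J%03d", seq_len(K)))

    ## feature-level parameters (drawn before any sample value)
    muLog <- stats::rnorm(Jtot, mean = 11, sd = 1.2)
    fc <- rep(1, Jtot)
    pe <- spec@plantedEffects
    if (nrow(pe)) fc[pe$feature] <- pe$fc
    sigmaStudy <- rep(.cvToSigma(spec@noiseCv), Jtot)
    sigmaQc <- rep(.cvToSigma(spec@qcNoiseCv), Jtot)
    junkMode <- character(0)
    if (K) {
        junkMode <- rep(c("cv", "missing", "nonlinear"), length.out = K)
        junkCv <- stats::runif(K, 0.8, 1.5)
        isCvJunk <- junkMode == "cv"
        sigmaQc[J + which(isCvJunk)] <- .cvToSigma(junkCv[isCvJunk])
        sigmaStudy[J + which(isCvJunk)] <- .cvToSigma(junkCv[isCvJunk])
    }

    ## sample layout: study samples in randomised run order, QCs interleaved
    nStudy <- spec@nCase + spec@nControl
    studyRole <- sample(c(rep("case", spec@nCase), rep("control", spec@nControl)))
    nQC <- spec@nQC
    total <- nStudy + nQC
    if (nQC > 0) {
        if (!is.na(spec@qcSpacing)) {
            after <- pmin(cumsum(rep(spec@qcSpacing, nQC)), nStudy)
            qcPos <- after + seq_len(nQC)
        } else {
            qcPos <- round(seq(1, total, length.out = max(nQC, 2)))[seq_len(nQC)]
        }
        qcPos <- sort(unique(pmin(pmax(qcPos, 1), total)))
        while (length(qcPos) < nQC)
            qcPos <- sort(unique(c(qcPos, sample(setdiff(seq_len(total), qcPos), 1))))
    } else qcPos <- integer(0)
    role <- character(total)
    role[qcPos] <- "qc"
    role[role == ""] <- studyRole
    role <- c(role, rep("dilution", 3))
    n <- length(role)
    injection <- seq_len(n)
    dilFactor <- rep(NA_real_, n)
    dilFactor[role == "dilution"] <- c(1, 0.5, 0.25)

    ## pool median = intensity-weighted mixture of the group medians
    poolLog <- muLog + log((spec@nCase * fc + spec@nControl) /
                           (spec@nCase + spec@nControl))

    x <- matrix(NA_real_, nrow = Jtot, ncol = n,
                dimnames = list(featIds, sprintf("S%03d", injection)))
    isCase <- role == "case"
    isControl <- role == "control"
    isQc <- role == "qc"
    isDil <- role == "dilution"
    for (j in seq_len(Jtot)) {
        lm <- numeric(n)
        sg <- numeric(n)
        lm[isControl] <- muLog[j]
        lm[isCase] <- muLog[j] + log(fc[j])
        lm[isQc] <- poolLog[j]
        lm[isDil] <- poolLog[j] + log(dilFactor[isDil])
        sg[isCase | isControl] <- sigmaStudy[j]
        sg[isQc | isDil] <- sigmaQc[j]
        if (j > J && junkMode[j - J] == "nonlinear")
            # detector saturation: non-monotone dilution response whose OLS
            # r-squared is ~0.04 by construction, robust to analytical noise
            lm[isDil] <- poolLog[j] + log(c(1, 2, 1))
        z <- stats::rnorm(n)
        x[j, ] <- exp(lm + sg * z)
    }

    ## missing values on missing-kind junk features
    if (K && spec@missingRate > 0) {
        for (k in which(junkMode == "missing")) {
            drop <- stats::runif(n) < spec@missingRate
            if (!any(drop)) drop[sample.int(n, 1)] <- TRUE
            x[J + k, drop] <- NA_real_
        }
    }

    me <- MetaboExperiment(
        x, role = role, injectionOrder = injection,
        dilutionFactor = dilFactor,
        metadata = list(
            planted_effects = if (nrow(pe))
                data.frame(feature_id = featIds[pe$feature], fc = pe$fc,
                           stringsAsFactors = FALSE)
            else data.frame(feature_id = character(0), fc = numeric(0)),
            cohort_seed = spec@seed))
    if (spec@driftModel != "none")
        me <- injectDrift(me, model = spec@driftModel,
                          amplitude = spec@driftAmplitude)
    me
}

#' Multiply intensities by an instrumental drift profile
#'
#' Applies a multiplicative drift along the injection sequence: every
#' intensity is multiplied by \code{drift(injection order)}. Roles and
#' metadata are unchanged. The drift multiplier must be strictly positive
#' over the whole run.
#'
#' @param table a \linkS4class{MetaboExperiment}.
#' @param model \code{"none"} (identity), \code{"linear"} (multiplier runs
#'   from 1-amplitude to 1+amplitude across the run) or \code{"smooth"}
#'   (one sinusoidal cycle of the given amplitude).
#' @param amplitude relative drift amplitude; must keep the multiplier
#'   positive.
#' @return the drifted \linkS4class{MetaboExperiment}.
#' @export
injectDrift <- function(table, model = c("none", "linear", "smooth"),
                        amplitude = 0.1) {
    model <- match.arg(model)
    if (model == "none") return(table)
    ord <- colData(table)$injection_order
    rng <- range(ord)
    u <- if (diff(rng) > 0) (ord - rng[1]) / diff(rng) else rep(0.5, length(ord))
    mult <- switch(model,
        linear = 1 + amplitude * (2 * u - 1),
        smooth = 1 + amplitude * sin(2 * pi * u))
    if (any(mult <= 0))
        stop("drift multiplier must be strictly positive over the injection range")
    x <- assay(table, "intensity")
    x <- sweep(x, 2, mult, "*")
    SummarizedExperiment::assay(table, "intensity") <- x
    md <- S4Vectors::metadata(table)
    md$drift <- list(model = model, amplitude = amplitude)
    S4Vectors::metadata(table) <- md
    table
}
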