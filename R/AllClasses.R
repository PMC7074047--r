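#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

.SAMPLE_ROLES <- c("case", "control", "qc", "dilution")
.DILUTION_FACTORS <- c(1, 0.5, 0.25)

#' Container for an LC-HRMS feature-intensity table
#'
#' A \linkS4class{SummarizedExperiment} holding one \code{"intensity"} assay
#' (features in rows, samples in columns) together with the per-sample
#' metadata the pipeline needs: the sample role (\code{"case"},
#' \code{"control"}, \code{"qc"} for pooled quality-control injections, or
#' \code{"dilution"} for the QC dilution series), the injection order within
#' the analytical run, and the dilution factor (1, 1/2 or 1/4) for dilution
#' samples.
#'
#' Validity requires unique positive injection orders, roles drawn from the
#' allowed set, non-negative intensities wherever observed, and dilution
#' factors in \{1, 0.5, 0.25\} on dilution samples.
#'
#' @seealso [MetaboExperiment()] for the constructor, [generateCohort()] for
#'   simulated instances.
#' @export
setClass("MetaboExperiment", contains = "SummarizedExperiment")

setValidity("MetaboExperiment", function(object) {
    msg <- character(0)
    cd <- colData(object)
    need <- c("role", "injection_order", "dilution_factor")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        return(paste("missing colData columns:", paste(miss, collapse = ", ")))
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
        return("assay 'intensity' is required")
    role <- cd$role
    if (!all(role %in% .SAMPLE_ROLES))
        msg <- c(msg, paste("invalid sample roles:",
                            paste(unique(setdiff(role, .SAMPLE_ROLES)), collapse = ", ")))
    ord <- cd$injection_order
    if (anyNA(ord) || any(ord < 1))
        msg <- c(msg, "injection_order must be positive and non-missing")
    if (anyDuplicated(ord))
        msg <- c(msg, "injection_order values must be unique")
    x <- assay(object, "intensity")
    if (any(x < 0, na.rm = TRUE))
        msg <- c(msg, "intensities must be non-negative where present")
    df <- cd$dilution_factor[role == "dilution"]
    if (length(df) && !all(df %in% .DILUTION_FACTORS))
        msg <- c(msg, "dilution_factor must be one of 1, 0.5, 0.25 on dilution samples")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Specification of a synthetic case-control metabolomics cohort
#'
#' Describes the cohort the generator emulates: a case/control study set with
#' interleaved pooled-QC injections, a QC dilution triple (1, 1/2, 1/4),
#' multiplicative lognormal noise, optional instrumental drift across the
#' injection sequence, planted case-vs-control fold changes on a subset of
#' features, and deliberately low-quality ("junk") features designed to fail
#' the QC filters.
#'
#' @slot nCase,nControl number of case / control study samples.
#' @slot nFeatures number of retained-quality features.
#' @slot nJunkFeatures number of features constructed to fail at least one
#'   QC filter (high QC coefficient of variation, missing values, or a flat
#'   dilution response).
#' @slot nQC number of pooled-QC injections interleaved across the run.
#' @slot qcSpacing approximate number of study injections between QCs; when
#'   \code{NA} the QCs are spread evenly across the run.
#' @slot plantedEffects data.frame with columns \code{feature} (index into
#'   the quality features) and \code{fc} (raw-scale case/control fold
#'   change).
#' @slot driftModel one of \code{"none"}, \code{"linear"}, \code{"smooth"}.
#' @slot driftAmplitude relative drift amplitude across the run (0.1 means
#'   the drift multiplier spans roughly 0.9--1.1).
#' @slot noiseCv lognormal coefficient of variation of study-sample
#'   intensities (biological + analytical).
#' @slot qcNoiseCv lognormal coefficient of variation of repeated QC and
#'   dilution injections (analytical only).
#' @slot missingRate per-value missing probability on junk features of the
#'   missing-value kind.
#' @slot seed integer RNG seed; identical seeds give bit-identical cohorts.
#' @export
setClass("CohortSpec",
    representation(
        nCase = "integer", nControl = "integer",
        nFeatures = "integer", nJunkFeatures = "integer",
        nQC = "integer", qcSpacing = "integer",
        plantedEffects = "data.frame",
        driftModel = "character", driftAmplitude = "numeric",
        noiseCv = "numeric", qcNoiseCv = "numeric",
        missingRate = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
    msg <- character(0)
    if (object@nCase < 3L) msg <- c(msg, "nCase must be >= 3")
    if (object@nControl < 3L) msg <- c(msg, "nControl must be >= 3")
    if (object@nFeatures < 1L) msg <- c(msg, "nFeatures must be >= 1")
    if (object@nJunkFeatures < 0L) msg <- c(msg, "nJunkFeatures must be >= 0")
    if (object@nQC < 0L) msg <- c(msg, "nQC must be >= 0")
    pe <- object@plantedEffects
    if (nrow(pe)) {
        if (!all(c("feature", "fc") %in% colnames(pe)))
            msg <- c(msg, "plantedEffects needs columns 'feature' and 'fc'")
        else {
            if (any(pe$fc <= 0)) msg <- c(msg, "plantedEffects: fold changes must be > 0")
            if (any(pe$feature < 1 | pe$feature > object@nFeatures))
                msg <- c(msg, "plantedEffects: feature index out of range")
            if (anyDuplicated(pe$feature))
                msg <- c(msg, "plantedEffects: duplicated feature index")
        }
    }
    if (!object@driftModel %in% c("none", "linear", "smooth"))
        msg <- c(msg, "driftModel must be one of none, linear, smooth")
    if (object@driftAmplitude < 0 || object@driftAmplitude >= 1)
        msg <- c(msg, "driftAmplitude must be in [0, 1)")
    if (object@noiseCv < 0) msg <- c(msg, "noiseCv must be >= 0")
    if (object@qcNoiseCv < 0) msg <- c(msg, "qcNoiseCv must be >= 0")
    if (object@missingRate < 0 || object@missingRate > 1)
        msg <- c(msg, "missingRate must be in [0, 1]")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Per-feature quality-filter report
#'
#' One row per feature with the pooled-QC coefficient of variation, the
#' dilution-series linearity r-squared, the completeness flag, the combined
#' retention decision and the first reason a feature was dropped
#' (\code{"cv"}, \code{"linearity"}, \code{"missing"}, or \code{"none"}).
#' Columns not evaluated by a single-filter call are \code{NA}.
#'
#' @slot stats a [S4Vectors::DataFrame] with columns \code{feature_id},
#'   \code{qc_cv}, \code{dilution_r2}, \code{complete}, \code{retained},
#'   \code{reason_dropped}.
#' @slot thresholds list of the thresholds applied.
#' @export
setClass("FilterReport",
    representation(stats = "DataFrame", thresholds = "list"))

setValidity("FilterReport", function(object) {
    st <- object@stats
    need <- c("feature_id", "qc_cv", "dilution_r2", "complete",
              "retained", "reason_dropped")
    miss <- setdiff(need, colnames(st))
    if (length(miss))
        return(paste("missing stats columns:", paste(miss, collapse = ", ")))
    if (!all(st$reason_dropped %in% c("cv", "linearity", "missing", "none")))
        return("invalid reason_dropped value")
    if (any(st$retained != (st$reason_dropped == "none")))
        return("retained flag inconsistent with reason_dropped")
    ok <- !is.na(st$qc_cv)
    if (any(st$qc_cv[ok] < 0)) return("qc_cv must be >= 0")
    TRUE
})

#' Log-transformed, Pareto-scaled statistical matrix
#'
#' The study-sample matrix entering the statistical branches: per retained
#' feature, log intensities are mean-centred and divided by the square root
#' of their standard deviation (Pareto scaling). QC and dilution samples are
#' excluded. The log-scale feature means and standard deviations are kept so
#' the transform can be inverted.
#'
#' @slot values numeric matrix, samples x features, no missing values.
#' @slot logBase one of \code{"natural"}, \code{"log2"}, \code{"log10"}.
#' @slot featureMeans,featureSds per-feature log-scale mean and sd.
#' @slot sampleClass factor with levels \code{control}, \code{case}.
#' @slot provenance list: filter report, transform parameters, dropped
#'   zero-variance features.
#' @export
setClass("ProcessedMatrix",
    representation(values = "matrix", logBase = "character",
                   featureMeans = "numeric", featureSds = "numeric",
                   sampleClass = "factor", provenance = "list"))

setValidity("ProcessedMatrix", function(object) {
    v <- object@values
    if (anyNA(v)) return("values must not contain missing entries")
    if (ncol(v) && max(abs(colMeans(v))) > 1e-9)
        return("columns must be mean-centred (tolerance 1e-9)")
    if (length(object@sampleClass) != nrow(v))
        return("sampleClass length must equal sample count")
    if (length(object@featureMeans) != ncol(v) ||
        length(object@featureSds) != ncol(v))
        return("featureMeans/featureSds must match feature count")
    TRUE
})

#' Fitted OPLS-DA model
#'
#' One predictive latent component plus \code{nOrth} orthogonal
#' (class-uncorrelated) components fitted by NIPALS-style orthogonal signal
#' correction. Class labels are coded numerically (+1 positive class, -1
#' other) and centred. The training matrix is retained so cross-validation,
#' permutation and jack-knife diagnostics can refit from the model object.
#'
#' @slot weights,loadings,scores predictive component (w, p, t).
#' @slot orthoWeights,orthoLoadings,orthoScores orthogonal components
#'   (features x nOrth and samples x nOrth matrices).
#' @slot b regression coefficient of the centred class code on the
#'   predictive score.
#' @slot R2Y fraction of class-code variance explained on the training data.
#' @slot vip variable importance in the projection (predictive component).
#' @slot splot DataFrame with \code{p1} (covariance of each feature with the
#'   predictive score) and \code{pcorr1} (the corresponding correlation).
#' @slot X training matrix (centred copies are recomputed on demand),
#'   \code{y} the class factor, \code{positiveClass} the level coded +1.
#' @slot xMeans column means used for centring; \code{yMean} mean class code.
#' @slot nOrth number of orthogonal components.
#' @export
setClass("OplsdaModel",
    representation(weights = "numeric", loadings = "numeric",
                   scores = "numeric",
                   orthoWeights = "matrix", orthoLoadings = "matrix",
                   orthoScores = "matrix",
                   b = "numeric", yMean = "numeric", xMeans = "numeric",
                   R2Y = "numeric", vip = "numeric", splot = "DataFrame",
                   nOrth = "integer", X = "matrix", y = "factor",
                   positiveClass = "character"))

setValidity("OplsdaModel", function(object) {
    J <- length(object@weights)
    if (J && abs(mean(object@vip^2) - 1) > 1e-8)
        return("mean of squared VIP over features must equal 1")
    if (object@R2Y < -1e-8 || object@R2Y > 1 + 1e-8)
        return("R2Y must lie in [0, 1]")
    pc <- object@splot$pcorr1
    if (length(pc) && any(abs(pc) > 1 + 1e-8, na.rm = TRUE))
        return("|pcorr1| must be <= 1")
    TRUE
})

#' Result of the bootstrapped wrapper feature selection
#'
#' Per classifier (PLS-DA, random forest, linear SVM): the S-tier feature
#' set, i.e. the minimal subset that survived every round of the
#' permutation-by-dichotomy selection, plus the out-of-bag balanced accuracy
#' of the classifier refit on that signature.
#'
#' @slot tiers named list of character vectors (S tier per classifier).
#' @slot accuracies named numeric; \code{NA} where the tier is empty.
#' @slot featureIds the feature universe the selection ran on.
#' @slot nBoot,pThreshold,seed the settings used.
#' @export
setClass("BiosignerResult",
    representation(tiers = "list", accuracies = "numeric",
                   featureIds = "character", nBoot = "integer",
                   pThreshold = "numeric", seed = "integer"))

setValidity("BiosignerResult", function(object) {
    if (!all(names(object@tiers) %in% c("plsda", "rf", "svm")))
        return("tiers must be named plsda/rf/svm")
    bad <- !vapply(object@tiers, function(s) all(s %in% object@featureIds),
                   logical(1))
    if (any(bad)) return("tier features outside the feature universe")
    acc <- object@accuracies[!is.na(object@accuracies)]
    if (any(acc < 0 | acc > 1)) return("accuracies must lie in [0, 1]")
    TRUE
})

#' Configuration of the resampled-LASSO stability selection
#'
#' @slot nSplits number of stratified train/test splits (default 1000).
#' @slot trainFraction fraction of each class allocated to training
#'   (default 2/3).
#' @slot aucGood,aucExcellent test-set AUC thresholds defining good and
#'   excellent models (defaults 0.8 and 0.9).
#' @slot thrI,thrII group thresholds as fractions of the excellent-model
#'   count (defaults 250/303 and 100/303, the study's absolute counts
#'   rescaled).
#' @slot lambdaRule \code{"1se"} or \code{"min"}: which internally
#'   cross-validated penalty is used within each training set.
#' @slot nFoldsInner folds of the internal cross-validation.
#' @slot seed master seed; one child seed is spawned per split.
#' @export
setClass("StabilityConfig",
    representation(nSplits = "integer", trainFraction = "numeric",
                   aucGood = "numeric", aucExcellent = "numeric",
                   thrI = "numeric", thrII = "numeric",
                   lambdaRule = "character", nFoldsInner = "integer",
                   seed = "integer"))

setValidity("StabilityConfig", function(object) {
    msg <- character(0)
    if (object@trainFraction <= 0 || object@trainFraction >= 1)
        msg <- c(msg, "trainFraction must lie strictly between 0 and 1")
    if (object@aucExcellent < object@aucGood)
        msg <- c(msg, "aucExcellent must be >= aucGood")
    if (!object@lambdaRule %in% c("1se", "min"))
        msg <- c(msg, "lambdaRule must be '1se' or 'min'")
    if (object@nSplits < 2L) msg <- c(msg, "nSplits must be >= 2")
    if (object@thrI < object@thrII)
        msg <- c(msg, "thrI must be >= thrII")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Result of the resampled-LASSO stability selection
#'
#' @slot featureIds feature universe.
#' @slot freq per-feature selection frequency F: count of excellent models (test AUC >=
#'   \code{aucExcellent}) in which the feature had a non-zero coefficient.
#' @slot coefMedian per-feature median coefficient C across excellent models (zeros
#'   included).
#' @slot group factor I/II/III by selection frequency among excellent models.
#' @slot splitAuc per-split test AUC.
#' @slot nGood,nExcellent,medianAuc,meanAuc summary of the split AUCs.
#' @slot valid whether the good-model gate (median AUC >= aucGood and at
#'   least one excellent model) fired; when \code{FALSE} the selection is
#'   not interpretable.
#' @slot excellentCoefs coefficient matrix of the excellent models
#'   (models x features).
#' @slot config the [StabilityConfig-class] used.
#' @export
setClass("StabilityResult",
    representation(featureIds = "character", freq = "integer",
                   coefMedian = "numeric",
                   group = "factor", splitAuc = "numeric",
                   nGood = "integer", nExcellent = "integer",
                   medianAuc = "numeric", meanAuc = "numeric",
                   valid = "logical", excellentCoefs = "matrix",
                   config = "StabilityConfig"))

setValidity("StabilityResult", function(object) {
    if (length(object@freq) != length(object@featureIds))
        return("freq must have one entry per feature")
    if (any(object@freq < 0L) || any(object@freq > object@nExcellent))
        return("freq must lie in [0, nExcellent]")
    if (!all(levels(object@group) == c("I", "II", "III")))
        return("group levels must be I, II, III")
    TRUE
})

#' Consensus signature across the four selection branches
#'
#' @slot flags logical matrix, features x methods (univariate, oplsda,
#'   biosigner, lasso).
#' @slot nMethods per-feature count of methods that flagged it.
#' @slot signature ordered character vector: the final signature.
#' @slot vennCounts named integer vector, one entry per non-empty method
#'   subset (names like \code{"univariate+oplsda"}).
#' @slot rule the combination rule used.
#' @export
setClass("ConsensusSignature",
    representation(flags = "matrix", nMethods = "integer",
                   signature = "character", vennCounts = "integer",
                   rule = "character"))

setValidity("ConsensusSignature", function(object) {
    if (!identical(colnames(object@flags),
                   c("univariate", "oplsda", "biosigner", "lasso")))
        return("flags columns must be univariate, oplsda, biosigner, lasso")
    if (!identical(object@nMethods, unname(as.integer(rowSums(object@flags)))))
        return("nMethods must equal the row sums of flags")
    if (sum(object@vennCounts) != sum(rowSums(object@flags) > 0))
        return("vennCounts must sum to the number of flagged features")
    TRUE
})
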