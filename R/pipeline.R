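.CONFIG_DEFAULTS <- list(
    max_cv = 0.30, min_r2 = 0.8, q_max = 0.05, fc_min = 1.5,
    vip_min = 1.3, pcorr_min = 0.4, require_stable = TRUE, n_orth = 1,
    cv_folds = 7,
    log_base = "natural", loess_span = 0.75, min_qc = 5, exact_limit = 30,
    filter_post_loess = FALSE,
    consensus_rule = "union-univ-oplsda", seed = 1,
    biosigner = list(n_boot = 50, p_threshold = 0.05, ntree = 100,
                     classifiers = c("plsda", "rf", "svm")),
    stability = list(n_splits = 1000, train_fraction = 2 / 3,
                     auc_good = 0.8, auc_excellent = 0.9,
                     thr_I = 250 / 303, thr_II = 100 / 303,
                     lambda_rule = "1se", n_folds_inner = 5),
    cohort = NULL)

.validateConfig <- function(cfg) {
    errs <- character(0)
    chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
    chk(cfg$max_cv > 0, "max_cv must be > 0")
    chk(cfg$min_r2 >= 0 && cfg$min_r2 <= 1, "min_r2 must lie in [0, 1]")
    chk(cfg$q_max > 0 && cfg$q_max <= 1, "q_max must lie in (0, 1]")
    chk(cfg$fc_min >= 1, "fc_min must be >= 1")
    chk(cfg$vip_min >= 0, "vip_min must be >= 0")
    chk(cfg$pcorr_min >= 0 && cfg$pcorr_min <= 1, "pcorr_min must lie in [0, 1]")
    chk(cfg$n_orth >= 0, "n_orth must be >= 0")
    chk(cfg$cv_folds >= 2, "cv_folds must be >= 2")
    chk(cfg$log_base %in% c("natural", "log2", "log10"),
        "log_base must be natural/log2/log10")
    chk(cfg$consensus_rule %in% c("union-univ-oplsda", "any-2", "all-flagged"),
        "unknown consensus_rule")
    chk(cfg$biosigner$n_boot >= 10, "biosigner n_boot must be >= 10")
    chk(cfg$biosigner$p_threshold > 0 && cfg$biosigner$p_threshold < 1,
        "biosigner p_threshold must lie in (0, 1)")
    chk(cfg$stability$train_fraction > 0 && cfg$stability$train_fraction < 1,
        "stability train_fraction must lie in (0, 1)")
    chk(cfg$stability$auc_excellent >= cfg$stability$auc_good,
        "stability auc_excellent must be >= auc_good")
    if (length(errs))
        stop("invalid pipeline configuration:\n  ",
             paste(errs, collapse = "\n  "))
    cfg
}

.mergeConfig <- function(defaults, given, path = "") {
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown))
        stop("unknown configuration key(s): ",
             paste(paste0(path, unknown), collapse = ", "))
    for (k in names(given)) {
        if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
            defaults[[k]] <- .mergeConfig(defaults[[k]], as.list(given[[k]]),
                                          paste0(path, k, "$"))
        else defaults[[k]] <- given[[k]]
    }
    defaults
}

#' Pipeline configuration
#'
#' Builds a validated configuration for [runPipeline()]. Defaults equal the
#' published thresholds: QC CV < 0.30, dilution r-squared >= 0.8, q < 0.05,
#' effective fold change > 1.5, VIP > 1.3, 50 wrapper bootstraps at p <
#' 0.05, 1000 stability splits with AUC gates 0.8/0.9. Unknown keys are
#' rejected; every threshold is checked against its documented domain.
#'
#' @param ... named overrides of the defaults; nested lists
#'   (\code{biosigner}, \code{stability}, \code{cohort}) are merged by key.
#' @return a validated configuration list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(...) {
    cfg <- .mergeConfig(.CONFIG_DEFAULTS, list(...))
    ## cohort has open-ended keys; validated by cohortSpec() itself
    cfg <- .validateConfig(cfg)
    class(cfg) <- c("PipelineConfig", "list")
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' Strict: unknown keys raise an error, and all thresholds are validated.
#'
#' @param path YAML file.
#' @return a validated configuration (see [pipelineConfig()]).
#' @export
readPipelineConfig <- function(path) {
    given <- yaml::read_yaml(path)
    do.call(pipelineConfig, given)
}

#' Run the full consensus pipeline
#'
#' Executes drift correction, quality filtering, log/Pareto transformation,
#' the univariate, OPLS-DA, wrapper and LASSO-stability selections, and the
#' consensus combination, with per-stage error reporting. When \code{input}
#' is \code{NULL} a synthetic cohort is generated from the configuration's
#' \code{cohort} entry (or the defaults).
#'
#' @param config a configuration from [pipelineConfig()].
#' @param input optional \linkS4class{MetaboExperiment}; otherwise a cohort
#'   is simulated.
#' @param outDir optional directory; when given, intermediates and the
#'   consensus report are written there.
#' @return list with the intermediates of every stage (\code{table},
#'   \code{filter_report}, \code{processed}, \code{stats}, \code{model},
#'   \code{cv}, \code{selections}, \code{biosigner}, \code{stability},
#'   \code{consensus}, \code{summaries}).
#' @export
runPipeline <- function(config = pipelineConfig(), input = NULL,
                        outDir = NULL) {
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    me <- stage("simulate", {
        if (is.null(input))
            generateCohort(do.call(cohortSpec,
                                   c(config$cohort,
                                     if (is.null(config$cohort$seed))
                                         list(seed = config$seed))))
        else input
    })
    corrected <- stage("drift-correction",
        correctDrift(me, span = config$loess_span, minQC = config$min_qc))
    ## quality filters run on pre-correction intensities by default: the QC
    ## CV must measure raw analytical repeatability, not the post-LOESS
    ## residuals, and the dilution triple sits beyond the last QC where the
    ## LOESS fit extrapolates
    report <- stage("filtering",
        filterFeatures(if (config$filter_post_loess) corrected else me,
                       maxCv = config$max_cv, minR2 = config$min_r2))
    processed <- stage("transform",
        logParetoTransform(corrected, report, base = config$log_base))
    feats <- colnames(processed@values)

    stats <- stage("univariate",
        univariateStats(corrected, features = feats,
                        exactLimit = config$exact_limit))
    univSel <- selectUnivariate(stats, qMax = config$q_max,
                                fcMin = config$fc_min)

    model <- stage("oplsda", fitOplsda(processed, nOrth = config$n_orth))
    cv <- stage("oplsda-cv",
        crossValidateOplsda(model, folds = config$cv_folds,
                            seed = config$seed))
    oplsSel <- stage("oplsda-select",
        selectOplsda(model, vipMin = config$vip_min,
                     pcorrMin = config$pcorr_min,
                     requireStable = config$require_stable,
                     folds = config$cv_folds, seed = config$seed))

    bios <- stage("biosigner",
        biosignerSelect(processed, nBoot = config$biosigner$n_boot,
                        pThreshold = config$biosigner$p_threshold,
                        seed = config$seed,
                        classifiers = config$biosigner$classifiers,
                        ntree = config$biosigner$ntree))
    biosSel <- unique(unlist(tiers(bios)))

    stab <- stage("lasso-stability",
        runStabilitySelection(processed, config = stabilityConfig(
            nSplits = config$stability$n_splits,
            trainFraction = config$stability$train_fraction,
            aucGood = config$stability$auc_good,
            aucExcellent = config$stability$auc_excellent,
            thrI = config$stability$thr_I,
            thrII = config$stability$thr_II,
            lambdaRule = config$stability$lambda_rule,
            nFoldsInner = config$stability$n_folds_inner,
            seed = config$seed)))
    lassoSel <- if (stab@valid)
        selectLassoFeatures(stab, stats, vip(model),
                            vipMin = config$vip_min, qMax = config$q_max)
    else character(0)

    selections <- list(univariate = univSel, oplsda = oplsSel,
                       biosigner = biosSel, lasso = lassoSel)
    consensus <- stage("consensus",
        buildConsensus(selections, universe = feats,
                       rule = config$consensus_rule, stats = stats))
    summaries <- list(
        oplsda = c(R2Y = model@R2Y, Q2 = cv$Q2, cv_anova_p = cv$cvAnovaP),
        biosigner = bios@accuracies,
        stability = c(median_auc = stab@medianAuc, mean_auc = stab@meanAuc,
                      n_good = stab@nGood, n_excellent = stab@nExcellent))

    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeIntensityTable(corrected,
                            file.path(outDir, "corrected_intensities.csv"))
        utils::write.table(as.data.frame(filterStats(report)),
                           file.path(outDir, "filter_report.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(as.data.frame(stats),
                           file.path(outDir, "univariate_stats.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (stab@valid)
            utils::write.table(as.data.frame(yplotData(stab)),
                               file.path(outDir, "yplot.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        writeReport(consensus, outDir, stats = stats, vip = vip(model),
                    summaries = summaries,
                    config = unclass(config))
    }
    list(table = me, corrected = corrected, filter_report = report,
         processed = processed, stats = stats, model = model, cv = cv,
         selections = selections, biosigner = bios, stability = stab,
         consensus = consensus, summaries = summaries, config = config)
}
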