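.CONSENSUS_METHODS <- c("univariate", "oplsda", "biosigner", "lasso")

#' Combine the four selection branches into a consensus signature
#'
#' Builds the per-feature method flags, the Venn census over non-empty
#' method subsets, and the final signature under the chosen rule:
#' \describe{
#'   \item{\code{"union-univ-oplsda"}}{(default) the union of the univariate
#'     and OPLS-DA selections -- the strict-criteria rule that yields the
#'     nine-metabolite signature from the published selection table;}
#'   \item{\code{"any-2"}}{features flagged by at least two methods;}
#'   \item{\code{"all-flagged"}}{every feature flagged by at least one
#'     method (the full Venn union).}
#' }
#' The signature is ordered by the number of supporting methods
#' (descending), then by q-value (ascending) when \code{stats} is supplied,
#' then alphabetically.
#'
#' @param selections named list with elements \code{univariate},
#'   \code{oplsda}, \code{biosigner}, \code{lasso}, each a character vector
#'   of feature identifiers.
#' @param universe character vector of all candidate features; every
#'   selected feature must belong to it.
#' @param rule combination rule, see above.
#' @param stats optional per-feature statistics (columns \code{feature_id},
#'   \code{q}) used only for ordering.
#' @return a \linkS4class{ConsensusSignature}.
#' @export
buildConsensus <- function(selections, universe,
                           rule = c("union-univ-oplsda", "any-2",
                                    "all-flagged"),
                           stats = NULL) {
    rule <- match.arg(rule)
    miss <- setdiff(.CONSENSUS_METHODS, names(selections))
    if (length(miss))
        stop("selections must be named: ", paste(miss, collapse = ", "))
    selections <- selections[.CONSENSUS_METHODS]
    unknown <- setdiff(unique(unlist(selections)), universe)
    if (length(unknown))
        stop("selected feature(s) outside the universe: ",
             paste(unknown, collapse = ", "))
    flags <- vapply(selections, function(s) universe %in% s,
                    logical(length(universe)))
    flags <- matrix(flags, nrow = length(universe),
                    dimnames = list(universe, .CONSENSUS_METHODS))
    nMethods <- as.integer(rowSums(flags))
    sig <- switch(rule,
        "union-univ-oplsda" = universe[flags[, "univariate"] | flags[, "oplsda"]],
        "any-2" = universe[nMethods >= 2L],
        "all-flagged" = universe[nMethods >= 1L])
    q <- rep(NA_real_, length(universe))
    names(q) <- universe
    if (!is.null(stats))
        q[intersect(universe, stats$feature_id)] <-
            setNames(stats$q, stats$feature_id)[
                intersect(universe, stats$feature_id)]
    ord <- order(-nMethods[match(sig, universe)], q[sig], sig)
    sig <- sig[ord]
    flagged <- nMethods > 0
    keys <- apply(flags[flagged, , drop = FALSE], 1, function(r)
        paste(.CONSENSUS_METHODS[r], collapse = "+"))
    venn <- if (length(keys)) {
        tab <- table(keys)
        setNames(as.integer(tab), names(tab))
    } else integer(0)
    new("ConsensusSignature", flags = flags, nMethods = nMethods,
        signature = sig, vennCounts = venn, rule = rule)
}

#' @rdname ConsensusSignature
#' @export
setMethod("signatureFeatures", "ConsensusSignature",
          function(object) object@signature)

#' @rdname ConsensusSignature
#' @export
setMethod("vennCounts", "ConsensusSignature", function(object) object@vennCounts)

setMethod("show", "ConsensusSignature", function(object) {
    cat("ConsensusSignature (rule:", object@rule, ")\n")
    cat("  per-method counts:",
        paste(colnames(object@flags), colSums(object@flags),
              sep = "=", collapse = ", "), "\n")
    cat("  signature (", length(object@signature), "):",
        paste(object@signature, collapse = ", "), "\n")
})

## Deterministic md5 of an R object via its canonical JSON serialisation.
.configHash <- function(x) {
    f <- tempfile(fileext = ".json")
    on.exit(unlink(f))
    jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
    unname(tools::md5sum(f))
}

#' Write the consensus report
#'
#' Emits a deterministic, regenerable report of the whole analysis: a
#' Markdown methods echo (parameters, filter census, per-method selections,
#' a selection-table-style feature summary, Venn counts and the final
#' signature), a JSON twin of the same content, the Venn counts as CSV and
#' the feature summary as TSV. Every file embeds the configuration hash so
#' outputs can be matched to the run that produced them.
#'
#' @param signature a \linkS4class{ConsensusSignature}.
#' @param dir output directory (created if needed).
#' @param stats optional per-feature statistics (from [univariateStats()]).
#' @param vip optional named VIP vector.
#' @param summaries optional list of model summaries (numbers only) echoed
#'   into the report.
#' @param config optional configuration list; hashed into every output.
#' @return (invisibly) the paths written.
#' @export
writeReport <- function(signature, dir, stats = NULL, vip = NULL,
                        summaries = list(), config = list()) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    hash <- .configHash(config)
    flags <- signature@flags
    feat <- rownames(flags)
    tabl <- data.frame(
        feature_id = feat,
        n_methods = signature@nMethods,
        univariate = flags[, "univariate"],
        oplsda = flags[, "oplsda"],
        biosigner = flags[, "biosigner"],
        lasso = flags[, "lasso"],
        in_signature = feat %in% signature@signature,
        stringsAsFactors = FALSE)
    if (!is.null(stats)) {
        m <- match(feat, stats$feature_id)
        tabl$fc <- stats$fc[m]
        tabl$q <- stats$q[m]
    }
    if (!is.null(vip)) tabl$vip <- unname(vip[feat])
    tabl <- tabl[order(-tabl$n_methods, tabl$feature_id), ]

    tsv <- file.path(dir, "feature_summary.tsv")
    utils::write.table(tabl, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    vennCsv <- file.path(dir, "venn_counts.csv")
    utils::write.csv(
        data.frame(subset = names(signature@vennCounts),
                   count = as.integer(signature@vennCounts)),
        vennCsv, row.names = FALSE, quote = FALSE)

    js <- file.path(dir, "report.json")
    jsonlite::write_json(list(
        config_hash = hash,
        rule = signature@rule,
        config = config,
        summaries = summaries,
        per_method_counts = as.list(colSums(flags)),
        venn_counts = as.list(signature@vennCounts),
        signature = signature@signature),
        js, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)

    md <- file.path(dir, "report.md")
    lines <- c(
        "# Consensus metabolite signature",
        "",
        paste0("Configuration hash: `", hash, "`"),
        "",
        paste0("Combination rule: `", signature@rule, "`"),
        "",
        "## Per-method selections",
        "",
        vapply(colnames(flags), function(mn) sprintf(
            "- %s (%d): %s", mn, sum(flags[, mn]),
            paste(feat[flags[, mn]], collapse = ", ")), character(1)),
        "",
        "## Model summaries",
        "",
        if (length(summaries))
            vapply(names(summaries), function(nm) sprintf(
                "- %s: %s", nm,
                paste(names(summaries[[nm]]),
                      vapply(summaries[[nm]], function(v)
                          format(v, digits = 6), character(1)),
                      sep = "=", collapse = ", ")), character(1))
        else "- none recorded",
        "",
        "## Venn counts",
        "",
        sprintf("- %s: %d", names(signature@vennCounts),
                as.integer(signature@vennCounts)),
        "",
        sprintf("## Signature (%d features)", length(signature@signature)),
        "",
        sprintf("%d. %s", seq_along(signature@signature),
                signature@signature))
    writeLines(lines, md)
    invisible(c(md, js, tsv, vennCsv))
}
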