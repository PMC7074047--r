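#' Read a feature-intensity table from CSV/TSV
#'
#' Expects a header row and the metadata columns \code{sample_id},
#' \code{role}, \code{injection_order}, \code{dilution_factor}, \code{class}
#' followed by one column per feature (samples in rows). Every schema
#' violation -- duplicated sample identifiers, negative intensities, missing
#' or duplicated injection orders, unknown roles -- is collected and
#' reported in a single error, with row/column positions.
#'
#' @param path file path; the separator is inferred from the extension
#'   (.tsv/.txt = tab, otherwise comma).
#' @return a \linkS4class{MetaboExperiment}.
#' @export
readIntensityTable <- function(path) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    meta <- c("sample_id", "role", "injection_order", "dilution_factor",
              "class")
    missCols <- setdiff(meta, colnames(df))
    if (length(missCols))
        stop("missing metadata column(s): ", paste(missCols, collapse = ", "))
    featCols <- setdiff(colnames(df), meta)
    errs <- character(0)
    dup <- df$sample_id[duplicated(df$sample_id)]
    if (length(dup))
        errs <- c(errs, paste("duplicated sample id(s):",
                              paste(unique(dup), collapse = ", ")))
    badRole <- !df$role %in% .SAMPLE_ROLES
    if (any(badRole))
        errs <- c(errs, paste0("invalid role in row(s) ",
                               paste(which(badRole), collapse = ", ")))
    ord <- suppressWarnings(as.integer(df$injection_order))
    if (anyNA(ord))
        errs <- c(errs, paste0("missing injection order in row(s) ",
                               paste(which(is.na(ord)), collapse = ", ")))
    else if (anyDuplicated(ord))
        errs <- c(errs, paste0("duplicated injection order in row(s) ",
                               paste(which(duplicated(ord)), collapse = ", ")))
    for (fc in featCols) {
        v <- suppressWarnings(as.numeric(df[[fc]]))
        neg <- which(!is.na(v) & v < 0)
        if (length(neg))
            errs <- c(errs, paste0("negative intensity in column '", fc,
                                   "', row(s) ", paste(neg, collapse = ", ")))
    }
    if (length(errs))
        stop("invalid intensity table:\n  ", paste(errs, collapse = "\n  "))
    x <- t(as.matrix(df[, featCols, drop = FALSE]))
    colnames(x) <- df$sample_id
    MetaboExperiment(x, role = df$role, injectionOrder = ord,
                     dilutionFactor = as.numeric(df$dilution_factor))
}

#' Write a feature-intensity table as CSV/TSV
#'
#' Inverse of [readIntensityTable()]: samples in rows, metadata columns
#' first, one column per feature.
#'
#' @param table a \linkS4class{MetaboExperiment}.
#' @param path output file; extension selects the separator.
#' @return (invisibly) the path.
#' @export
writeIntensityTable <- function(table, path) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
    cd <- colData(table)
    cls <- ifelse(cd$role %in% c("case", "control"), cd$role, NA)
    df <- data.frame(sample_id = colnames(table),
                     role = cd$role,
                     injection_order = cd$injection_order,
                     dilution_factor = cd$dilution_factor,
                     class = cls,
                     t(assay(table, "intensity")),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Load the published metabolite-selection table
#'
#' The packaged fixture transcribes the study's selection table: 28
#' FDR-significant metabolites with their median-ratio fold change
#' (case/control), direction, Benjamini-Hochberg q-value, OPLS-DA VIP and
#' the per-method selection flags, plus one supplementary row
#' (5,6-dihydrouracil, q = 0.0986) that enters only the LASSO group-I
#' discussion. The effective fold change max(FC, 1/FC) is added.
#'
#' @param includeSupplementary keep the supplementary row (default TRUE).
#' @return [S4Vectors::DataFrame] with columns \code{feature_id}, \code{fc},
#'   \code{direction}, \code{effective_fc}, \code{q}, \code{vip},
#'   \code{flag_oplsda}, \code{flag_biosigner}, \code{flag_lasso},
#'   \code{supplementary}.
#' @export
loadTable1Fixture <- function(includeSupplementary = TRUE) {
    path <- system.file("extdata", "table1_metabolite_stats.tsv",
                        package = "metaboconsensus", mustWork = TRUE)
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "")
    if (!includeSupplementary) df <- df[!df$supplementary, ]
    S4Vectors::DataFrame(
        feature_id = df$metabolite,
        fc = df$fold_change,
        direction = df$direction,
        effective_fc = pmax(df$fold_change, 1 / df$fold_change),
        q = df$q_value,
        vip = df$vip,
        flag_oplsda = df$flag_oplsda,
        flag_biosigner = df$flag_biosigner,
        flag_lasso = df$flag_lasso,
        supplementary = df$supplementary,
        row.names = df$metabolite)
}
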