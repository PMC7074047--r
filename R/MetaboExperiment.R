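#' Construct a MetaboExperiment
#'
#' @param intensities numeric matrix, features in rows, samples in columns.
#'   Row and column names are used as feature and sample identifiers.
#' @param role character vector of sample roles (\code{"case"},
#'   \code{"control"}, \code{"qc"}, \code{"dilution"}), one per sample.
#' @param injectionOrder unique positive integers, one per sample.
#' @param dilutionFactor numeric, \code{NA} except on dilution samples where
#'   it must be 1, 0.5 or 0.25.
#' @param metadata optional list stored as experiment metadata (the cohort
#'   generator records the planted ground truth here).
#' @return a \linkS4class{MetaboExperiment}.
#' @examples
#' x <- matrix(100, 2, 4, dimnames = list(c("M1", "M2"), paste0("S", 1:4)))
#' me <- MetaboExperiment(x, role = c("case", "case", "control", "qc"),
#'                        injectionOrder = 1:4)
#' sampleRole(me)
#' @export
MetaboExperiment <- function(intensities, role, injectionOrder,
                             dilutionFactor = NA_real_, metadata = list()) {
    intensities <- as.matrix(intensities)
    if (is.null(rownames(intensities)))
        rownames(intensities) <- sprintf("F%03d", seq_len(nrow(intensities)))
    if (is.null(colnames(intensities)))
        colnames(intensities) <- sprintf("S%03d", seq_len(ncol(intensities)))
    n <- ncol(intensities)
    dilutionFactor <- rep_len(dilutionFactor, n)
    cd <- S4Vectors::DataFrame(
        role = as.character(role),
        injection_order = as.integer(injectionOrder),
        dilution_factor = as.numeric(dilutionFactor),
        row.names = colnames(intensities))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = intensities), colData = cd,
        metadata = metadata)
    new("MetaboExperiment", se)
}

#' @rdname MetaboExperiment
#' @aliases sampleRole injectionOrder dilutionFactor intensityMatrix
#'   plantedEffects studySamples
#' @export
setMethod("sampleRole", "MetaboExperiment",
          function(object) setNames(colData(object)$role, colnames(object)))

#' @rdname MetaboExperiment
#' @export
setMethod("injectionOrder", "MetaboExperiment",
          function(object) setNames(colData(object)$injection_order,
                                    colnames(object)))

#' @rdname MetaboExperiment
#' @export
setMethod("dilutionFactor", "MetaboExperiment",
          function(object) setNames(colData(object)$dilution_factor,
                                    colnames(object)))

#' @rdname MetaboExperiment
#' @export
setMethod("intensityMatrix", "MetaboExperiment",
          function(object) assay(object, "intensity"))

#' @rdname MetaboExperiment
#' @export
setMethod("plantedEffects", "MetaboExperiment",
          function(object) S4Vectors::metadata(object)$planted_effects)

#' Logical index of the study (case/control) samples
#' @param object a \linkS4class{MetaboExperiment}.
#' @return named logical vector.
#' @export
studySamples <- function(object)
    setNames(colData(object)$role %in% c("case", "control"), colnames(object))

setMethod("show", "MetaboExperiment", function(object) {
    role <- colData(object)$role
    cat("MetaboExperiment:", nrow(object), "features,",
        sum(role == "case"), "case /", sum(role == "control"),
        "control study samples,", sum(role == "qc"), "QC,",
        sum(role == "dilution"), "dilution injections\n")
    pe <- plantedEffects(object)
    if (!is.null(pe))
        cat("  planted effects on", nrow(pe), "features\n")
})
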