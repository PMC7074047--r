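#' @rdname MetaboExperiment
#' @param object a \linkS4class{MetaboExperiment}.
#' @export
setGeneric("sampleRole", function(object) standardGeneric("sampleRole"))

#' @rdname MetaboExperiment
#' @export
setGeneric("injectionOrder", function(object) standardGeneric("injectionOrder"))

#' @rdname MetaboExperiment
#' @export
setGeneric("dilutionFactor", function(object) standardGeneric("dilutionFactor"))

#' @rdname MetaboExperiment
#' @export
setGeneric("intensityMatrix", function(object) standardGeneric("intensityMatrix"))

#' @rdname MetaboExperiment
#' @export
setGeneric("plantedEffects", function(object) standardGeneric("plantedEffects"))

#' @rdname FilterReport
#' @param object a \linkS4class{FilterReport}.
#' @export
setGeneric("filterStats", function(object) standardGeneric("filterStats"))

#' @rdname FilterReport
#' @export
setGeneric("retainedFeatures", function(object) standardGeneric("retainedFeatures"))

#' Fit an OPLS-DA model
#'
#' @param x a samples-by-features numeric matrix (column-centred internally)
#'   or a \linkS4class{ProcessedMatrix}.
#' @param ... further arguments: \code{y} (class factor, required for the
#'   matrix method), \code{nOrth} (number of orthogonal components, default
#'   1), \code{positiveClass} (class coded +1, default the last factor
#'   level).
#' @return an \linkS4class{OplsdaModel}.
#' @export
setGeneric("fitOplsda", function(x, ...) standardGeneric("fitOplsda"))

#' @rdname OplsdaModel
#' @param object an \linkS4class{OplsdaModel}.
#' @export
setGeneric("vip", function(object, ...) standardGeneric("vip"))

#' @rdname OplsdaModel
#' @export
setGeneric("splotData", function(object) standardGeneric("splotData"))

#' @rdname BiosignerResult
#' @param object a \linkS4class{BiosignerResult}.
#' @export
setGeneric("tiers", function(object) standardGeneric("tiers"))

#' @rdname StabilityResult
#' @param object a \linkS4class{StabilityResult}.
#' @export
setGeneric("selectionFrequency", function(object) standardGeneric("selectionFrequency"))

#' @rdname StabilityResult
#' @export
setGeneric("medianCoefficient", function(object) standardGeneric("medianCoefficient"))

#' @rdname StabilityResult
#' @export
setGeneric("stabilityGroup", function(object) standardGeneric("stabilityGroup"))

#' @rdname ConsensusSignature
#' @param object a \linkS4class{ConsensusSignature}.
#' @export
setGeneric("signatureFeatures", function(object) standardGeneric("signatureFeatures"))

#' @rdname ConsensusSignature
#' @export
setGeneric("vennCounts", function(object) standardGeneric("vennCounts"))
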