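#' Generics for octavesad classes
#'
#' Accessor and analysis generics used across the package's S4 classes.
#'
#' @param object,x an octavesad S4 object.
#' @param ... further arguments passed to methods.
#' @name octavesad-generics
#' @keywords internal
NULL

#' @rdname octavesad-generics
#' @export
setGeneric("communityName", function(object) standardGeneric("communityName"))

#' @rdname octavesad-generics
#' @export
setGeneric("layerName", function(object) standardGeneric("layerName"))

#' @rdname octavesad-generics
#' @export
setGeneric("speciesNames", function(object) standardGeneric("speciesNames"))

#' @rdname octavesad-generics
#' @export
setGeneric("abundances", function(object) standardGeneric("abundances"))

#' @rdname octavesad-generics
#' @export
setGeneric("totalSpecies", function(object) standardGeneric("totalSpecies"))

#' @rdname octavesad-generics
#' @export
setGeneric("totalIndividuals",
           function(object) standardGeneric("totalIndividuals"))

#' @rdname octavesad-generics
#' @export
setGeneric("descriptiveStats",
           function(object, ...) standardGeneric("descriptiveStats"))

#' @rdname octavesad-generics
#' @export
setGeneric("binOctaves", function(object, ...) standardGeneric("binOctaves"))

#' @rdname octavesad-generics
#' @export
setGeneric("octaves", function(object) standardGeneric("octaves"))

#' @rdname octavesad-generics
#' @export
setGeneric("octaveCounts", function(object) standardGeneric("octaveCounts"))

#' @rdname octavesad-generics
#' @export
setGeneric("octaveDialect", function(object) standardGeneric("octaveDialect"))

#' @rdname octavesad-generics
#' @export
setGeneric("belowVeil", function(object) standardGeneric("belowVeil"))

#' @rdname octavesad-generics
#' @export
setGeneric("octaveTotal", function(object) standardGeneric("octaveTotal"))

#' @rdname octavesad-generics
#' @export
setGeneric("modalOctave", function(object) standardGeneric("modalOctave"))

#' @rdname octavesad-generics
#' @export
setGeneric("modelName", function(object) standardGeneric("modelName"))

#' @rdname octavesad-generics
#' @export
setGeneric("nParameters", function(object) standardGeneric("nParameters"))

#' @rdname octavesad-generics
#' @export
setGeneric("parameters", function(object) standardGeneric("parameters"))

#' @rdname octavesad-generics
#' @export
setGeneric("fittedValues", function(object) standardGeneric("fittedValues"))

#' @rdname octavesad-generics
#' @export
setGeneric("gofStats", function(object) standardGeneric("gofStats"))

#' @rdname octavesad-generics
#' @export
setGeneric("totalRichness",
           function(object, ...) standardGeneric("totalRichness"))

#' @rdname octavesad-generics
#' @export
setGeneric("fitModel",
           function(object, histogram, ...) standardGeneric("fitModel"))

#' @rdname octavesad-generics
#' @export
setGeneric("sadFits", function(object) standardGeneric("sadFits"))

#' @rdname octavesad-generics
#' @export
setGeneric("selectBest", function(object, ...) standardGeneric("selectBest"))

#' @rdname octavesad-generics
#' @export
setGeneric("adequacyFlags",
           function(object, ...) standardGeneric("adequacyFlags"))

#' @rdname octavesad-generics
#' @export
setGeneric("truncatedDensity",
           function(object, ...) standardGeneric("truncatedDensity"))

#' @rdname octavesad-generics
#' @export
setGeneric("peakHeight", function(object) standardGeneric("peakHeight"))
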