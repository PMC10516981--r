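#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Accessors for the package's core classes; see the class pages for
#' details.
#'
#' @param object a package object.
#' @param ... passed to methods.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))

#' @rdname accessors
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))

#' @rdname accessors
#' @export
setGeneric("modelGenes", function(object) standardGeneric("modelGenes"))

#' @rdname accessors
#' @export
setGeneric("lowerBounds", function(object) standardGeneric("lowerBounds"))

#' @rdname accessors
#' @export
setGeneric("upperBounds", function(object) standardGeneric("upperBounds"))

#' @rdname accessors
#' @export
setGeneric("objectiveCoefficients",
           function(object) standardGeneric("objectiveCoefficients"))

#' @rdname accessors
#' @export
setGeneric("gprRules", function(object) standardGeneric("gprRules"))

#' @rdname accessors
#' @export
setGeneric("stoichiometricMatrix",
           function(object) standardGeneric("stoichiometricMatrix"))

#' @rdname accessors
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))

#' @rdname accessors
#' @export
setGeneric("solutionStatus", function(object) standardGeneric("solutionStatus"))

#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))

#' @rdname accessors
#' @export
setGeneric("koScores", function(object) standardGeneric("koScores"))

#' @rdname accessors
#' @export
setGeneric("mutationCalls", function(object) standardGeneric("mutationCalls"))

#' @rdname accessors
#' @export
setGeneric("scanResults", function(object) standardGeneric("scanResults"))

#' @rdname accessors
#' @export
setGeneric("scanMetadata", function(object) standardGeneric("scanMetadata"))

#' @rdname accessors
#' @export
setGeneric("significantPairs",
           function(object, ...) standardGeneric("significantPairs"))
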