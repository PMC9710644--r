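#' @import methods
NULL

#' Sample identifiers of an object
#'
#' @param x a \linkS4class{ProfileTable}, \linkS4class{DistanceMatrix} or
#'   \linkS4class{PcoaResult}.
#' @return Character vector of sample identifiers, in storage order.
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' Feature (gene-family) identifiers of an object
#'
#' @param x a \linkS4class{ProfileTable}.
#' @return Character vector of feature identifiers, in storage order.
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' Abundance matrix of a profile table
#'
#' @param x a \linkS4class{ProfileTable}.
#' @return Numeric samples x features matrix with dimnames.
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
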