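#' @import methods
NULL

#' Number of atoms in an object
#'
#' @param x an object holding atomic data
#' @return integer atom count
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Atomic coordinates
#'
#' @param x an object holding atomic data
#' @return numeric matrix of Cartesian coordinates (Angstrom)
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))

#' Invariant scalar feature channels
#'
#' @param x a [NodeFeatures], [TokenArray] or [FeatureStore]
#' @return numeric array of scalar channels
#' @export
setGeneric("scalarFeatures", function(x) standardGeneric("scalarFeatures"))

#' Equivariant vector feature channels
#'
#' @param x a [NodeFeatures], [TokenArray] or [FeatureStore]
#' @return numeric array of vector channels (with a length-3 Cartesian axis)
#' @export
setGeneric("vectorFeatures", function(x) standardGeneric("vectorFeatures"))

#' Number of structural tokens
#'
#' @param x a [TokenArray] or [FeatureStore]
#' @return integer token count
#' @export
setGeneric("nTokens", function(x) standardGeneric("nTokens"))

#' Number of trajectory frames
#'
#' @param x a [FeatureStore]
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Provenance metadata of a feature store
#'
#' @param x a [FeatureStore]
#' @return named list of metadata (encoder checkpoint hash, partition hash,
#'   selection, frame stride, units)
#' @export
setGeneric("storeMetadata", function(x) standardGeneric("storeMetadata"))

#' Per-frame state labels as an integer vector
#'
#' @param x a [StateLabels]
#' @return integer vector of labels
#' @export
setGeneric("labelVector", function(x) standardGeneric("labelVector"))

#' Number of distinct populated states
#'
#' @param x a [StateLabels]
#' @return integer count of distinct labels present
#' @export
setGeneric("populatedCount", function(x) standardGeneric("populatedCount"))
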