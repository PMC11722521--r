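#' Molecular system: topology and one set of coordinates
#'
#' Light container for a molecular structure: element symbols, atomic numbers,
#' residue assignment, and Cartesian coordinates in Angstrom.  Residue indices
#' define the default token partition used by [partitionByResidue()].
#'
#' @slot element character vector of element symbols, length N
#' @slot atomicNumber integer vector of atomic numbers, length N
#' @slot resid integer vector of residue indices (1-based), length N
#' @slot resname character vector of residue names, length N
#' @slot coords numeric N x 3 matrix, Angstrom
#'
#' @export
setClass("MolSystem",
  representation(
    element = "character",
    atomicNumber = "integer",
    resid = "integer",
    resname = "character",
    coords = "matrix"
  ),
  validity = function(object) {
    n <- length(object@element)
    if (length(object@atomicNumber) != n) return("atomicNumber length mismatch")
    if (length(object@resid) != n) return("resid length mismatch")
    if (length(object@resname) != n) return("resname length mismatch")
    if (!is.numeric(object@coords) || ncol(object@coords) != 3L ||
        nrow(object@coords) != n) {
      return("coords must be an N x 3 numeric matrix")
    }
    if (any(!is.finite(object@coords))) return("coords must be finite")
    if (any(object@atomicNumber < 1L)) return("atomic numbers must be >= 1")
    TRUE
  }
)

#' Construct a MolSystem
#'
#' @param element character element symbols
#' @param coords N x 3 coordinate matrix (Angstrom)
#' @param resid residue index per atom (default all 1)
#' @param resname residue name per atom (default "UNK")
#' @param atomicNumber atomic numbers; derived from `element` when omitted
#' @return a [MolSystem]
#' @examples
#' molSystem(c("O", "H", "H"),
#'           matrix(c(0, 0, 0, 0.96, 0, 0, -0.24, 0.93, 0), 3, 3, byrow = TRUE))
#' @export
molSystem <- function(element, coords, resid = rep(1L, length(element)),
                      resname = rep("UNK", length(element)),
                      atomicNumber = NULL) {
  if (is.null(atomicNumber)) atomicNumber <- elementToZ(element)
  new("MolSystem",
      element = as.character(element),
      atomicNumber = as.integer(atomicNumber),
      resid = as.integer(resid),
      resname = as.character(resname),
      coords = as.matrix(coords))
}

#' Atomic graph under a distance cutoff
#'
#' Directed edge list over atoms: (i, j) is present iff the interatomic
#' distance is at most `cutoff` and i != j.  The edge list is symmetric and
#' free of self-edges; this locality structure is what restricts message
#' passing to nearby atoms.
#'
#' @slot atomicNumbers integer vector [N]
#' @slot coords numeric N x 3 matrix (Angstrom)
#' @slot edges integer E x 2 matrix of directed edges (receiver i, sender j)
#' @slot cutoff numeric cutoff radius (Angstrom)
#'
#' @export
setClass("AtomicGraph",
  representation(
    atomicNumbers = "integer",
    coords = "matrix",
    edges = "matrix",
    cutoff = "numeric"
  ),
  validity = function(object) {
    n <- length(object@atomicNumbers)
    if (nrow(object@coords) != n || ncol(object@coords) != 3L) {
      return("coords must be N x 3")
    }
    if (any(!is.finite(object@coords))) return("coords must be finite")
    if (object@cutoff <= 0) return("cutoff must be positive")
    e <- object@edges
    if (nrow(e) > 0) {
      if (any(e[, 1L] == e[, 2L])) return("self-edges are not allowed")
      key <- paste(e[, 1L], e[, 2L])
      rkey <- paste(e[, 2L], e[, 1L])
      if (!all(rkey %in% key)) return("edge list must be symmetric")
      d <- sqrt(rowSums((object@coords[e[, 1L], , drop = FALSE] -
                           object@coords[e[, 2L], , drop = FALSE])^2))
      if (any(d > object@cutoff + 1e-9)) {
        return("edge present beyond the cutoff distance")
      }
    }
    TRUE
  }
)

#' Per-atom scalar and vector features
#'
#' Output of the equivariant encoder: for each atom, d invariant scalar
#' channels and d equivariant 3-vector channels.  Under a rigid rotation of
#' the input coordinates the scalars are unchanged and every vector channel
#' rotates; permuting atoms permutes rows.
#'
#' @slot scalars numeric N x d matrix
#' @slot vectors numeric N x 3 x d array
#'
#' @export
setClass("NodeFeatures",
  representation(scalars = "matrix", vectors = "array"),
  validity = function(object) {
    dm <- dim(object@vectors)
    if (length(dm) != 3L || dm[2L] != 3L) return("vectors must be N x 3 x d")
    if (dm[1L] != nrow(object@scalars)) return("atom count mismatch")
    if (dm[3L] != ncol(object@scalars)) return("channel count mismatch")
    TRUE
  }
)

#' Structural tokens: pooled per-unit features
#'
#' Token m is the exact sum of the per-atom features over the atoms of
#' structural unit m (e.g. an amino-acid residue); see [coarseGrain()].
#' Tokens obey the same invariance/equivariance contract as [NodeFeatures].
#'
#' @slot scalars numeric M x d matrix
#' @slot vectors numeric M x 3 x d array
#'
#' @export
setClass("TokenArray",
  representation(scalars = "matrix", vectors = "array"),
  validity = function(object) {
    dm <- dim(object@vectors)
    if (length(dm) != 3L || dm[2L] != 3L) return("vectors must be M x 3 x d")
    if (dm[1L] != nrow(object@scalars)) return("token count mismatch")
    if (dm[3L] != ncol(object@scalars)) return("channel count mismatch")
    TRUE
  }
)

#' Stack of token features over trajectory frames
#'
#' Cache of per-frame [TokenArray]s produced by [inferTrajectory()], with
#' provenance metadata (encoder checkpoint hash, partition hash, atom
#' selection, frame stride, units).  Read-back verifies the metadata hash so
#' stale caches are rejected rather than silently reused.
#'
#' @slot scalars numeric T x M x d array
#' @slot vectors numeric T x M x 3 x d array
#' @slot metadata named list of provenance fields
#'
#' @export
setClass("FeatureStore",
  representation(scalars = "array", vectors = "array", metadata = "list"),
  validity = function(object) {
    ds <- dim(object@scalars)
    dv <- dim(object@vectors)
    if (length(ds) != 3L) return("scalars must be T x M x d")
    if (length(dv) != 4L || dv[3L] != 3L) return("vectors must be T x M x 3 x d")
    if (!all(ds == dv[c(1L, 2L, 4L)])) return("scalar/vector shape mismatch")
    TRUE
  }
)

#' Per-frame metastable-state labels
#'
#' Integer label per frame in 1..k.  `populatedCount()` reports the number of
#' distinct labels actually present; SPIB training shrinks this toward the
#' number of metastable states.
#'
#' @slot labels integer vector [T]
#' @slot k integer, number of possible labels
#'
#' @export
setClass("StateLabels",
  representation(labels = "integer", k = "integer"),
  validity = function(object) {
    if (length(object@k) != 1L || object@k < 1L) return("k must be >= 1")
    if (any(object@labels < 1L | object@labels > object@k)) {
      return("labels must lie in 1..k")
    }
    TRUE
  }
)

#' Construct a StateLabels object
#'
#' @param labels integer labels in 1..k
#' @param k number of possible labels (default `max(labels)`)
#' @return a [StateLabels]
#' @export
stateLabels <- function(labels, k = max(labels)) {
  new("StateLabels", labels = as.integer(labels), k = as.integer(k))
}

## ---- accessors -------------------------------------------------------------

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "MolSystem", function(x) length(x@element))
#' @rdname nAtoms
#' @export
setMethod("nAtoms", "AtomicGraph", function(x) length(x@atomicNumbers))
#' @rdname nAtoms
#' @export
setMethod("nAtoms", "NodeFeatures", function(x) nrow(x@scalars))

#' @rdname atomCoords
#' @export
setMethod("atomCoords", "MolSystem", function(x) x@coords)
#' @rdname atomCoords
#' @export
setMethod("atomCoords", "AtomicGraph", function(x) x@coords)

#' @rdname scalarFeatures
#' @export
setMethod("scalarFeatures", "NodeFeatures", function(x) x@scalars)
#' @rdname scalarFeatures
#' @export
setMethod("scalarFeatures", "TokenArray", function(x) x@scalars)
#' @rdname scalarFeatures
#' @export
setMethod("scalarFeatures", "FeatureStore", function(x) x@scalars)

#' @rdname vectorFeatures
#' @export
setMethod("vectorFeatures", "NodeFeatures", function(x) x@vectors)
#' @rdname vectorFeatures
#' @export
setMethod("vectorFeatures", "TokenArray", function(x) x@vectors)
#' @rdname vectorFeatures
#' @export
setMethod("vectorFeatures", "FeatureStore", function(x) x@vectors)

#' @rdname nTokens
#' @export
setMethod("nTokens", "TokenArray", function(x) nrow(x@scalars))
#' @rdname nTokens
#' @export
setMethod("nTokens", "FeatureStore", function(x) dim(x@scalars)[2L])

#' @rdname nFrames
#' @export
setMethod("nFrames", "FeatureStore", function(x) dim(x@scalars)[1L])

#' @rdname storeMetadata
#' @export
setMethod("storeMetadata", "FeatureStore", function(x) x@metadata)

#' @rdname labelVector
#' @export
setMethod("labelVector", "StateLabels", function(x) x@labels)

#' @rdname populatedCount
#' @export
setMethod("populatedCount", "StateLabels", function(x) {
  length(unique(x@labels))
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "MolSystem", function(object) {
  cat(sprintf("MolSystem: %d atoms, %d residues (%s)\n",
              nAtoms(object), length(unique(object@resid)),
              paste(utils::head(unique(object@element), 6), collapse = ",")))
})

setMethod("show", "AtomicGraph", function(object) {
  cat(sprintf("AtomicGraph: %d atoms, %d directed edges, cutoff %.2f A\n",
              nAtoms(object), nrow(object@edges), object@cutoff))
})

setMethod("show", "NodeFeatures", function(object) {
  cat(sprintf("NodeFeatures: %d atoms x %d channels (scalar + 3-vector)\n",
              nrow(object@scalars), ncol(object@scalars)))
})

setMethod("show", "TokenArray", function(object) {
  cat(sprintf("TokenArray: %d tokens x %d channels (scalar + 3-vector)\n",
              nrow(object@scalars), ncol(object@scalars)))
})

setMethod("show", "FeatureStore", function(object) {
  d <- dim(object@scalars)
  cat(sprintf("FeatureStore: %d frames x %d tokens x %d channels\n",
              d[1L], d[2L], d[3L]))
  if (!is.null(object@metadata$checkpoint_hash)) {
    cat(sprintf("  encoder checkpoint: %s\n",
                substr(object@metadata$checkpoint_hash, 1, 12)))
  }
})

setMethod("show", "StateLabels", function(object) {
  cat(sprintf("StateLabels: %d frames, %d of %d states populated\n",
              length(object@labels), populatedCount(object), object@k))
})
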