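#' Build an atomic graph under a distance cutoff
#'
#' Connects every pair of atoms whose interatomic distance is at most
#' `cutoff` (Angstrom) with a pair of directed edges.  Neighbor search is a
#' brute-force O(N^2) scan, adequate for the system sizes handled here
#' (hundreds of atoms) and replaceable by a cell list for larger systems.
#'
#' @param coords numeric N x 3 coordinate matrix (Angstrom)
#' @param atomicNumbers integer vector of atomic numbers, length N
#' @param cutoff positive cutoff radius (Angstrom)
#' @return an [AtomicGraph]
#' @examples
#' g <- buildGraph(rbind(c(0, 0, 0), c(3, 0, 0)), c(6L, 6L), cutoff = 5)
#' g
#' @export
buildGraph <- function(coords, atomicNumbers, cutoff) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L) stop("graph needs at least one atom")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  if (cutoff <= 0) stop("cutoff must be positive")
  if (length(atomicNumbers) != nrow(coords)) {
    stop("atomicNumbers length must match coords")
  }
  new("AtomicGraph", atomicNumbers = as.integer(atomicNumbers),
      coords = coords, edges = build_edges(coords, cutoff),
      cutoff = as.numeric(cutoff))
}

# Directed symmetric edge list under a cutoff (no S4 overhead; hot path)
build_edges <- function(coords, cutoff) {
  n <- nrow(coords)
  if (n == 1L) return(matrix(integer(0), 0L, 2L))
  dm <- as.matrix(stats::dist(coords))
  sel <- which(dm <= cutoff & upper.tri(dm), arr.ind = TRUE)
  edges <- rbind(sel, sel[, 2:1, drop = FALSE])
  dimnames(edges) <- NULL
  matrix(as.integer(edges), ncol = 2L)
}

# Gaussian radial basis expansion of edge distances on [0, cutoff]
radial_basis <- function(r, cutoff, n_rbf) {
  mu <- seq(0, cutoff, length.out = n_rbf)
  sigma <- cutoff / n_rbf
  exp(-outer(r, mu, function(a, b) (a - b)^2) / (2 * sigma^2))
}

# Cosine cutoff envelope: 1 at r = 0, smoothly 0 at r = cutoff
cosine_cutoff <- function(r, cutoff) {
  ifelse(r < cutoff, 0.5 * (cos(pi * r / cutoff) + 1), 0)
}

# Precompute the per-edge geometric constants the encoder consumes.
graph_tensors <- function(graph, n_rbf) {
  graph_tensors_raw(graph@coords, graph@atomicNumbers, graph@edges,
                    graph@cutoff, n_rbf)
}

graph_tensors_raw <- function(coords, z, edges, cutoff, n_rbf) {
  n <- nrow(coords)
  if (nrow(edges) == 0L) {
    return(list(z = z, n = n, ei = integer(0), ej = integer(0),
                rbf = matrix(0, 0L, n_rbf), phi = numeric(0),
                u = matrix(0, 0L, 3L)))
  }
  ei <- edges[, 1L]
  ej <- edges[, 2L]
  rv <- coords[ei, , drop = FALSE] - coords[ej, , drop = FALSE]
  r <- sqrt(rowSums(rv^2))
  list(z = z, n = n, ei = ei, ej = ej,
       rbf = radial_basis(r, cutoff, n_rbf),
       phi = cosine_cutoff(r, cutoff),
       u = rv / r)
}

# Concatenate several molecules into one block-diagonal batch graph.
# `systems` is a list of list(coords =, z =).  Edges never cross molecules.
batch_graph_tensors <- function(systems, cutoff, n_rbf) {
  parts <- lapply(systems, function(s) {
    graph_tensors_raw(s$coords, s$z, build_edges(s$coords, cutoff),
                      cutoff, n_rbf)
  })
  sizes <- vapply(parts, function(p) p$n, integer(1))
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  list(
    z = unlist(lapply(parts, function(p) p$z)),
    n = sum(sizes),
    sizes = sizes,
    ei = unlist(lapply(seq_along(parts),
                       function(k) parts[[k]]$ei + offs[k])),
    ej = unlist(lapply(seq_along(parts),
                       function(k) parts[[k]]$ej + offs[k])),
    rbf = do.call(rbind, lapply(parts, function(p) p$rbf)),
    phi = unlist(lapply(parts, function(p) p$phi)),
    u = do.call(rbind, lapply(parts, function(p) p$u))
  )
}
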