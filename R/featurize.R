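# Frozen-encoder featurization of trajectories: atom selection,
# coarse-graining of per-atom features into per-unit structural tokens, and
# a cached, provenance-hashed feature store.

#' Select atoms from a molecular system
#'
#' @param system a [MolSystem]
#' @param rule one of the strings `"all"` or `"non-hydrogen"` (alias
#'   `"heavy"`), an explicit integer index vector, or a list with elements
#'   `resid` and/or `element` to filter by residue index / element symbol
#' @return sorted unique integer atom indices (1-based)
#' @examples
#' w <- molSystem(c("O", "H", "H"), matrix(rnorm(9), 3, 3))
#' selectAtoms(w, "non-hydrogen")
#' @export
selectAtoms <- function(system, rule = "non-hydrogen") {
  stopifnot(is(system, "MolSystem"))
  n <- nAtoms(system)
  idx <- if (is.numeric(rule)) {
    ri <- as.integer(rule)
    if (any(ri < 1L | ri > n)) stop("explicit atom index out of range")
    ri
  } else if (is.list(rule)) {
    keep <- rep(TRUE, n)
    if (!is.null(rule$resid)) keep <- keep & system@resid %in% rule$resid
    if (!is.null(rule$element)) {
      keep <- keep & toupper(system@element) %in% toupper(rule$element)
    }
    which(keep)
  } else if (identical(rule, "all")) {
    seq_len(n)
  } else if (rule %in% c("non-hydrogen", "heavy")) {
    which(system@atomicNumber != 1L)
  } else {
    stop("unknown selection rule: ", rule)
  }
  idx <- sort(unique(idx))
  if (length(idx) == 0L) stop("selection matches no atoms")
  idx
}

#' Partition selected atoms by residue
#'
#' Yields one token subset per residue present in the selection, in residue
#' order.  Indices are positions *within* the selection (1-based), as
#' [coarseGrain()] expects.
#'
#' @param system a [MolSystem]
#' @param selection integer atom indices from [selectAtoms()]
#' @return list of integer index vectors, one per residue
#' @export
partitionByResidue <- function(system, selection = seq_len(nAtoms(system))) {
  res <- system@resid[selection]
  split(seq_along(selection), factor(res, levels = unique(res)))
}

check_partition <- function(partition, n) {
  all_idx <- unlist(partition)
  if (any(vapply(partition, length, integer(1)) == 0L)) {
    stop("partition subsets must be non-empty")
  }
  if (anyDuplicated(all_idx)) stop("partition subsets overlap")
  if (any(all_idx < 1L | all_idx > n)) stop("partition index out of range")
  if (length(all_idx) != n) {
    stop("partition must cover all ", n, " selected atoms (covers ",
         length(all_idx), ")")
  }
  invisible(TRUE)
}

#' Coarse-grain per-atom features into structural tokens
#'
#' Token m is the exact (parameter-free) sum of the per-atom feature rows
#' over subset m of the partition, for scalar and vector channels alike.
#' Coarse-graining is linear, and summing all tokens equals summing all atom
#' features (partition conservation).
#'
#' @param features a [NodeFeatures] over the selected atoms
#' @param partition list of disjoint index vectors covering all atoms of
#'   `features` (e.g. from [partitionByResidue()])
#' @return a [TokenArray] with one token per subset
#' @export
coarseGrain <- function(features, partition) {
  stopifnot(is(features, "NodeFeatures"))
  n <- nrow(features@scalars)
  check_partition(partition, n)
  M <- length(partition)
  d <- ncol(features@scalars)
  sc <- matrix(0, M, d)
  vec <- array(0, dim = c(M, 3L, d))
  for (m in seq_len(M)) {
    ii <- partition[[m]]
    sc[m, ] <- colSums(features@scalars[ii, , drop = FALSE])
    for (cc in 1:3) {
      vec[m, cc, ] <- colSums(vec_slice(features@vectors, cc)[ii, ,
                                                              drop = FALSE])
    }
  }
  new("TokenArray", scalars = sc, vectors = vec)
}

#' Pool tokens into a single global feature
#'
#' Order-independent reduction over tokens.  Sum-pooling of tokens is
#' identical to pooling the underlying per-atom features directly.
#'
#' @param tokens a [TokenArray]
#' @param mode `"sum"` or `"mean"`
#' @return list with `scalars` (length-d vector) and `vectors` (3 x d matrix)
#' @export
globalPool <- function(tokens, mode = c("sum", "mean")) {
  stopifnot(is(tokens, "TokenArray"))
  mode <- match.arg(mode)
  M <- nTokens(tokens)
  red <- function(x) if (mode == "sum") colSums(x) else colSums(x) / M
  vec <- apply(tokens@vectors, c(2L, 3L), if (mode == "sum") sum else mean)
  list(scalars = red(tokens@scalars), vectors = vec)
}

#' Featurize a trajectory with a frozen encoder
#'
#' Runs encoder inference on every frame (in batches of whole frames),
#' selects atoms, coarse-grains into tokens, and stacks the results into a
#' [FeatureStore].  Encoder parameters are never modified.  The store records
#' the encoder checkpoint hash, partition hash and selection hash so stale
#' caches are detected on read-back.
#'
#' @param frames numeric T x N x 3 coordinate array (Angstrom), or a list of
#'   N x 3 matrices
#' @param system a [MolSystem] giving the shared topology
#' @param model a `gnnEncoder`
#' @param selection atom selection rule or indices (see [selectAtoms()])
#' @param partition token partition of the *selected* atoms; default one
#'   token per residue
#' @param batchSize frames encoded per inference batch
#' @param stride keep every `stride`-th frame
#' @return a [FeatureStore] of shape T x M x (1+3)d
#' @export
inferTrajectory <- function(frames, system, model,
                            selection = "non-hydrogen",
                            partition = NULL, batchSize = 16L, stride = 1L) {
  stopifnot(inherits(model, "gnnEncoder"), is(system, "MolSystem"))
  if (is.list(frames)) {
    frames_list <- frames
  } else {
    stopifnot(length(dim(frames)) == 3L, dim(frames)[3L] == 3L)
    frames_list <- lapply(seq_len(dim(frames)[1L]), function(t) {
      matrix(frames[t, , ], ncol = 3L)
    })
  }
  if (any(vapply(frames_list, nrow, integer(1)) != nAtoms(system))) {
    stop("frame atom count does not match topology")
  }
  frames_list <- frames_list[seq(1L, length(frames_list), by = stride)]
  sel <- selectAtoms(system, selection)
  if (is.null(partition)) partition <- partitionByResidue(system, sel)
  check_partition(partition, length(sel))
  z <- system@atomicNumber[sel]
  cfg <- model$config
  TT <- length(frames_list)
  M <- length(partition)
  d <- cfg$d
  sc <- array(0, dim = c(TT, M, d))
  vec <- array(0, dim = c(TT, M, 3L, d))
  # flat index map: rows of the batched node output -> (frame, token)
  nsel <- length(sel)
  starts <- seq(1L, TT, by = batchSize)
  for (s in starts) {
    ids <- s:min(s + batchSize - 1L, TT)
    sys <- lapply(ids, function(t) {
      list(coords = frames_list[[t]][sel, , drop = FALSE], z = z)
    })
    gt <- batch_graph_tensors(sys, cfg$cutoff, cfg$nRbf)
    tape <- ad_tape()
    bp <- lapply(model$params, function(p) ad_const(tape, p))
    out <- encoder_forward(tape, bp, gt, cfg)
    xs <- out$x$val
    Vs <- lapply(out$V, function(v) v$val)
    for (k in seq_along(ids)) {
      off <- (k - 1L) * nsel
      for (m in seq_len(M)) {
        ii <- partition[[m]] + off
        sc[ids[k], m, ] <- colSums(xs[ii, , drop = FALSE])
        for (cc in 1:3) {
          vec[ids[k], m, cc, ] <- colSums(Vs[[cc]][ii, , drop = FALSE])
        }
      }
    }
  }
  meta <- list(
    checkpoint_hash = encoder_hash(model),
    partition_hash = object_hash(partition),
    selection_hash = object_hash(sel),
    stride = as.integer(stride),
    units = "Angstrom",
    d = d, M = M
  )
  new("FeatureStore", scalars = sc, vectors = vec, metadata = meta)
}

.STORE_VERSION <- 1L

#' Write a feature store to disk
#'
#' Single-file archive with the metadata block and arrays; the content hash
#' stored alongside is verified by [readFeatureStore()].
#'
#' @param store a [FeatureStore]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeFeatureStore <- function(store, path) {
  stopifnot(is(store, "FeatureStore"))
  payload <- list(scalars = store@scalars, vectors = store@vectors,
                  metadata = store@metadata)
  saveRDS(list(format_version = .STORE_VERSION,
               content_hash = object_hash(payload), payload = payload),
          path)
  invisible(path)
}

#' Read a feature store from disk
#'
#' @param path file written by [writeFeatureStore()]
#' @return a [FeatureStore]; fails if the content hash does not match
#' @export
readFeatureStore <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format_version, .STORE_VERSION)) {
    stop("unsupported feature store version")
  }
  if (!identical(object_hash(obj$payload), obj$content_hash)) {
    stop("feature store content hash mismatch (corrupt or stale file)")
  }
  new("FeatureStore", scalars = obj$payload$scalars,
      vectors = obj$payload$vectors, metadata = obj$payload$metadata)
}

#' Read a token partition from a text file
#'
#' One line per token, whitespace-separated 1-based atom indices.
#'
#' @param path text file path
#' @return list of integer vectors
#' @export
readPartitionFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) as.integer(strsplit(trimws(l), "\\s+")[[1]]))
}
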