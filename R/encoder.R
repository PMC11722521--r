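# Equivariant geometric graph encoder.
#
# Message-passing layers in the TorchMD-ET style: edge filters from a
# Gaussian radial basis of the interatomic distance, a cosine cutoff
# envelope, dot-product attention weights on edges, and separate update
# paths for invariant scalar channels and equivariant 3-vector channels.
# Vector channels are only ever combined linearly across the channel
# dimension or scaled by invariant gates, which is what guarantees exact
# rotational equivariance of the architecture.

#' Encoder configuration
#'
#' @param d hidden channels per atom (scalar and vector alike)
#' @param nLayers number of message-passing layers
#' @param cutoff neighbor cutoff in Angstrom
#' @param nRbf number of radial basis functions for edge distances
#' @param maxZ largest atomic number with an embedding
#' @param seed integer seed fixing parameter initialization
#' @return a list of class `encoderConfig`
#' @export
encoderConfig <- function(d = 64L, nLayers = 4L, cutoff = 5.0, nRbf = 32L,
                          maxZ = 54L, seed = 1L) {
  stopifnot(d >= 1, nLayers >= 1, cutoff > 0, nRbf >= 1, maxZ >= 1)
  structure(list(d = as.integer(d), nLayers = as.integer(nLayers),
                 cutoff = as.numeric(cutoff), nRbf = as.integer(nRbf),
                 maxZ = as.integer(maxZ), seed = as.integer(seed)),
            class = "encoderConfig")
}

#' Initialize encoder parameters
#'
#' Parameters are drawn deterministically from the seed in the configuration:
#' identical configurations yield bitwise-identical parameters.
#'
#' @param config an [encoderConfig()]
#' @return list of class `gnnEncoder` with elements `config` and `params`
#' @export
encoderInit <- function(config) {
  stopifnot(inherits(config, "encoderConfig"))
  d <- config$d
  nr <- config$nRbf
  params <- local_seed(config$seed, {
    p <- list(Emb = matrix(stats::rnorm(config$maxZ * d, sd = 1), config$maxZ, d))
    for (l in seq_len(config$nLayers)) {
      pl <- list(
        ln_g = matrix(1, 1L, d), ln_b = init_zeros(d),
        Wq = init_dense(d, d), bq = init_zeros(d),
        Wk = init_dense(d, d), bk = init_zeros(d),
        Wv = init_dense(d, 3L * d), bv = init_zeros(3L * d),
        Wdk = init_dense(nr, d), bdk = init_zeros(d),
        Wdv = init_dense(nr, 3L * d), bdv = init_zeros(3L * d),
        Wo = init_dense(d, d), bo = init_zeros(d),
        U1 = init_dense(d, d), U2 = init_dense(d, d),
        M1 = init_dense(2L * d, d), m1b = init_zeros(d),
        M2 = init_dense(d, 3L * d), m2b = init_zeros(3L * d)
      )
      names(pl) <- paste0("L", l, "_", names(pl))
      p <- c(p, pl)
    }
    p
  })
  structure(list(config = config, params = params), class = "gnnEncoder")
}

# Forward pass on a tape.  `bp` is the bound parameter node list, `gt` the
# precomputed graph tensors.  Returns list(x = scalar node [N x d],
# V = list of 3 nodes [N x d], one per Cartesian axis).
encoder_forward <- function(tape, bp, gt, config) {
  d <- config$d
  if (any(gt$z > config$maxZ)) {
    stop("atomic number ", max(gt$z), " has no embedding (maxZ = ",
         config$maxZ, ")")
  }
  x <- ad_rows(tape, bp$Emb, gt$z)
  zero <- ad_const(tape, matrix(0, gt$n, d))
  V <- list(zero, zero, zero)
  has_edges <- length(gt$ei) > 0L
  if (has_edges) {
    rbf <- ad_const(tape, gt$rbf)
    phi <- gt$phi
  }
  for (l in seq_len(config$nLayers)) {
    p <- function(nm) bp[[paste0("L", l, "_", nm)]]
    if (has_edges) {
      xn <- ad_layernorm(tape, x, p("ln_g"), p("ln_b"))
      q <- ad_dense(tape, xn, p("Wq"), p("bq"))
      k <- ad_dense(tape, xn, p("Wk"), p("bk"))
      v <- ad_dense(tape, xn, p("Wv"), p("bv"))
      qi <- ad_rows(tape, q, gt$ei)
      kj <- ad_rows(tape, k, gt$ej)
      vj <- ad_rows(tape, v, gt$ej)
      dk <- ad_silu(tape, ad_dense(tape, rbf, p("Wdk"), p("bdk")))
      dv <- ad_silu(tape, ad_dense(tape, rbf, p("Wdv"), p("bdv")))
      ae <- ad_silu(tape, ad_rowsum(tape, ad_mul(tape, ad_mul(tape, qi, kj), dk)))
      ae <- ad_colscale(tape, ae, phi)
      vals <- ad_mul(tape, vj, dv)
      s1 <- ad_cols(tape, vals, 1:d)
      s2 <- ad_cols(tape, vals, (d + 1L):(2L * d))
      s3 <- ad_cols(tape, vals, (2L * d + 1L):(3L * d))
      ms <- ad_scatter_add(tape, ad_colscale(tape, s1, ae), gt$ei, gt$n)
      x <- ad_add(tape, x, ad_dense(tape, ms, p("Wo"), p("bo")))
      for (cc in 1:3) {
        Vj <- ad_rows(tape, V[[cc]], gt$ej)
        term <- ad_add(tape, ad_mul(tape, s2, Vj),
                       ad_colscale(tape, s3, gt$u[, cc]))
        mv <- ad_scatter_add(tape, ad_colscale(tape, term, ae), gt$ei, gt$n)
        V[[cc]] <- ad_add(tape, V[[cc]], mv)
      }
    }
    # node-local update mixing scalar and vector channels
    Uv <- lapply(V, function(vc) ad_matmul(tape, vc, p("U1")))
    Wv <- lapply(V, function(vc) ad_matmul(tape, vc, p("U2")))
    nrm <- ad_sqrt_eps(tape,
      ad_add(tape, ad_add(tape, ad_square(tape, Uv[[1]]),
                          ad_square(tape, Uv[[2]])),
             ad_square(tape, Uv[[3]])))
    dt <- ad_add(tape, ad_add(tape, ad_mul(tape, Uv[[1]], Wv[[1]]),
                              ad_mul(tape, Uv[[2]], Wv[[2]])),
                 ad_mul(tape, Uv[[3]], Wv[[3]]))
    feat <- ad_cbind(tape, list(x, nrm))
    h <- ad_silu(tape, ad_dense(tape, feat, p("M1"), p("m1b")))
    gates <- ad_dense(tape, h, p("M2"), p("m2b"))
    g1 <- ad_cols(tape, gates, 1:d)
    g2 <- ad_cols(tape, gates, (d + 1L):(2L * d))
    g3 <- ad_cols(tape, gates, (2L * d + 1L):(3L * d))
    x <- ad_add(tape, x, ad_add(tape, g1, ad_mul(tape, g2, dt)))
    for (cc in 1:3) {
      V[[cc]] <- ad_add(tape, V[[cc]], ad_mul(tape, g3, Wv[[cc]]))
    }
  }
  list(x = x, V = V)
}

#' Encode an atomic graph into per-atom features
#'
#' Applies the encoder to a graph and returns per-atom invariant scalar
#' channels and equivariant vector channels.  Outputs depend only on the
#' invariant geometry (pairwise distances and relative directions) and atom
#' identities: rigid rotation of the input rotates the vector channels and
#' leaves the scalars unchanged; permuting atoms permutes rows.
#'
#' @param graph an [AtomicGraph]
#' @param model a `gnnEncoder` from [encoderInit()] or a loaded checkpoint
#' @return a [NodeFeatures]
#' @export
encode <- function(graph, model) {
  stopifnot(inherits(model, "gnnEncoder"))
  gt <- graph_tensors(graph, model$config$nRbf)
  tape <- ad_tape()
  bp <- lapply(model$params, function(p) ad_const(tape, p))
  out <- encoder_forward(tape, bp, gt, model$config)
  node_features(out)
}

# Drop-safe slice of an [N x 3 x d] array along the Cartesian axis
vec_slice <- function(arr, cc) {
  dm <- dim(arr)
  matrix(arr[, cc, ], nrow = dm[1L], ncol = dm[3L])
}

# Assemble a NodeFeatures S4 from forward-pass nodes (or plain matrices)
node_features <- function(out) {
  x <- if (is.environment(out$x)) out$x$val else out$x
  Vc <- lapply(out$V, function(v) if (is.environment(v)) v$val else v)
  n <- nrow(x)
  d <- ncol(x)
  vec <- array(0, dim = c(n, 3L, d))
  for (cc in 1:3) vec[, cc, ] <- Vc[[cc]]
  new("NodeFeatures", scalars = x, vectors = vec)
}

#' Initialize a gated equivariant head
#'
#' The head maps per-atom features to one 3-vector per atom (used to predict
#' denoising displacements).  Two linear maps act on the vector channels; the
#' channel norms of the first map are concatenated with the scalars and fed
#' through a two-layer MLP whose output gates the second vector map.  The
#' output is therefore linear in the vector channels for fixed gates and
#' exactly equivariant.
#'
#' @param d number of feature channels the head accepts
#' @param seed seed for parameter initialization
#' @return named list of head parameters
#' @export
gatedHeadInit <- function(d, seed = 1L) {
  local_seed(seed, list(
    H_W1 = init_dense(d, d),
    H_W2 = init_dense(d, 1L),
    H_M1 = init_dense(2L * d, d), H_m1b = init_zeros(d),
    H_M2 = init_dense(d, 1L), H_m2b = init_zeros(1L)
  ))
}

# Tape-level head forward: returns list of 3 nodes [N x 1]
gated_head_forward <- function(tape, bp, x, V) {
  W1V <- lapply(V, function(vc) ad_matmul(tape, vc, bp$H_W1))
  W2V <- lapply(V, function(vc) ad_matmul(tape, vc, bp$H_W2))
  nrm <- ad_sqrt_eps(tape,
    ad_add(tape, ad_add(tape, ad_square(tape, W1V[[1]]),
                        ad_square(tape, W1V[[2]])),
           ad_square(tape, W1V[[3]])))
  feat <- ad_cbind(tape, list(x, nrm))
  h <- ad_silu(tape, ad_dense(tape, feat, bp$H_M1, bp$H_m1b))
  gate <- ad_dense(tape, h, bp$H_M2, bp$H_m2b)
  lapply(W2V, function(wc) ad_mul(tape, wc, gate))
}

#' Apply a gated equivariant head to node features
#'
#' @param features a [NodeFeatures]
#' @param params head parameters from [gatedHeadInit()]
#' @return numeric N x 3 matrix of per-atom output vectors
#' @export
gatedEquivariantHead <- function(features, params) {
  stopifnot(is(features, "NodeFeatures"))
  d <- ncol(features@scalars)
  if (nrow(params$H_W1) != d) {
    stop("head channel width (", nrow(params$H_W1),
         ") does not match features (", d, ")")
  }
  tape <- ad_tape()
  bp <- lapply(params, function(p) ad_const(tape, p))
  x <- ad_const(tape, features@scalars)
  V <- lapply(1:3, function(cc) ad_const(tape, vec_slice(features@vectors, cc)))
  out <- gated_head_forward(tape, bp, x, V)
  cbind(out[[1]]$val, out[[2]]$val, out[[3]]$val)
}
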