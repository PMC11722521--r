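# Learnable heads over token arrays.  Three families: direct pooling, an
# MLP-mixer over tokens ("SubMixer"), and a transformer over tokens with an
# optional global token encoding pairwise inter-token distances
# ("SubFormer").  GVP-style enrichment injects rotation-invariant functions
# of the token vector channels into the scalar channels before mixing.
# Only scalar (invariant) channels enter the mixers directly, so every task
# output is invariant under rigid motion of the molecule.

#' Token-mixer configuration
#'
#' @param kind one of `"pool"`, `"submixer"`, `"subformer"`,
#'   `"submixer_gvp"`, `"subformer_gvp"`
#' @param depth number of mixing blocks
#' @param modelDim embedding width
#' @param heads attention heads (subformer kinds); must divide `modelDim`
#' @param expansion widening factor of the mixer/transformer MLPs
#' @param outputDim task output dimension (d_o)
#' @param positional add learned per-token positional embeddings (residue
#'   order matters for proteins; can be disabled to make the subformer
#'   permutation-equivariant over tokens)
#' @param seed integer seed for parameter initialization
#' @return list of class `mixerConfig`
#' @export
mixerConfig <- function(kind = c("subformer", "submixer", "pool",
                                 "submixer_gvp", "subformer_gvp"),
                        depth = 2L, modelDim = 32L, heads = 2L,
                        expansion = 2, outputDim = 2L, positional = TRUE,
                        seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(depth >= 1, modelDim >= 1, outputDim >= 1, expansion > 0)
  if (grepl("subformer", kind) && modelDim %% heads != 0) {
    stop("modelDim must be divisible by heads")
  }
  structure(list(kind = kind, depth = as.integer(depth),
                 modelDim = as.integer(modelDim), heads = as.integer(heads),
                 expansion = expansion, outputDim = as.integer(outputDim),
                 positional = isTRUE(positional), seed = as.integer(seed)),
            class = "mixerConfig")
}

#' Initialize GVP-style enrichment parameters
#'
#' Two linear maps act on the vector channels; per-channel norms of the
#' first map and channel-wise inner products between the two maps are
#' concatenated with the scalars and mapped back to width d.  All outputs
#' are rotation-invariant; with zero vector channels the enrichment reduces
#' to a linear map of the scalars alone.
#'
#' @param d scalar/vector channel count of the tokens
#' @param dg width of the vector maps (default `d`)
#' @param seed integer seed
#' @return named parameter list
#' @export
gvpInit <- function(d, dg = d, seed = 1L) {
  local_seed(seed, list(
    G_V1 = init_dense(d, dg),
    G_V2 = init_dense(d, dg),
    G_W = init_dense(d + 2L * dg, d), G_b = init_zeros(d)
  ))
}

# tape-level enrichment; Xs (n x d), Xv list of 3 (n x d) nodes
gvp_enrich_fwd <- function(tape, bp, Xs, Xv) {
  V1 <- lapply(Xv, function(v) ad_matmul(tape, v, bp$G_V1))
  V2 <- lapply(Xv, function(v) ad_matmul(tape, v, bp$G_V2))
  nrm <- ad_sqrt_eps(tape,
    ad_add(tape, ad_add(tape, ad_square(tape, V1[[1]]),
                        ad_square(tape, V1[[2]])),
           ad_square(tape, V1[[3]])))
  dt <- ad_add(tape, ad_add(tape, ad_mul(tape, V1[[1]], V2[[1]]),
                            ad_mul(tape, V1[[2]], V2[[2]])),
               ad_mul(tape, V1[[3]], V2[[3]]))
  ad_dense(tape, ad_cbind(tape, list(Xs, nrm, dt)), bp$G_W, bp$G_b)
}

#' Enrich token scalars with invariants of the vector channels
#'
#' @param tokens a [TokenArray]
#' @param params parameters from [gvpInit()]
#' @return a [TokenArray] with enriched scalar channels (vectors unchanged)
#' @export
gvpEnrich <- function(tokens, params) {
  stopifnot(is(tokens, "TokenArray"))
  if (dim(tokens@vectors)[3L] != nrow(params$G_V1)) {
    stop("vector channel width does not match enrichment parameters")
  }
  tape <- ad_tape()
  bp <- lapply(params, function(p) ad_const(tape, p))
  Xs <- ad_const(tape, tokens@scalars)
  Xv <- lapply(1:3, function(cc) ad_const(tape, vec_slice(tokens@vectors, cc)))
  out <- gvp_enrich_fwd(tape, bp, Xs, Xv)
  new("TokenArray", scalars = out$val, vectors = tokens@vectors)
}

#' Initialize the global-token map
#'
#' The global token is computed from the M(M-1)/2 upper-triangular pairwise
#' distances between per-token reference points (for proteins, the Calpha
#' atoms), standardized by training-set statistics and passed through a
#' two-layer MLP.  It is invariant to rigid transforms of the coordinates
#' but not to scaling.
#'
#' @param M number of tokens (>= 2)
#' @param modelDim embedding width the token must match
#' @param stats list(mean =, sd =) standardization constants per distance
#' @param seed integer seed
#' @return named parameter list (standardization constants included)
#' @export
globalTokenInit <- function(M, modelDim, stats = NULL, seed = 1L) {
  if (M < 2L) stop("global token needs at least two tokens")
  P <- M * (M - 1L) / 2L
  if (is.null(stats)) stats <- list(mean = rep(0, P), sd = rep(1, P))
  local_seed(seed, list(
    GT_W1 = init_dense(P, modelDim), GT_b1 = init_zeros(modelDim),
    GT_W2 = init_dense(modelDim, modelDim), GT_b2 = init_zeros(modelDim),
    GT_mean = matrix(stats$mean, 1L), GT_sd = matrix(stats$sd, 1L)
  ))
}

# tape-level: D (B x P) distance node -> (B x modelDim)
global_token_fwd <- function(tape, bp, D) {
  Ds <- ad_mul_row(tape, ad_sub_row(tape, D, bp$GT_mean),
                   ad_const(tape, matrix(1 / as.vector(bp$GT_sd$val), 1L)))
  h <- ad_silu(tape, ad_dense(tape, Ds, bp$GT_W1, bp$GT_b1))
  ad_dense(tape, h, bp$GT_W2, bp$GT_b2)
}

#' Compute the global token for one frame
#'
#' @param caCoords M x 3 matrix of per-token reference coordinates
#' @param params parameters from [globalTokenInit()]
#' @return numeric vector of length `modelDim`
#' @export
makeGlobalToken <- function(caCoords, params) {
  caCoords <- as.matrix(caCoords)
  if (nrow(caCoords) < 2L) stop("need at least two reference points")
  d <- upperTriDistances(caCoords)
  tape <- ad_tape()
  bp <- lapply(params, function(p) ad_const(tape, p))
  out <- global_token_fwd(tape, bp, ad_const(tape, matrix(d, 1L)))
  as.vector(out$val)
}

#' Upper-triangular pairwise distances
#'
#' @param coords M x 3 coordinate matrix
#' @return numeric vector of length M(M-1)/2 (column-major upper triangle,
#'   the ordering of `stats::dist`)
#' @export
upperTriDistances <- function(coords) {
  as.vector(stats::dist(coords))
}

## ---- parameter initialization ----------------------------------------------

# `M` tokens, input width dIn; nGlobalDist = length of the pairwise distance
# vector when a distance-based global token is used (subformer only).
mixer_init <- function(cfg, M, dIn, nGlobalDist = NULL,
                       globalStats = NULL) {
  D <- cfg$modelDim
  E <- max(1L, round(cfg$expansion * D))
  H <- max(1L, round(cfg$expansion * M))
  local_seed(cfg$seed, {
    p <- list(W_emb = init_dense(dIn, D), b_emb = init_zeros(D))
    if (grepl("gvp", cfg$kind)) {
      p <- c(p, gvpInit(dIn, seed = derive_seed(cfg$seed, 91L)))
    }
    if (cfg$positional && cfg$kind != "pool") {
      p$Pos <- matrix(stats::rnorm(M * D, sd = 0.02), M, D)
    }
    if (grepl("subformer", cfg$kind)) {
      if (!is.null(nGlobalDist)) {
        p <- c(p, local_seed(derive_seed(cfg$seed, 92L), list(
          GT_W1 = init_dense(nGlobalDist, D), GT_b1 = init_zeros(D),
          GT_W2 = init_dense(D, D), GT_b2 = init_zeros(D),
          GT_mean = matrix(globalStats$mean %||% rep(0, nGlobalDist), 1L),
          GT_sd = matrix(globalStats$sd %||% rep(1, nGlobalDist), 1L)
        )))
      } else {
        p$GlobalTok <- matrix(stats::rnorm(D, sd = 0.02), 1L, D)
      }
      for (l in seq_len(cfg$depth)) {
        pl <- list(
          ln1_g = matrix(1, 1L, D), ln1_b = init_zeros(D),
          Wq = init_dense(D, D), bq = init_zeros(D),
          Wk = init_dense(D, D), bk = init_zeros(D),
          Wv = init_dense(D, D), bv = init_zeros(D),
          Wo = init_dense(D, D), bo = init_zeros(D),
          ln2_g = matrix(1, 1L, D), ln2_b = init_zeros(D),
          Wm1 = init_dense(D, E), bm1 = init_zeros(E),
          Wm2 = init_dense(E, D), bm2 = init_zeros(D)
        )
        names(pl) <- paste0("T", l, "_", names(pl))
        p <- c(p, pl)
      }
    } else if (grepl("submixer", cfg$kind)) {
      for (l in seq_len(cfg$depth)) {
        pl <- list(
          ln1_g = matrix(1, 1L, D), ln1_b = init_zeros(D),
          Tok1 = init_dense(M, H), Tok2 = init_dense(H, M),
          ln2_g = matrix(1, 1L, D), ln2_b = init_zeros(D),
          Wm1 = init_dense(D, E), bm1 = init_zeros(E),
          Wm2 = init_dense(E, D), bm2 = init_zeros(D)
        )
        names(pl) <- paste0("X", l, "_", names(pl))
        p <- c(p, pl)
      }
    }
    # output head: 2-layer MLP on the pooled/readout feature
    p$Wh <- init_dense(D, D)
    p$bh <- init_zeros(D)
    p$Wout <- init_dense(D, cfg$outputDim)
    p$bout <- init_zeros(cfg$outputDim)
    p
  })
}

## ---- forward pass -----------------------------------------------------------

# Scaled-dot self-attention over S positions on a row-blocked (B*S) x D node.
# Returns list(out = node, map = S x S x B head-averaged attention array).
attention_block <- function(tape, X, Wq, bq, Wk, bk, Wv, bv, Wo, bo,
                            S, heads, want_map = FALSE) {
  D <- ncol(X$val)
  B <- nrow(X$val) %/% S
  dh <- D %/% heads
  Q <- ad_dense(tape, X, Wq, bq)
  K <- ad_dense(tape, X, Wk, bk)
  V <- ad_dense(tape, X, Wv, bv)
  pos_idx <- lapply(seq_len(S), function(p) p + S * (0:(B - 1L)))
  Qp <- lapply(pos_idx, function(ii) ad_rows(tape, Q, ii))
  Kp <- lapply(pos_idx, function(ii) ad_rows(tape, K, ii))
  Vp <- lapply(pos_idx, function(ii) ad_rows(tape, V, ii))
  map <- if (want_map) array(0, dim = c(S, S, B)) else NULL
  out_pos <- vector("list", S)
  for (a in seq_len(S)) {
    head_outs <- vector("list", heads)
    for (h in seq_len(heads)) {
      hc <- ((h - 1L) * dh + 1L):(h * dh)
      Qa <- ad_cols(tape, Qp[[a]], hc)
      logit_cols <- lapply(seq_len(S), function(m) {
        ad_rowsum(tape, ad_mul(tape, Qa, ad_cols(tape, Kp[[m]], hc)))
      })
      logits <- ad_scale(tape, ad_cbind(tape, logit_cols), 1 / sqrt(dh))
      attn <- ad_softmax_rows(tape, logits)          # B x S
      if (want_map) map[a, , ] <- map[a, , ] + t(attn$val) / heads
      acc <- NULL
      for (m in seq_len(S)) {
        term <- ad_colscale(tape, ad_cols(tape, Vp[[m]], hc),
                            ad_cols(tape, attn, m))
        acc <- if (is.null(acc)) term else ad_add(tape, acc, term)
      }
      head_outs[[h]] <- acc
    }
    out_pos[[a]] <- if (heads == 1L) head_outs[[1L]] else
      ad_cbind(tape, head_outs)
  }
  # restack position-major output back to row-blocked order
  stacked <- ad_rbind(tape, out_pos)                  # rows: (a-1)*B + b
  a_idx <- rep(seq_len(S), times = B)
  b_idx <- rep(seq_len(B), each = S)
  perm <- (a_idx - 1L) * B + b_idx
  O <- ad_rows(tape, stacked, perm)
  list(out = ad_dense(tape, O, Wo, bo), map = map)
}

# Full mixer forward.  Xs: (B*M) x dIn scalar node (row-blocked, token
# fastest); Xv: list of 3 nodes or NULL; gdist: B x P node or NULL.
# Returns list(feat = B x outputDim node, pre = B x D readout node,
# attn = list of per-layer S x S x B arrays).
mixer_forward <- function(tape, bp, cfg, M, Xs, Xv = NULL, gdist = NULL,
                          want_attention = FALSE) {
  D <- cfg$modelDim
  B <- nrow(Xs$val) %/% M
  if (grepl("gvp", cfg$kind)) {
    if (is.null(Xv)) stop("GVP mixer kinds require vector channels")
    Xs <- gvp_enrich_fwd(tape, bp, Xs, Xv)
  }
  X <- ad_dense(tape, Xs, bp$W_emb, bp$b_emb)
  if (cfg$positional && cfg$kind != "pool" && !is.null(bp$Pos)) {
    X <- ad_rowgroup_add(tape, X, bp$Pos, rep(seq_len(M), B))
  }
  attn_maps <- list()
  if (cfg$kind == "pool") {
    pooled <- ad_blockmix(tape, X, ad_const(tape, matrix(1 / M, 1L, M)), M)
  } else if (grepl("submixer", cfg$kind)) {
    for (l in seq_len(cfg$depth)) {
      p <- function(nm) bp[[paste0("X", l, "_", nm)]]
      Tok1 <- p("Tok1")
      H <- ncol(Tok1$val)
      h <- ad_layernorm(tape, X, p("ln1_g"), p("ln1_b"))
      h <- ad_blockmix(tape, h, ad_node_t(tape, Tok1), M)   # (B*H) x D
      h <- ad_silu(tape, h)
      h <- ad_blockmix(tape, h, ad_node_t(tape, p("Tok2")), H)
      X <- ad_add(tape, X, h)
      h <- ad_layernorm(tape, X, p("ln2_g"), p("ln2_b"))
      h <- ad_silu(tape, ad_dense(tape, h, p("Wm1"), p("bm1")))
      h <- ad_dense(tape, h, p("Wm2"), p("bm2"))
      X <- ad_add(tape, X, h)
    }
    pooled <- ad_blockmix(tape, X, ad_const(tape, matrix(1 / M, 1L, M)), M)
  } else {                                            # subformer kinds
    glob <- if (!is.null(bp$GT_W1)) {
      if (is.null(gdist)) stop("this subformer was configured with a ",
                               "distance global token; supply distances")
      global_token_fwd(tape, bp, gdist)
    } else {
      ad_rows(tape, bp$GlobalTok, rep(1L, B))
    }
    S <- M + 1L
    comb <- ad_rbind(tape, list(glob, X))
    p_idx <- integer(B * S)
    for (b in seq_len(B)) {
      p_idx[(b - 1L) * S + 1L] <- b
      p_idx[(b - 1L) * S + 1L + seq_len(M)] <- B + (b - 1L) * M + seq_len(M)
    }
    X <- ad_rows(tape, comb, p_idx)
    for (l in seq_len(cfg$depth)) {
      p <- function(nm) bp[[paste0("T", l, "_", nm)]]
      h <- ad_layernorm(tape, X, p("ln1_g"), p("ln1_b"))
      ab <- attention_block(tape, h, p("Wq"), p("bq"), p("Wk"), p("bk"),
                            p("Wv"), p("bv"), p("Wo"), p("bo"),
                            S, cfg$heads, want_map = want_attention)
      if (want_attention) attn_maps[[l]] <- ab$map
      X <- ad_add(tape, X, ab$out)
      h <- ad_layernorm(tape, X, p("ln2_g"), p("ln2_b"))
      h <- ad_silu(tape, ad_dense(tape, h, p("Wm1"), p("bm1")))
      h <- ad_dense(tape, h, p("Wm2"), p("bm2"))
      X <- ad_add(tape, X, h)
    }
    # readout from the global-token position
    pooled <- ad_rows(tape, X, seq(1L, B * S, by = S))
  }
  pre <- ad_silu(tape, ad_dense(tape, pooled, bp$Wh, bp$bh))
  feat <- ad_dense(tape, pre, bp$Wout, bp$bout)
  list(feat = feat, pre = pre, attn = attn_maps)
}

# transpose-of-parameter helper for blockmix (weights stored M x H)
ad_node_t <- function(tape, a) {
  ad_node(tape, t(a$val), list(a), function(g) ad_acc(a, t(g)))
}

#' Apply an output head MLP to a feature vector
#'
#' @param features numeric vector or matrix (rows = samples)
#' @param params list with `Wh`, `bh`, `Wout`, `bout` (e.g. a mixer's head)
#' @return numeric matrix of task outputs
#' @export
outputHead <- function(features, params) {
  x <- if (is.matrix(features)) features else matrix(features, 1L)
  if (ncol(x) != nrow(params$Wh)) stop("feature width mismatch")
  h <- x %*% params$Wh
  h <- sweep(h, 2L, as.vector(params$bh), "+")
  h <- h / (1 + exp(-h)) * 1  # silu
  out <- h %*% params$Wout
  sweep(out, 2L, as.vector(params$bout), "+")
}
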