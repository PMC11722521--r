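# Reverse-mode automatic differentiation on a tape of matrix-valued nodes.
#
# All neural components in this package (equivariant encoder, token mixers,
# VAMPnet and SPIB heads) are differentiated through this engine.  Values are
# plain numeric matrices; a node records its value, its parent nodes, and a
# backward closure that distributes the node's cotangent to its parents.
# Gradients of every op are verified against central finite differences in the
# test suite.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_as_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = length(x), ncol = 1L)
}

ad_node <- function(tape, val, parents = list(), backfn = NULL,
                    requires_grad = NULL) {
  if (is.null(requires_grad)) {
    requires_grad <- any(vapply(parents, function(p) p$rg, logical(1)))
  }
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$rg <- requires_grad
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd$id <- n
  nd
}

ad_const <- function(tape, x) {
  ad_node(tape, ad_as_matrix(x), requires_grad = FALSE)
}

ad_param <- function(tape, x) {
  ad_node(tape, ad_as_matrix(x), requires_grad = TRUE)
}

# accumulate cotangent g into node p
ad_acc <- function(p, g) {
  if (!p$rg) return(invisible(NULL))
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

# Run backward pass from `root` (must be 1x1).  Leaves' $grad fields are
# populated afterwards.
ad_backward <- function(tape, root) {
  stopifnot(length(root$val) == 1L)
  root$grad <- matrix(1, 1L, 1L)
  for (i in seq(root$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd) || !nd$rg || is.null(nd$grad) || is.null(nd$backfn)) next
    nd$backfn(nd$grad)
  }
  invisible(NULL)
}

## ---- elementary ops --------------------------------------------------------

ad_matmul <- function(tape, a, b) {
  ad_node(tape, a$val %*% b$val, list(a, b), function(g) {
    ad_acc(a, g %*% t(b$val))
    ad_acc(b, t(a$val) %*% g)
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$val + b$val, list(a, b), function(g) {
    ad_acc(a, g)
    ad_acc(b, g)
  })
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, a$val - b$val, list(a, b), function(g) {
    ad_acc(a, g)
    ad_acc(b, -g)
  })
}

ad_neg <- function(tape, a) {
  ad_node(tape, -a$val, list(a), function(g) ad_acc(a, -g))
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$val * b$val, list(a, b), function(g) {
    ad_acc(a, g * b$val)
    ad_acc(b, g * a$val)
  })
}

ad_scale <- function(tape, a, k) {
  ad_node(tape, a$val * k, list(a), function(g) ad_acc(a, g * k))
}

ad_addc <- function(tape, a, cst) {
  ad_node(tape, a$val + cst, list(a), function(g) ad_acc(a, g))
}

# a (n x d) plus a 1 x d bias row
ad_rowbias <- function(tape, a, b) {
  ad_node(tape, sweep(a$val, 2L, as.vector(b$val), "+"), list(a, b),
          function(g) {
            ad_acc(a, g)
            ad_acc(b, matrix(colSums(g), 1L))
          })
}

# a (n x d) minus a 1 x d row (broadcast)
ad_sub_row <- function(tape, a, r) {
  ad_node(tape, sweep(a$val, 2L, as.vector(r$val), "-"), list(a, r),
          function(g) {
            ad_acc(a, g)
            ad_acc(r, matrix(-colSums(g), 1L))
          })
}

# a (n x d) times a 1 x d row (broadcast)
ad_mul_row <- function(tape, a, r) {
  ad_node(tape, sweep(a$val, 2L, as.vector(r$val), "*"), list(a, r),
          function(g) {
            ad_acc(a, sweep(g, 2L, as.vector(r$val), "*"))
            ad_acc(r, matrix(colSums(g * a$val), 1L))
          })
}

# scale every row i of a (n x d) by w_i; w is an n x 1 node or numeric
ad_colscale <- function(tape, a, w) {
  if (!is.environment(w)) w <- ad_const(tape, w)
  wv <- as.vector(w$val)
  ad_node(tape, a$val * wv, list(a, w), function(g) {
    ad_acc(a, g * wv)
    ad_acc(w, matrix(rowSums(g * a$val), ncol = 1L))
  })
}

## ---- nonlinearities --------------------------------------------------------

ad_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$val))
  ad_node(tape, s, list(a), function(g) ad_acc(a, g * s * (1 - s)))
}

ad_silu <- function(tape, a) {
  s <- 1 / (1 + exp(-a$val))
  ad_node(tape, a$val * s, list(a), function(g) {
    ad_acc(a, g * s * (1 + a$val * (1 - s)))
  })
}

ad_tanh <- function(tape, a) {
  v <- tanh(a$val)
  ad_node(tape, v, list(a), function(g) ad_acc(a, g * (1 - v^2)))
}

ad_exp <- function(tape, a) {
  v <- exp(a$val)
  ad_node(tape, v, list(a), function(g) ad_acc(a, g * v))
}

ad_square <- function(tape, a) {
  ad_node(tape, a$val^2, list(a), function(g) ad_acc(a, 2 * g * a$val))
}

# sqrt(a + eps), eps > 0 keeps the gradient finite at zero
ad_sqrt_eps <- function(tape, a, eps = 1e-8) {
  v <- sqrt(a$val + eps)
  ad_node(tape, v, list(a), function(g) ad_acc(a, g * 0.5 / v))
}

## ---- reductions ------------------------------------------------------------

ad_sum <- function(tape, a) {
  ad_node(tape, matrix(sum(a$val), 1L, 1L), list(a), function(g) {
    ad_acc(a, matrix(g[1L], nrow(a$val), ncol(a$val)))
  })
}

ad_mean <- function(tape, a) {
  n <- length(a$val)
  ad_node(tape, matrix(mean(a$val), 1L, 1L), list(a), function(g) {
    ad_acc(a, matrix(g[1L] / n, nrow(a$val), ncol(a$val)))
  })
}

ad_rowsum <- function(tape, a) {
  d <- ncol(a$val)
  ad_node(tape, matrix(rowSums(a$val), ncol = 1L), list(a), function(g) {
    ad_acc(a, matrix(g, nrow(a$val), d))
  })
}

## ---- structural ops --------------------------------------------------------

ad_cbind <- function(tape, nodes) {
  widths <- vapply(nodes, function(x) ncol(x$val), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(tape, do.call(cbind, lapply(nodes, function(x) x$val)), nodes,
          function(g) {
            for (k in seq_along(nodes)) {
              ad_acc(nodes[[k]], g[, starts[k]:ends[k], drop = FALSE])
            }
          })
}

ad_rbind <- function(tape, nodes) {
  hts <- vapply(nodes, function(x) nrow(x$val), integer(1))
  ends <- cumsum(hts)
  starts <- ends - hts + 1L
  ad_node(tape, do.call(rbind, lapply(nodes, function(x) x$val)), nodes,
          function(g) {
            for (k in seq_along(nodes)) {
              ad_acc(nodes[[k]], g[starts[k]:ends[k], , drop = FALSE])
            }
          })
}

ad_cols <- function(tape, a, idx) {
  ad_node(tape, a$val[, idx, drop = FALSE], list(a), function(g) {
    gp <- matrix(0, nrow(a$val), ncol(a$val))
    gp[, idx] <- g
    ad_acc(a, gp)
  })
}

# scatter-add of g's rows into groups (shared by several backward passes)
ad_rowsum_scatter <- function(g, idx, nout) {
  rs <- rowsum(g, group = idx)
  out <- matrix(0, nout, ncol(g))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# gather rows: out[k, ] = a[idx[k], ]
ad_rows <- function(tape, a, idx) {
  ad_node(tape, a$val[idx, , drop = FALSE], list(a), function(g) {
    ad_acc(a, ad_rowsum_scatter(g, idx, nrow(a$val)))
  })
}

# scatter-add rows of a into nout rows: out[j, ] = sum_{k: idx[k]==j} a[k, ]
ad_scatter_add <- function(tape, a, idx, nout) {
  ad_node(tape, ad_rowsum_scatter(a$val, idx, nout), list(a), function(g) {
    ad_acc(a, g[idx, , drop = FALSE])
  })
}

# a (n x d) with P[gidx[i], ] added to row i (positional embeddings, biases)
ad_rowgroup_add <- function(tape, a, P, gidx) {
  ad_node(tape, a$val + P$val[gidx, , drop = FALSE], list(a, P), function(g) {
    ad_acc(a, g)
    ad_acc(P, ad_rowsum_scatter(g, gidx, nrow(P$val)))
  })
}

# select one entry per row: out[i] = a[i, j[i]]
ad_pick <- function(tape, a, j) {
  n <- nrow(a$val)
  ii <- cbind(seq_len(n), j)
  ad_node(tape, matrix(a$val[ii], ncol = 1L), list(a), function(g) {
    gp <- matrix(0, n, ncol(a$val))
    gp[ii] <- g
    ad_acc(a, gp)
  })
}

## ---- row-wise softmax family -----------------------------------------------

ad_softmax_rows <- function(tape, a) {
  m <- apply(a$val, 1L, max)
  e <- exp(a$val - m)
  s <- e / rowSums(e)
  ad_node(tape, s, list(a), function(g) {
    ad_acc(a, s * (g - rowSums(g * s)))
  })
}

ad_logsumexp_rows <- function(tape, a) {
  m <- apply(a$val, 1L, max)
  e <- exp(a$val - m)
  se <- rowSums(e)
  ad_node(tape, matrix(m + log(se), ncol = 1L), list(a), function(g) {
    ad_acc(a, (e / se) * as.vector(g))
  })
}

ad_log_softmax_rows <- function(tape, a) {
  m <- apply(a$val, 1L, max)
  sh <- a$val - m
  lse <- log(rowSums(exp(sh)))
  s <- exp(sh - lse)
  ad_node(tape, sh - lse, list(a), function(g) {
    ad_acc(a, g - s * rowSums(g))
  })
}

## ---- layer normalization over feature columns ------------------------------

ad_layernorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  x <- a$val
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowSums(xc^2) / d
  sd_ <- sqrt(v + eps)
  xhat <- xc / sd_
  out <- sweep(sweep(xhat, 2L, as.vector(gamma$val), "*"),
               2L, as.vector(beta$val), "+")
  ad_node(tape, out, list(a, gamma, beta), function(g) {
    dxhat <- sweep(g, 2L, as.vector(gamma$val), "*")
    dvar <- rowSums(dxhat * xc) * (-0.5) * (v + eps)^(-1.5)
    dmu <- -rowSums(dxhat) / sd_
    da <- dxhat / sd_ + (2 / d) * xc * dvar + dmu / d
    ad_acc(a, da)
    ad_acc(gamma, matrix(colSums(g * xhat), 1L))
    ad_acc(beta, matrix(colSums(g), 1L))
  })
}

## ---- token mixing across a blocked batch -----------------------------------

# X holds B frames of M tokens as a (B*M) x D matrix with the token index
# fastest (row (b-1)*M + m).  Returns (B*Mout) x D with
# out[b, a, ] = sum_m W[a, m] X[b, m, ]; W is Mout x M.
ad_blockmix <- function(tape, X, W, M) {
  D <- ncol(X$val)
  B <- nrow(X$val) %/% M
  stopifnot(B * M == nrow(X$val), ncol(W$val) == M)
  Mout <- nrow(W$val)
  fwd <- function(Xv, Wv) {
    Xm <- matrix(as.vector(Xv), nrow = M)          # M x (B*D)
    matrix(as.vector(Wv %*% Xm), nrow = Mout * B)  # (B*Mout) x D
  }
  val <- fwd(X$val, W$val)
  ad_node(tape, val, list(X, W), function(g) {
    Gm <- matrix(as.vector(g), nrow = Mout)        # Mout x (B*D)
    Xm <- matrix(as.vector(X$val), nrow = M)
    ad_acc(X, matrix(as.vector(t(W$val) %*% Gm), nrow = M * B))
    ad_acc(W, Gm %*% t(Xm))
  })
}

## ---- dense layers ----------------------------------------------------------

# y = act(x W + b); params is list(W = , b = ) of nodes
ad_dense <- function(tape, x, W, b, act = NULL) {
  h <- ad_rowbias(tape, ad_matmul(tape, x, W), b)
  if (is.null(act)) h else act(tape, h)
}

## ---- parameter binding -----------------------------------------------------

# Wrap a named list of numeric arrays as parameter nodes on the tape.
ad_bind_params <- function(tape, params) {
  lapply(params, function(p) ad_param(tape, p))
}

# Collect gradients of bound parameter nodes (zeros where unused).
ad_collect_grads <- function(bound) {
  lapply(bound, function(nd) {
    if (is.null(nd$grad)) matrix(0, nrow(nd$val), ncol(nd$val)) else nd$grad
  })
}
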