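# State Predictive Information Bottleneck (SPIB).
#
# A Gaussian encoder maps present features x_t to a latent z; a categorical
# decoder predicts the metastable-state label at t + tau from z.  The
# variational objective trades prediction accuracy against the information
# the latent retains about the input, with a mixture-of-posteriors
# (VampPrior) latent prior.  Labels start from k-means clusters and are
# iteratively refined: each frame is relabeled with the decoder argmax at
# the posterior mean, which empties redundant states until only metastable
# ones remain populated.

#' SPIB training configuration
#'
#' @param latentDim latent dimensionality
#' @param beta information-bottleneck tradeoff (>= 0); larger values merge
#'   states more aggressively
#' @param lag prediction lag tau in frames
#' @param initK initial number of k-means states
#' @param refreshInterval training steps between label refinements; `NULL`
#'   (default) refreshes once per epoch
#' @param nPseudo number of VampPrior mixture components
#' @param batchSize samples per gradient step
#' @param hiddenDim encoder/decoder hidden width
#' @param epochs training epochs
#' @param learningRate Adam learning rate
#' @param seed integer seed
#' @return list of class `spibConfig`
#' @export
spibConfig <- function(latentDim = 2L, beta = 0.01, lag = 1L, initK = 100L,
                       refreshInterval = NULL, nPseudo = 10L,
                       batchSize = 1000L, hiddenDim = 32L, epochs = 15L,
                       learningRate = 1e-3, seed = 1L) {
  stopifnot(latentDim >= 1, beta >= 0, lag >= 1, initK >= 1, nPseudo >= 1,
            batchSize >= 1, epochs >= 1)
  if (!is.null(refreshInterval)) stopifnot(refreshInterval >= 1)
  structure(list(latentDim = as.integer(latentDim), beta = beta,
                 lag = as.integer(lag), initK = as.integer(initK),
                 refreshInterval = if (is.null(refreshInterval)) NULL else
                   as.integer(refreshInterval),
                 nPseudo = as.integer(nPseudo),
                 batchSize = as.integer(batchSize),
                 hiddenDim = as.integer(hiddenDim),
                 epochs = as.integer(epochs), learningRate = learningRate,
                 seed = as.integer(seed)),
            class = "spibConfig")
}

#' Initial state labels by k-means
#'
#' Deterministic given the seed; labels are 1-based.
#'
#' @param cvSeries T x k_cv matrix of collective-variable values
#' @param k number of clusters
#' @param seed integer seed
#' @return a [StateLabels] with `k` possible labels
#' @export
initLabels <- function(cvSeries, k, seed = 1L) {
  cvSeries <- as.matrix(cvSeries)
  if (nrow(cvSeries) < k) {
    stop("need at least k = ", k, " frames for k-means initialization")
  }
  km <- local_seed(seed,
                   stats::kmeans(cvSeries, centers = k, nstart = 5L,
                                 iter.max = 50L))
  stateLabels(km$cluster, k = k)
}

spib_init <- function(cfg, dIn, pseudoInputs) {
  h <- cfg$hiddenDim
  L <- cfg$latentDim
  local_seed(derive_seed(cfg$seed, 17L), list(
    E_W1 = init_dense(dIn, h), E_b1 = init_zeros(h),
    E_W2 = init_dense(h, h), E_b2 = init_zeros(h),
    E_Wmu = init_dense(h, L), E_bmu = init_zeros(L),
    E_Wlv = init_dense(h, L), E_blv = matrix(-1, 1L, L),
    D_W1 = init_dense(L, h), D_b1 = init_zeros(h),
    D_W2 = init_dense(h, cfg$initK), D_b2 = init_zeros(cfg$initK),
    U = pseudoInputs,
    logw = matrix(0, 1L, nrow(pseudoInputs))
  ))
}

# encoder trunk: x node -> list(mu, logvar) nodes
spib_encode_fwd <- function(tape, bp, x) {
  h <- ad_silu(tape, ad_dense(tape, x, bp$E_W1, bp$E_b1))
  h <- ad_silu(tape, ad_dense(tape, h, bp$E_W2, bp$E_b2))
  list(mu = ad_dense(tape, h, bp$E_Wmu, bp$E_bmu),
       logvar = ad_dense(tape, h, bp$E_Wlv, bp$E_blv))
}

spib_decode_fwd <- function(tape, bp, z) {
  h <- ad_silu(tape, ad_dense(tape, z, bp$D_W1, bp$D_b1))
  ad_dense(tape, h, bp$D_W2, bp$D_b2)   # logits over initK
}

# log N(z; mu_row, diag(exp(logvar_row))) for every row of z against one
# component row; returns B x 1 node
gauss_logdens_row <- function(tape, z, mu_row, lv_row) {
  diff <- ad_sub_row(tape, z, mu_row)
  inv <- ad_exp(tape, ad_neg(tape, lv_row))      # 1 x L
  quad <- ad_mul_row(tape, ad_square(tape, diff), inv)
  tot <- ad_rowbias(tape, quad, lv_row)          # adds logvar per column
  s <- ad_rowsum(tape, tot)
  L <- ncol(z$val)
  ad_addc(tape, ad_scale(tape, s, -0.5), -0.5 * L * log(2 * pi))
}

#' Sample the SPIB latent posterior
#'
#' Reparameterized draw z = mu + exp(logvar/2) * eps with standard-normal
#' eps; mu and the diagonal covariance are deterministic in the input.
#'
#' @param features numeric vector or matrix of input features (rows =
#'   samples)
#' @param model a `spibFit` or raw SPIB parameter list
#' @param seed integer seed for the noise draw
#' @return list with `z`, `mean`, `logvar` matrices (rows = samples)
#' @export
encodeLatent <- function(features, model, seed = 1L) {
  params <- if (inherits(model, "spibFit")) model$params else model
  x <- if (is.matrix(features)) features else matrix(features, 1L)
  tape <- ad_tape()
  bp <- lapply(params, function(p) ad_const(tape, p))
  enc <- spib_encode_fwd(tape, bp, ad_const(tape, x))
  mu <- enc$mu$val
  lv <- enc$logvar$val
  eps <- local_seed(seed, matrix(stats::rnorm(length(mu)), nrow(mu)))
  list(z = mu + exp(0.5 * lv) * eps, mean = mu, logvar = lv)
}

#' Decode state probabilities from a latent point
#'
#' @param z numeric vector or matrix of latent coordinates (rows = samples)
#' @param model a `spibFit` or raw SPIB parameter list
#' @return matrix of per-state probabilities; each row sums to 1
#' @export
decodeState <- function(z, model) {
  params <- if (inherits(model, "spibFit")) model$params else model
  zm <- if (is.matrix(z)) z else matrix(z, 1L)
  tape <- ad_tape()
  bp <- lapply(params, function(p) ad_const(tape, p))
  lg <- spib_decode_fwd(tape, bp, ad_const(tape, zm))$val
  e <- exp(lg - apply(lg, 1L, max))
  e / rowSums(e)
}

#' VampPrior density at latent points
#'
#' r(z) = sum_i w_i p(z | u_i) / sum_i w_i, the weight-normalized mixture
#' of encoder posteriors at the pseudo-inputs.
#'
#' @param z numeric vector or matrix of latent points (rows = samples)
#' @param model a `spibFit` or raw SPIB parameter list
#' @return numeric vector of strictly positive densities
#' @export
vampPriorDensity <- function(z, model) {
  params <- if (inherits(model, "spibFit")) model$params else model
  w <- exp(as.vector(params$logw))
  if (all(w == 0)) stop("all VampPrior weights are zero")
  zm <- if (is.matrix(z)) z else matrix(z, 1L)
  tape <- ad_tape()
  bp <- lapply(params, function(p) ad_const(tape, p))
  enc <- spib_encode_fwd(tape, bp, ad_const(tape, params$U))
  mu <- enc$mu$val
  lv <- enc$logvar$val
  L <- ncol(mu)
  dens <- matrix(0, nrow(zm), nrow(mu))
  for (i in seq_len(nrow(mu))) {
    q <- sweep(zm, 2L, mu[i, ], "-")^2 %*% exp(-lv[i, ])
    dens[, i] <- exp(-0.5 * (q + sum(lv[i, ]) + L * log(2 * pi)))
  }
  as.vector(dens %*% (w / sum(w)))
}

# tape-level loss (to MINIMIZE): -E[log q(s|z)] + beta E[log p(z|x)-log r(z)]
spib_loss_fwd <- function(tape, bp, x, yTarget, eps_mat, beta, nPseudo) {
  enc <- spib_encode_fwd(tape, bp, x)
  sd_ <- ad_exp(tape, ad_scale(tape, enc$logvar, 0.5))
  z <- ad_add(tape, enc$mu, ad_mul(tape, sd_, ad_const(tape, eps_mat)))
  logq <- ad_log_softmax_rows(tape, spib_decode_fwd(tape, bp, z))
  ce <- ad_mean(tape, ad_pick(tape, logq, yTarget))       # E[log q(s|z)]
  # log p(z|x): diff = sd * eps, so quad term = sum(eps^2); keep the graph
  # through logvar only (the quad term's z/mu dependence cancels exactly)
  L <- ncol(enc$mu$val)
  logp <- ad_addc(tape,
                  ad_scale(tape, ad_rowsum(tape, enc$logvar), -0.5),
                  -0.5 * L * log(2 * pi))
  logp <- ad_add(tape, logp, ad_const(
    tape, matrix(-0.5 * rowSums(eps_mat^2), ncol = 1L)))
  encU <- spib_encode_fwd(tape, bp, bp$U)
  comp <- vector("list", nPseudo)
  for (i in seq_len(nPseudo)) {
    comp[[i]] <- gauss_logdens_row(tape, z,
                                   ad_rows(tape, encU$mu, i),
                                   ad_rows(tape, encU$logvar, i))
  }
  lse <- ad_logsumexp_rows(tape, bp$logw)         # 1 x 1
  nP <- ncol(bp$logw$val)
  lw <- ad_sub(tape, bp$logw,
               ad_matmul(tape, lse, ad_const(tape, matrix(1, 1L, nP))))
  compM <- ad_cbind(tape, comp)                   # B x nPseudo
  logr <- ad_logsumexp_rows(tape, ad_rowbias(tape, compM, lw))
  kl <- ad_mean(tape, ad_sub(tape, logp, logr))
  ad_add(tape, ad_scale(tape, ce, -1), ad_scale(tape, kl, beta))
}

#' SPIB objective on a batch
#'
#' Monte-Carlo estimate (one latent sample per datum) of the SPIB loss:
#' `E[log q(s_tau | z)] - beta * E[log p(z|x) - log r(z)]`.  Returned as
#' the value to *maximize*; [trainSpib()] minimizes its negative.
#'
#' @param features B x d input feature matrix
#' @param targets integer labels (1-based) of the frames at t + tau
#' @param model a `spibFit` or raw SPIB parameter list
#' @param beta tradeoff parameter
#' @param seed seed for the latent noise
#' @return scalar objective value
#' @export
spibLoss <- function(features, targets, model, beta = 0.01, seed = 1L) {
  params <- if (inherits(model, "spibFit")) model$params else model
  x <- as.matrix(features)
  stopifnot(nrow(x) == length(targets), nrow(x) >= 1L)
  tape <- ad_tape()
  bp <- lapply(params, function(p) ad_const(tape, p))
  eps_mat <- local_seed(seed, matrix(stats::rnorm(nrow(x) * ncol(params$E_Wmu)),
                                     nrow(x)))
  loss <- spib_loss_fwd(tape, bp, ad_const(tape, x), as.integer(targets),
                        eps_mat, beta, nrow(params$U))
  v <- -loss$val[1L]
  if (!is.finite(v)) stop("SPIB objective is non-finite")
  v
}

#' Refine state labels by decoder argmax at the posterior mean
#'
#' Deterministic (no latent sampling); ties go to the lowest label index.
#' States that receive no frames become unpopulated and are ignored from
#' then on.
#'
#' @param features T x d input feature matrix
#' @param model a `spibFit` or raw SPIB parameter list
#' @param k total number of possible labels (`initK`)
#' @return a [StateLabels]
#' @export
refineLabels <- function(features, model, k) {
  params <- if (inherits(model, "spibFit")) model$params else model
  x <- as.matrix(features)
  lab <- integer(nrow(x))
  bs <- 5000L
  for (s in seq(1L, nrow(x), by = bs)) {
    ids <- s:min(s + bs - 1L, nrow(x))
    tape <- ad_tape()
    bp <- lapply(params, function(p) ad_const(tape, p))
    mu <- spib_encode_fwd(tape, bp, ad_const(tape, x[ids, , drop = FALSE]))$mu
    lg <- spib_decode_fwd(tape, bp, mu)$val
    lab[ids] <- max.col(lg, ties.method = "first")
  }
  stateLabels(lab, k = k)
}

# features argument normalization: matrix, or FeatureStore (token-mean pool)
spib_features <- function(x) {
  if (is(x, "FeatureStore")) {
    sc <- x@scalars
    matrix(apply(sc, c(1L, 3L), mean), dim(sc)[1L])
  } else {
    as.matrix(x)
  }
}

#' Train a State Predictive Information Bottleneck model
#'
#' Alternates gradient steps on the SPIB objective with deterministic label
#' refinement every `refreshInterval` steps (default: once per epoch).
#' Targets are the current labels at t + tau; pairs never cross training
#' segment boundaries.  The populated-state count is recorded at every
#' refresh.
#'
#' @param features T x d feature matrix (e.g. collective variables or
#'   pooled tokens), or a [FeatureStore] (scalar channels are mean-pooled
#'   over tokens)
#' @param cfg a [spibConfig()]
#' @param split a [temporalSplit()] result; training pairs are drawn from
#'   its segments
#' @param initialLabels optional [StateLabels]; default k-means on the
#'   features with `cfg$initK` clusters
#' @return list of class `spibFit`: `params`, `cfg`, `labels`
#'   (final [StateLabels]), `populatedTrace`, `lossTrace`
#' @export
trainSpib <- function(features, cfg, split, initialLabels = NULL) {
  stopifnot(inherits(cfg, "spibConfig"))
  X <- spib_features(features)
  TT <- nrow(X)
  labels <- if (is.null(initialLabels)) {
    initLabels(X, cfg$initK, seed = derive_seed(cfg$seed, 3L))
  } else {
    stopifnot(is(initialLabels, "StateLabels"))
    if (initialLabels@k != cfg$initK) stop("initialLabels@k != cfg$initK")
    initialLabels
  }
  segs <- split$trainSegments
  seg_ok <- segs[vapply(segs, length, integer(1)) > cfg$lag]
  if (length(seg_ok) == 0L) stop("lag exceeds every training segment")
  pair_t <- unlist(lapply(seg_ok, function(s) s[seq_len(length(s) - cfg$lag)]))
  n_pairs <- length(pair_t)
  steps_per_epoch <- max(1L, ceiling(n_pairs / cfg$batchSize))
  refresh <- cfg$refreshInterval %||% steps_per_epoch

  u_idx <- local_seed(derive_seed(cfg$seed, 5L),
                      sample(pair_t, cfg$nPseudo, replace = cfg$nPseudo > n_pairs))
  params <- spib_init(cfg, ncol(X), X[u_idx, , drop = FALSE])
  opt <- adam_init(params)

  lab <- labelVector(labels)
  populated <- data.frame(step = 0L, populated = populatedCount(labels))
  loss_trace <- numeric(0)
  step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- local_seed(derive_seed(cfg$seed, 100L + ep), sample(n_pairs))
    for (s in seq(1L, n_pairs, by = cfg$batchSize)) {
      step <- step + 1L
      ids <- pair_t[ord[s:min(s + cfg$batchSize - 1L, n_pairs)]]
      xb <- X[ids, , drop = FALSE]
      yb <- lab[ids + cfg$lag]
      tape <- ad_tape()
      bp <- ad_bind_params(tape, params)
      eps_mat <- local_seed(derive_seed(cfg$seed, 1000L + step),
                            matrix(stats::rnorm(nrow(xb) * cfg$latentDim),
                                   nrow(xb)))
      loss <- spib_loss_fwd(tape, bp, ad_const(tape, xb), yb, eps_mat,
                            cfg$beta, cfg$nPseudo)
      lv <- loss$val[1L]
      if (!is.finite(lv)) {
        stop("SPIB training diverged at step ", step, "; recent losses: ",
             paste(signif(utils::tail(loss_trace, 5L), 4L), collapse = ", "))
      }
      loss_trace <- c(loss_trace, lv)
      ad_backward(tape, loss)
      st <- adam_step(opt, params, ad_collect_grads(bp),
                      lr = cfg$learningRate)
      params <- st$params
      opt <- st$state
      if (step %% refresh == 0L) {
        labels <- refineLabels(X, params, cfg$initK)
        lab <- labelVector(labels)
        populated <- rbind(populated,
                           data.frame(step = step,
                                      populated = populatedCount(labels)))
      }
    }
  }
  labels <- refineLabels(X, params, cfg$initK)
  if (populated$step[nrow(populated)] != step) {
    populated <- rbind(populated,
                       data.frame(step = step,
                                  populated = populatedCount(labels)))
  }
  structure(list(params = params, cfg = cfg, labels = labels,
                 populatedTrace = populated, lossTrace = loss_trace),
            class = "spibFit")
}

#' @export
print.spibFit <- function(x, ...) {
  cat(sprintf(
    "SPIB fit: latent %d, beta %.3g, lag %d; %d of %d states populated\n",
    x$cfg$latentDim, x$cfg$beta, x$cfg$lag, populatedCount(x$labels),
    x$cfg$initK))
  invisible(x)
}
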