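# VAMP-2 scoring and VAMPnet training.
#
# The VAMP-2 score is the squared Frobenius norm of the whitened time-lagged
# cross-correlation, || C00^{-1/2} C0t Ctt^{-1/2} ||_F^2, estimated from
# batches of trajectory-frame pairs separated by the lag time.  Training
# maximizes the score by gradient ascent through the whitening transform;
# the gradient is computed analytically via the eigendecomposition chain
# rule for the regularized inverse matrix square root.

#' Sample lagged frame pairs
#'
#' Draws `batch` pairs (t, t + tau), uniformly over admissible start frames.
#' Pairs never span trajectory (or training-segment) boundaries.
#'
#' @param lengths integer vector of per-trajectory frame counts
#' @param tau lag in frames (tau = 0 gives pairs of identical frames)
#' @param batch number of pairs to draw
#' @param seed integer seed
#' @return list with `traj`, `t0`, `t1` (per-trajectory frame index) and
#'   `g0`, `g1` (frame index into the concatenated trajectory)
#' @export
sampleLaggedPairs <- function(lengths, tau, batch, seed = 1L) {
  stopifnot(tau >= 0, batch >= 1)
  if (any(lengths <= tau)) {
    stop("lag tau = ", tau, " is not shorter than every trajectory")
  }
  offs <- cumsum(c(0L, lengths[-length(lengths)]))
  n_adm <- lengths - tau
  tot <- sum(n_adm)
  pick <- local_seed(seed, sample.int(tot, batch, replace = TRUE))
  traj <- findInterval(pick - 1L, cumsum(c(0L, n_adm)), left.open = FALSE,
                       rightmost.closed = TRUE)
  traj <- pmin(traj, length(lengths))
  t0 <- pick - cumsum(c(0L, n_adm))[traj]
  list(traj = traj, t0 = t0, t1 = t0 + tau,
       g0 = offs[traj] + t0, g1 = offs[traj] + t0 + tau)
}

#' Instantaneous and time-lagged correlation matrices
#'
#' C00 = A'A/n, C0t = A'B/n, Ctt = B'B/n after optional column-mean
#' centering of A and B (each by its own mean).
#'
#' @param A n x d feature matrix at time t
#' @param B n x d feature matrix at time t + tau
#' @param center subtract column means first
#' @return list of class `correlationTriple` with `C00`, `C0t`, `Ctt`, `n`
#' @export
correlationMatrices <- function(A, B, center = TRUE) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("A and B must have matching shapes")
  n <- nrow(A)
  if (center) {
    if (n < 2L) stop("centering needs at least two samples")
    A <- scale(A, center = TRUE, scale = FALSE)
    B <- scale(B, center = TRUE, scale = FALSE)
  }
  structure(list(C00 = crossprod(A) / n, C0t = crossprod(A, B) / n,
                 Ctt = crossprod(B) / n, n = n),
            class = "correlationTriple")
}

#' Regularized inverse matrix square root
#'
#' Eigendecomposition with eigenvalues floored at `eps * max(eigenvalue)`;
#' returns U diag(lambda^{-1/2}) U'.
#'
#' @param S symmetric positive semidefinite matrix
#' @param eps relative eigenvalue floor
#' @return symmetric matrix S^{-1/2}
#' @export
invSqrt <- function(S, eps = 1e-6) {
  S <- as.matrix(S)
  if (max(abs(S - t(S))) > 1e-6 * max(1, max(abs(S)))) {
    stop("matrix is not symmetric")
  }
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lf <- pmax(e$values, eps * max(e$values, 0), .Machine$double.eps)
  e$vectors %*% (t(e$vectors) * lf^(-0.5))
}

#' VAMP-2 score of a correlation triple
#'
#' @param triple a [correlationMatrices()] result (or list with C00, C0t,
#'   Ctt)
#' @param eps relative eigenvalue floor for the whitening inverses
#' @return the score, a non-negative scalar
#' @export
vamp2Score <- function(triple, eps = 1e-6) {
  K <- invSqrt(triple$C00, eps) %*% triple$C0t %*% invSqrt(triple$Ctt, eps)
  s <- sum(K^2)
  if (!is.finite(s)) {
    stop("VAMP-2 score is non-finite; condition numbers: C00 ",
         format(kappa(triple$C00)), ", Ctt ", format(kappa(triple$Ctt)),
         ". Increase the batch size or the eigenvalue floor.")
  }
  s
}

# d f(C)/dC for scalar objective with G = dR/dW, W = f(C) spectral function.
# Returns the symmetric gradient matrix dR/dC.
spectral_backward <- function(C, G, eps) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  lam <- e$values
  floor_ <- max(eps * max(lam, 0), .Machine$double.eps)
  lf <- pmax(lam, floor_)
  f <- lf^(-0.5)
  fp <- ifelse(lam > floor_, -0.5 * lf^(-1.5), 0)
  K <- length(lam)
  F_ <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      F_[i, j] <- if (abs(lam[i] - lam[j]) > 1e-12 * max(1, abs(lam[i]))) {
        (f[i] - f[j]) / (lam[i] - lam[j])
      } else {
        0.5 * (fp[i] + fp[j])
      }
    }
  }
  Gs <- (G + t(G)) / 2
  U <- e$vectors
  U %*% (F_ * (t(U) %*% Gs %*% U)) %*% t(U)
}

# Analytic score and gradients of the empirical VAMP-2 w.r.t. the feature
# matrices.  Verified against finite differences in the test suite.
vamp2_score_grad <- function(A, B, eps = 1e-6, center = TRUE) {
  n <- nrow(A)
  if (center) {
    Ac <- scale(A, center = TRUE, scale = FALSE)
    Bc <- scale(B, center = TRUE, scale = FALSE)
  } else {
    Ac <- A
    Bc <- B
  }
  C00 <- crossprod(Ac) / n
  C0t <- crossprod(Ac, Bc) / n
  Ctt <- crossprod(Bc) / n
  W0 <- invSqrt(C00, eps)
  Wt <- invSqrt(Ctt, eps)
  S <- W0 %*% C0t %*% Wt
  score <- sum(S^2)
  G0t <- 2 * W0 %*% S %*% Wt
  GW0 <- 2 * S %*% Wt %*% t(C0t)
  GWt <- 2 * t(S) %*% W0 %*% C0t
  G00 <- spectral_backward(C00, GW0, eps)
  Gtt <- spectral_backward(Ctt, GWt, eps)
  gA <- (Ac %*% (G00 + t(G00)) + Bc %*% t(G0t)) / n
  gB <- (Bc %*% (Gtt + t(Gtt)) + Ac %*% G0t) / n
  if (center) {
    gA <- scale(gA, center = TRUE, scale = FALSE)
    gB <- scale(gB, center = TRUE, scale = FALSE)
  }
  list(score = score, gA = unclass(gA), gB = unclass(gB))
}

# tape op wrapping the analytic gradient
ad_vamp2 <- function(tape, A, B, eps = 1e-6, center = TRUE) {
  r <- vamp2_score_grad(A$val, B$val, eps = eps, center = center)
  ad_node(tape, matrix(r$score, 1L, 1L), list(A, B), function(g) {
    ad_acc(A, g[1L] * r$gA)
    ad_acc(B, g[1L] * r$gB)
  })
}

#' VAMPnet training configuration
#'
#' Early stopping follows a dual-patience rule: training stops when the
#' training score has not improved for `trainPatience` batches or the
#' validation score has not improved for `valPatience` consecutive
#' evaluations (validation is evaluated every `valEvery` training steps).
#'
#' @param outputDim number of collective variables d_o
#' @param lag lag time tau in frames
#' @param batchSize frame pairs per batch; small batches make the
#'   correlation-matrix inversion unstable, hence the warning below 1000
#' @param valEvery validation evaluation period in training steps
#' @param trainPatience training-score patience in batches
#' @param valPatience validation-score patience in evaluations
#' @param maxSteps hard cap on training steps
#' @param learningRate Adam learning rate
#' @param eps relative eigenvalue floor in the whitening inverses
#' @param center mean-center features before the correlation matrices
#'   (removes the trivial constant mode)
#' @param seed integer seed
#' @return list of class `vampTrainConfig`
#' @export
vampTrainConfig <- function(outputDim = 2L, lag = 1L, batchSize = 5000L,
                            valEvery = 10L, trainPatience = 500L,
                            valPatience = 10L, maxSteps = 2000L,
                            learningRate = 3e-4, eps = 1e-6, center = TRUE,
                            seed = 1L) {
  stopifnot(outputDim >= 1, lag >= 0, batchSize >= 1)
  if (batchSize < 1000L) {
    warning("batch sizes below 1000 often destabilize the correlation ",
            "matrix inversion")
  }
  structure(list(outputDim = as.integer(outputDim), lag = as.integer(lag),
                 batchSize = as.integer(batchSize),
                 valEvery = as.integer(valEvery),
                 trainPatience = as.integer(trainPatience),
                 valPatience = as.integer(valPatience),
                 maxSteps = as.integer(maxSteps),
                 learningRate = learningRate, eps = eps,
                 center = isTRUE(center), seed = as.integer(seed)),
            class = "vampTrainConfig")
}

# Flatten store frames to the row-blocked (|frames|*M) x d scalar matrix
# (and optional vector components) the mixers consume.
store_block <- function(store, frames, vectors = FALSE) {
  sc <- store@scalars[frames, , , drop = FALSE]
  TT <- length(frames)
  M <- dim(sc)[2L]
  d <- dim(sc)[3L]
  Xs <- matrix(aperm(sc, c(2L, 1L, 3L)), TT * M, d)
  out <- list(Xs = Xs)
  if (vectors) {
    out$Xv <- lapply(1:3, function(cc) {
      vv <- store@vectors[frames, , cc, , drop = FALSE]
      matrix(aperm(array(vv, dim = dim(vv)[c(1L, 2L, 4L)]),
                   c(2L, 1L, 3L)), TT * M, d)
    })
  }
  out
}

# forward a set of frames through the mixer; returns chi matrix (no grad)
mixer_apply <- function(params, cfg, M, store, frames, gdist = NULL,
                        want_attention = FALSE) {
  need_vec <- grepl("gvp", cfg$kind)
  blk <- store_block(store, frames, vectors = need_vec)
  tape <- ad_tape()
  bp <- lapply(params, function(p) ad_const(tape, p))
  Xs <- ad_const(tape, blk$Xs)
  Xv <- if (need_vec) lapply(blk$Xv, function(v) ad_const(tape, v)) else NULL
  gd <- if (!is.null(gdist)) {
    ad_const(tape, gdist[frames, , drop = FALSE])
  } else NULL
  out <- mixer_forward(tape, bp, cfg, M, Xs, Xv, gd,
                       want_attention = want_attention)
  list(chi = out$feat$val, attn = out$attn)
}

#' Train a VAMPnet over token features
#'
#' Gradient ascent on the VAMP-2 score of the mixer + output-head network,
#' with lagged-pair batches drawn from the training segments and the
#' dual-patience early-stopping rule.  Returns the parameters of the best
#' validation evaluation.
#'
#' @param store a [FeatureStore]
#' @param mixerCfg a [mixerConfig()]; its `outputDim` is overridden by the
#'   training configuration
#' @param cfg a [vampTrainConfig()]
#' @param split a [temporalSplit()] result (training segments + validation)
#' @param globalDist optional T x P matrix of per-frame pairwise distances
#'   feeding the subformer's global token
#' @return list of class `vampnetFit`: `params`, `mixerCfg`, `cfg`, `trace`
#'   (per-step scores), `bestValScore`, `M`, `storeMeta`
#' @export
trainVampnet <- function(store, mixerCfg, cfg, split, globalDist = NULL) {
  stopifnot(is(store, "FeatureStore"), inherits(mixerCfg, "mixerConfig"),
            inherits(cfg, "vampTrainConfig"))
  M <- nTokens(store)
  d <- dim(store@scalars)[3L]
  mixerCfg$outputDim <- cfg$outputDim
  seg_lengths <- vapply(split$trainSegments, length, integer(1))
  if (all(seg_lengths <= cfg$lag)) stop("lag exceeds every training segment")
  val_len <- length(split$val)
  if (val_len <= cfg$lag) stop("lag exceeds the validation set")

  gstats <- NULL
  nG <- NULL
  if (!is.null(globalDist) && grepl("subformer", mixerCfg$kind)) {
    tr_rows <- globalDist[split$train, , drop = FALSE]
    gstats <- list(mean = colMeans(tr_rows),
                   sd = pmax(apply(tr_rows, 2L, stats::sd), 1e-8))
    nG <- ncol(globalDist)
  }
  params <- mixer_init(mixerCfg, M, d, nGlobalDist = nG,
                       globalStats = gstats)
  frozen <- intersect(names(params), c("GT_mean", "GT_sd"))
  opt <- adam_init(params)
  need_vec <- grepl("gvp", mixerCfg$kind)

  seg_ok <- split$trainSegments[seg_lengths > cfg$lag]
  sample_train <- function(seed) {
    sp <- sampleLaggedPairs(vapply(seg_ok, length, integer(1)), cfg$lag,
                            cfg$batchSize, seed = seed)
    flat <- unlist(seg_ok)
    offs <- cumsum(c(0L, vapply(seg_ok, length, integer(1))))
    list(f0 = flat[offs[sp$traj] + sp$t0], f1 = flat[offs[sp$traj] + sp$t1])
  }
  sample_val <- function(seed) {
    sp <- sampleLaggedPairs(val_len, cfg$lag, cfg$batchSize, seed = seed)
    list(f0 = split$val[sp$t0], f1 = split$val[sp$t1])
  }

  score_batch <- function(params, f0, f1, want_grad) {
    frames <- c(f0, f1)
    blk <- store_block(store, frames, vectors = need_vec)
    tape <- ad_tape()
    bp <- if (want_grad) ad_bind_params(tape, params) else
      lapply(params, function(p) ad_const(tape, p))
    Xs <- ad_const(tape, blk$Xs)
    Xv <- if (need_vec) lapply(blk$Xv, function(v) ad_const(tape, v)) else
      NULL
    gd <- if (!is.null(nG)) ad_const(tape, rbind(
      globalDist[f0, , drop = FALSE], globalDist[f1, , drop = FALSE])) else
      NULL
    out <- mixer_forward(tape, bp, mixerCfg, M, Xs, Xv, gd)
    nb <- length(f0)
    chi0 <- ad_rows(tape, out$feat, seq_len(nb))
    chit <- ad_rows(tape, out$feat, nb + seq_len(nb))
    sc <- ad_vamp2(tape, chi0, chit, eps = cfg$eps, center = cfg$center)
    if (!is.finite(sc$val[1L])) {
      stop("VAMP-2 score became non-finite during training; raise the ",
           "batch size (current ", cfg$batchSize, ") or eps")
    }
    if (want_grad) {
      loss <- ad_scale(tape, sc, -1)
      ad_backward(tape, loss)
      g <- ad_collect_grads(bp)
      for (nm in frozen) g[[nm]][] <- 0
      list(score = sc$val[1L], grads = g)
    } else {
      list(score = sc$val[1L])
    }
  }

  trace <- data.frame(step = integer(0), train_score = numeric(0),
                      val_score = numeric(0))
  best_train <- -Inf
  best_train_step <- 0L
  best_val <- -Inf
  val_bad <- 0L
  best_params <- params
  stop_reason <- "maxSteps"
  step <- 0L
  while (step < cfg$maxSteps) {
    step <- step + 1L
    tr <- sample_train(derive_seed(cfg$seed, 2L * step))
    res <- score_batch(params, tr$f0, tr$f1, TRUE)
    st <- adam_step(opt, params, res$grads, lr = cfg$learningRate)
    params <- st$params
    opt <- st$state
    val_sc <- NA_real_
    if (step %% cfg$valEvery == 0L) {
      vb <- sample_val(derive_seed(cfg$seed, 2L * step + 1L))
      val_sc <- score_batch(params, vb$f0, vb$f1, FALSE)$score
      if (val_sc > best_val + 1e-6) {
        best_val <- val_sc
        best_params <- params
        val_bad <- 0L
      } else {
        val_bad <- val_bad + 1L
      }
    }
    trace <- rbind(trace, data.frame(step = step, train_score = res$score,
                                     val_score = val_sc))
    if (res$score > best_train + 1e-6) {
      best_train <- res$score
      best_train_step <- step
    }
    if (val_bad >= cfg$valPatience) {
      stop_reason <- "valPatience"
      break
    }
    if (step - best_train_step >= cfg$trainPatience) {
      stop_reason <- "trainPatience"
      break
    }
  }
  structure(list(params = best_params, mixerCfg = mixerCfg, cfg = cfg,
                 trace = trace, bestValScore = best_val,
                 stopReason = stop_reason, M = M,
                 storeMeta = storeMetadata(store)),
            class = "vampnetFit")
}

#' @export
print.vampnetFit <- function(x, ...) {
  cat(sprintf(
    "VAMPnet (%s mixer): d_o = %d, lag = %d; best validation VAMP-2 %.3f (%s)\n",
    x$mixerCfg$kind, x$cfg$outputDim, x$cfg$lag, x$bestValScore,
    x$stopReason))
  invisible(x)
}

#' Evaluate learned collective variables on a feature store
#'
#' Applies the trained network to every frame.  With `canonical = TRUE`
#' (default) the raw outputs are projected onto the VAMP singular functions
#' estimated at the training lag over the whole store, so CV 1 is the
#' slowest decorrelating mode, CV 2 the next, and so on.
#'
#' @param model a `vampnetFit`
#' @param store a [FeatureStore] (must match the training store's token
#'   count and channel width)
#' @param canonical order outputs by singular value
#' @param globalDist optional distance matrix, as in [trainVampnet()]
#' @return numeric T x d_o matrix of CV values
#' @export
evaluateCVs <- function(model, store, canonical = TRUE, globalDist = NULL) {
  stopifnot(inherits(model, "vampnetFit"), is(store, "FeatureStore"))
  if (nTokens(store) != model$M) stop("token count mismatch with model")
  TT <- nFrames(store)
  chi <- matrix(0, TT, model$cfg$outputDim)
  bs <- 2000L
  for (s in seq(1L, TT, by = bs)) {
    ids <- s:min(s + bs - 1L, TT)
    chi[ids, ] <- mixer_apply(model$params, model$mixerCfg, model$M, store,
                              ids, gdist = globalDist)$chi
  }
  if (!canonical) return(chi)
  lag <- max(1L, model$cfg$lag)
  if (TT <= lag) return(chi)
  A <- chi[1:(TT - lag), , drop = FALSE]
  B <- chi[(1 + lag):TT, , drop = FALSE]
  tr <- correlationMatrices(A, B, center = model$cfg$center)
  W0 <- invSqrt(tr$C00, model$cfg$eps)
  K <- W0 %*% tr$C0t %*% invSqrt(tr$Ctt, model$cfg$eps)
  sv <- svd(K)
  chic <- if (model$cfg$center) {
    scale(chi, center = colMeans(A), scale = FALSE)
  } else chi
  unclass(chic %*% W0 %*% sv$u)
}

#' VAMP-2 score of a trained model over a frame range
#'
#' Deterministic estimate using *all* lagged pairs within the given frames
#' (contiguous range assumed), avoiding both sampling noise and the
#' selection bias of the best-validation checkpoint score.
#'
#' @param model a `vampnetFit`
#' @param store a [FeatureStore]
#' @param frames contiguous frame indices (e.g. a validation half)
#' @param globalDist optional distance matrix, as in [trainVampnet()]
#' @return the VAMP-2 score under the model's centering convention
#' @export
vampScoreOnFrames <- function(model, store, frames, globalDist = NULL) {
  stopifnot(inherits(model, "vampnetFit"))
  chi <- matrix(0, length(frames), model$cfg$outputDim)
  bs <- 2000L
  for (s in seq(1L, length(frames), by = bs)) {
    ii <- s:min(s + bs - 1L, length(frames))
    chi[ii, ] <- mixer_apply(model$params, model$mixerCfg, model$M, store,
                             frames[ii], gdist = globalDist)$chi
  }
  lag <- model$cfg$lag
  n <- nrow(chi)
  if (n <= lag) stop("frame range shorter than the lag")
  tr <- correlationMatrices(chi[1:(n - lag), , drop = FALSE],
                            chi[(1 + lag):n, , drop = FALSE],
                            center = model$cfg$center)
  vamp2Score(tr, eps = model$cfg$eps)
}

#' Head-averaged attention maps over selected frames
#'
#' @param model a `vampnetFit` with a subformer mixer
#' @param store a [FeatureStore]
#' @param frames frame indices (default all)
#' @param globalDist optional distance matrix for the global token
#' @return list of per-layer arrays (M+1) x (M+1) x |frames|; each row of
#'   each per-frame map sums to 1
#' @export
attentionMaps <- function(model, store, frames = seq_len(nFrames(store)),
                          globalDist = NULL) {
  stopifnot(inherits(model, "vampnetFit"))
  if (!grepl("subformer", model$mixerCfg$kind)) {
    stop("attention maps are only available for subformer mixers")
  }
  maps <- NULL
  bs <- 1000L
  for (s in seq(1L, length(frames), by = bs)) {
    ids <- frames[s:min(s + bs - 1L, length(frames))]
    a <- mixer_apply(model$params, model$mixerCfg, model$M, store, ids,
                     gdist = globalDist, want_attention = TRUE)$attn
    if (is.null(maps)) {
      maps <- a
    } else {
      for (l in seq_along(maps)) {
        maps[[l]] <- array(c(maps[[l]], a[[l]]),
                           dim = c(dim(a[[l]])[1:2],
                                   dim(maps[[l]])[3] + dim(a[[l]])[3]))
      }
    }
  }
  maps
}
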