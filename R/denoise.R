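# Self-supervised pretraining by coordinate denoising: Gaussian displacements
# are added to conformer coordinates and the encoder plus a gated equivariant
# head are trained to predict them.  The encoder resulting from the epoch
# with the lowest validation MSE is the frozen featurizer used downstream.

#' Denoising pretraining configuration
#'
#' @param sigma standard deviation of the added Gaussian displacements
#'   (Angstrom).  Must be non-negative.
#' @param epochs number of training epochs
#' @param batchSize conformers per gradient step
#' @param learningRate Adam learning rate
#' @param valCount number of conformers held out for validation (disjoint
#'   from training, selected at random under the seed)
#' @param seed integer seed controlling the split, the noise draws, and the
#'   parameter initialization order
#' @return a list of class `denoiseConfig`
#' @export
denoiseConfig <- function(sigma = 0.2, epochs = 20L, batchSize = 32L,
                          learningRate = 1e-3, valCount = 50L, seed = 1L) {
  if (sigma < 0) stop("sigma must be non-negative")
  stopifnot(epochs >= 1, batchSize >= 1, valCount >= 1)
  structure(list(sigma = sigma, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate,
                 valCount = as.integer(valCount), seed = as.integer(seed)),
            class = "denoiseConfig")
}

#' Corrupt coordinates with Gaussian displacements
#'
#' Draws i.i.d. Normal(0, sigma^2) displacements per coordinate component and
#' adds them to the clean coordinates.  When dataset normalization constants
#' are supplied, the returned target is the standardized displacement.
#'
#' @param coords numeric N x 3 clean coordinates
#' @param sigma displacement scale (Angstrom), >= 0
#' @param seed integer seed making the draw reproducible
#' @param norm optional list(mean =, sd =) of dataset normalization constants
#' @return list with `clean`, `noisy`, `raw` (drawn displacements) and
#'   `target` (normalized displacements; equals `raw` when `norm` is NULL)
#' @export
corrupt <- function(coords, sigma, seed = NULL, norm = NULL) {
  if (sigma < 0) stop("sigma must be non-negative")
  coords <- as.matrix(coords)
  raw <- if (is.null(seed)) {
    matrix(stats::rnorm(length(coords), 0, sigma), nrow(coords), 3L)
  } else {
    local_seed(seed,
      matrix(stats::rnorm(length(coords), 0, sigma), nrow(coords), 3L))
  }
  target <- if (is.null(norm)) raw else (raw - norm$mean) / norm$sd
  list(clean = coords, noisy = coords + raw, raw = raw, target = target)
}

#' Mean squared error between predicted and target displacements
#'
#' @param pred numeric N x 3 predicted displacements
#' @param target numeric N x 3 target displacements
#' @return mean over all N x 3 entries of the squared error
#' @export
denoiseLoss <- function(pred, target) {
  pred <- as.matrix(pred)
  target <- as.matrix(target)
  if (!all(dim(pred) == dim(target))) stop("shape mismatch")
  mean((pred - target)^2)
}

#' Pretrain an encoder by coordinate denoising
#'
#' Splits the conformer collection into training and validation sets, freezes
#' displacement-normalization constants on the training split (scalar mean
#' and standard deviation over all displacement components), and trains the
#' encoder and gated head by Adam on the denoising MSE.  The parameters of
#' the epoch with the lowest validation MSE are returned; with targets
#' standardized to unit variance, predicting zero gives MSE 1, so any
#' learning shows up as a validation MSE below 1.
#'
#' @param dataset list of conformers, each `list(coords = N x 3 matrix,
#'   z = integer atomic numbers)`, e.g. from [genToyConformers()]
#' @param encoderCfg an [encoderConfig()]
#' @param cfg a [denoiseConfig()]
#' @return list of class `denoiserFit`: `encoder` (a `gnnEncoder` at the best
#'   validation epoch), `head` (gated head parameters), `norm`, `log`
#'   (per-epoch train/validation MSE), `bestEpoch`
#' @export
trainDenoiser <- function(dataset, encoderCfg, cfg = denoiseConfig()) {
  if (length(dataset) == 0L) stop("dataset is empty")
  stopifnot(inherits(encoderCfg, "encoderConfig"),
            inherits(cfg, "denoiseConfig"))
  n <- length(dataset)
  if (cfg$valCount >= n) stop("valCount must be smaller than the dataset")

  val_idx <- local_seed(derive_seed(cfg$seed, 1L),
                        sort(sample.int(n, cfg$valCount)))
  train_idx <- setdiff(seq_len(n), val_idx)

  # normalization constants: frozen from one seeded draw on the training set
  ref <- local_seed(derive_seed(cfg$seed, 2L), {
    unlist(lapply(train_idx, function(i) {
      stats::rnorm(length(dataset[[i]]$coords), 0, cfg$sigma)
    }))
  })
  norm <- list(mean = mean(ref), sd = stats::sd(ref))
  if (!is.finite(norm$sd) || norm$sd == 0) norm$sd <- 1

  # fixed corrupted validation set so epochs are comparable
  val_samples <- lapply(seq_along(val_idx), function(k) {
    corrupt(dataset[[val_idx[k]]]$coords, cfg$sigma,
            seed = derive_seed(cfg$seed, 100L + k), norm = norm)
  })

  enc <- encoderInit(encoderCfg)
  head_par <- gatedHeadInit(encoderCfg$d, seed = derive_seed(cfg$seed, 3L))
  params <- c(enc$params, head_par)
  opt <- adam_init(params)

  fwd_loss <- function(params, batch_systems, targets, want_grad) {
    gt <- batch_graph_tensors(batch_systems, encoderCfg$cutoff,
                              encoderCfg$nRbf)
    tape <- ad_tape()
    bp <- if (want_grad) ad_bind_params(tape, params) else
      lapply(params, function(p) ad_const(tape, p))
    out <- encoder_forward(tape, bp, gt, encoderCfg)
    pred <- gated_head_forward(tape, bp, out$x, out$V)
    tgt <- do.call(rbind, targets)
    err <- ad_sub(tape, ad_cbind(tape, pred), ad_const(tape, tgt))
    loss <- ad_mean(tape, ad_square(tape, err))
    if (want_grad) {
      ad_backward(tape, loss)
      list(loss = loss$val[1L], grads = ad_collect_grads(bp))
    } else {
      list(loss = loss$val[1L])
    }
  }

  val_mse <- function(params) {
    sys <- lapply(seq_along(val_idx), function(k) {
      list(coords = val_samples[[k]]$noisy, z = dataset[[val_idx[k]]]$z)
    })
    tg <- lapply(val_samples, function(s) s$target)
    fwd_loss(params, sys, tg, want_grad = FALSE)$loss
  }

  log <- data.frame(epoch = integer(0), train_mse = numeric(0),
                    val_mse = numeric(0))
  best <- list(mse = Inf, params = params, epoch = 0L)
  for (ep in seq_len(cfg$epochs)) {
    ep_seed <- derive_seed(cfg$seed, 1000L + ep)
    order_idx <- local_seed(ep_seed, sample(train_idx))
    batches <- split(order_idx,
                     ceiling(seq_along(order_idx) / cfg$batchSize))
    tr_losses <- numeric(0)
    for (bi in seq_along(batches)) {
      ids <- batches[[bi]]
      samples <- lapply(seq_along(ids), function(k) {
        corrupt(dataset[[ids[k]]]$coords, cfg$sigma,
                seed = derive_seed(ep_seed, k), norm = norm)
      })
      sys <- lapply(seq_along(ids), function(k) {
        list(coords = samples[[k]]$noisy, z = dataset[[ids[k]]]$z)
      })
      res <- fwd_loss(params, sys,
                      lapply(samples, function(s) s$target), TRUE)
      if (!is.finite(res$loss)) {
        stop("denoising loss diverged (non-finite) at epoch ", ep,
             "; loss log so far: ",
             paste(round(tr_losses, 4), collapse = ", "))
      }
      st <- adam_step(opt, params, res$grads, lr = cfg$learningRate)
      params <- st$params
      opt <- st$state
      tr_losses <- c(tr_losses, res$loss)
    }
    vm <- val_mse(params)
    log <- rbind(log, data.frame(epoch = ep, train_mse = mean(tr_losses),
                                 val_mse = vm))
    if (vm < best$mse) best <- list(mse = vm, params = params, epoch = ep)
  }

  enc_best <- structure(
    list(config = encoderCfg,
         params = best$params[names(enc$params)]),
    class = "gnnEncoder")
  structure(list(encoder = enc_best,
                 head = best$params[names(head_par)],
                 norm = norm, log = log, bestEpoch = best$epoch),
            class = "denoiserFit")
}

#' @export
print.denoiserFit <- function(x, ...) {
  cat(sprintf(
    "Denoising pretraining: best validation MSE %.4f at epoch %d of %d\n",
    min(x$log$val_mse), x$bestEpoch, nrow(x$log)))
  invisible(x)
}
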