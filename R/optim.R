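# Adam optimizer over named lists of numeric arrays.

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim = dim(ad_as_matrix(p)))),
    v = lapply(params, function(p) array(0, dim = dim(ad_as_matrix(p)))),
    t = 0L
  )
}

# One Adam update.  `params` and `grads` are parallel named lists of matrices.
# Returns list(params = updated parameters, state = updated moments).
adam_step <- function(state, params, grads, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / bc1
    vhat <- state$v[[k]] / bc2
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Glorot-uniform weight initialization
init_dense <- function(n_in, n_out, rng_scale = 1) {
  lim <- rng_scale * sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_zeros <- function(n_in, n_out = NULL) {
  if (is.null(n_out)) matrix(0, 1L, n_in) else matrix(0, n_in, n_out)
}
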