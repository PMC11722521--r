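spib_toy_params <- function(seed = 9L) {
  cfg <- spibConfig(latentDim = 2L, beta = 0.05, initK = 4L, nPseudo = 3L,
                    hiddenDim = 8L, seed = seed)
  X <- local_seed(seed, matrix(rnorm(60), 20, 3))
  list(cfg = cfg, X = X, params = spib_init(cfg, 3L, X[1:3, , drop = FALSE]))
}

test_that("k-means initialization recovers separable blobs", {
  set.seed(40)
  centers <- matrix(c(0, 0, 8, 0, 4, 7), 3, 2, byrow = TRUE)
  truth <- rep(1:3, each = 60)
  X <- centers[truth, ] + matrix(rnorm(360, sd = 0.3), ncol = 2)
  lab <- initLabels(X, 3L, seed = 1L)
  expect_s4_class(lab, "StateLabels")
  expect_equal(populatedCount(lab), 3L)
  # every true blob maps to exactly one cluster
  tab <- table(labelVector(lab), truth)
  expect_equal(sum(apply(tab, 2L, max)), 180L)
  expect_identical(labelVector(initLabels(X, 3L, seed = 1L)),
                   labelVector(lab))
  expect_equal(populatedCount(initLabels(X, 1L)), 1L)
  expect_error(initLabels(X[1:2, ], 5L), "at least")
})

test_that("latent encoding is reparameterized and deterministic by seed", {
  tp <- spib_toy_params()
  x <- tp$X[1L, ]
  e1 <- encodeLatent(x, tp$params, seed = 3L)
  e2 <- encodeLatent(x, tp$params, seed = 3L)
  expect_equal(e1$z, e2$z)
  expect_equal(e1$z, e1$mean + exp(0.5 * e1$logvar) *
                 local_seed(3L, matrix(rnorm(2L), 1L)))
  draws <- t(vapply(1:3000, function(i) encodeLatent(x, tp$params,
                                                     seed = i)$z[1L, ],
                    numeric(2L)))
  sigma <- exp(0.5 * e1$logvar)
  expect_true(all(abs(colMeans(draws) - e1$mean) <
                    3 * sigma / sqrt(3000) + 1e-8))
})

test_that("decoder probabilities normalize; zero logits give uniform", {
  tp <- spib_toy_params()
  z <- matrix(rnorm(10), 5, 2)
  pr <- decodeState(z, tp$params)
  expect_equal(rowSums(pr), rep(1, 5), tolerance = 1e-9)
  expect_true(all(pr >= 0))
  p0 <- tp$params
  p0$D_W2[] <- 0
  p0$D_b2[] <- 0
  pu <- decodeState(z, p0)
  expect_equal(pu, matrix(0.25, 5, 4), tolerance = 1e-12)
  expect_equal(-sum(pu[1L, ] * log(pu[1L, ])), log(4), tolerance = 1e-12)
})

test_that("VampPrior is a normalized weight mixture of posteriors", {
  tp <- spib_toy_params()
  z <- matrix(rnorm(6), 3, 2)
  pa <- tp$params
  pa$logw[] <- log(2)
  pb <- tp$params
  pb$logw[] <- 0
  expect_equal(vampPriorDensity(z, pa), vampPriorDensity(z, pb))
  expect_true(all(vampPriorDensity(z, tp$params) > 0))
  # Monte Carlo normalization by importance sampling
  zs <- local_seed(1L, matrix(rnorm(2L * 50000L, sd = 3), ncol = 2L))
  w <- 1 / (dnorm(zs[, 1L], sd = 3) * dnorm(zs[, 2L], sd = 3))
  expect_equal(mean(vampPriorDensity(zs, tp$params) * w), 1,
               tolerance = 0.02)
  pz <- tp$params
  pz$logw[] <- -Inf
  expect_error(vampPriorDensity(z, pz), "zero")
})

test_that("SPIB loss gradients match finite differences", {
  tp <- spib_toy_params()
  y <- local_seed(2L, sample(1:4, 20, replace = TRUE))
  eps_mat <- local_seed(3L, matrix(rnorm(40), 20))
  lossv <- function(pl) {
    tape <- ad_tape()
    bp <- lapply(pl, function(p) ad_const(tape, p))
    spib_loss_fwd(tape, bp, ad_const(tape, tp$X), y, eps_mat, 0.05,
                  3L)$val[1L]
  }
  tape <- ad_tape()
  bp <- ad_bind_params(tape, tp$params)
  loss <- spib_loss_fwd(tape, bp, ad_const(tape, tp$X), y, eps_mat, 0.05,
                        3L)
  ad_backward(tape, loss)
  gr <- ad_collect_grads(bp)
  for (nm in c("E_Wlv", "D_W2", "U", "logw")) {
    f <- function(v) {
      p2 <- tp$params
      p2[[nm]] <- v
      lossv(p2)
    }
    expect_lt(max(abs(gr[[nm]] - num_grad(f, tp$params[[nm]], 1e-5))),
              1e-6)
  }
  expect_true(is.finite(spibLoss(tp$X, y, tp$params, beta = 0.05)))
})

test_that("label refinement is deterministic with lowest-index ties", {
  tp <- spib_toy_params()
  lab <- refineLabels(tp$X, tp$params, 4L)
  expect_s4_class(lab, "StateLabels")
  expect_lte(populatedCount(lab), 4L)
  expect_identical(labelVector(refineLabels(tp$X, tp$params, 4L)),
                   labelVector(lab))
  # constant decoder collapses to a single state (lowest index on ties)
  p0 <- tp$params
  p0$D_W2[] <- 0
  p0$D_b2[] <- 0
  lab0 <- refineLabels(tp$X, p0, 4L)
  expect_equal(populatedCount(lab0), 1L)
  expect_true(all(labelVector(lab0) == 1L))
})

test_that("SPIB training merges k-means states down to the metastable count", {
  P3 <- matrix(c(0.95, 0.03, 0.02,
                 0.03, 0.95, 0.02,
                 0.02, 0.02, 0.96), 3, 3, byrow = TRUE)
  spec <- markovChainSpec(P3)
  traj <- simulateMarkovChain(spec, 3000L, seed = 21L)
  centers <- matrix(c(0, 0, 4, 0, 2, 3.5), 3, 2, byrow = TRUE)
  feats <- centers[traj, ] +
    local_seed(22L, matrix(rnorm(2L * 3000L, sd = 0.35), ncol = 2L))
  sp <- temporalSplit(3000L, 0.5, 1L, seed = 4L)
  cfg <- spibConfig(latentDim = 2L, beta = 0.01, lag = 5L, initK = 8L,
                    nPseudo = 5L, batchSize = 500L, hiddenDim = 16L,
                    epochs = 6L, seed = 2L)
  fit <- trainSpib(feats, cfg, sp)
  expect_s3_class(fit, "spibFit")
  tr <- fit$populatedTrace
  expect_equal(tr$populated[1L], 8L)
  expect_lte(tr$populated[nrow(tr)], 4L)
  expect_gte(tr$populated[nrow(tr)], 2L)
  # trace trends downward
  expect_true(all(diff(tr$populated) <= 1L))
  expect_lt(utils::tail(fit$lossTrace, 1L), fit$lossTrace[1L])
})

test_that("beta = 0 training increases the label likelihood on frozen labels", {
  set.seed(43)
  truth <- rep(1:2, each = 100)
  X <- cbind(ifelse(truth == 1L, -2, 2) + rnorm(200, sd = 0.3),
             rnorm(200, sd = 0.3))
  cfg <- spibConfig(latentDim = 2L, beta = 0, lag = 1L, initK = 2L,
                    nPseudo = 2L, batchSize = 50L, hiddenDim = 8L,
                    epochs = 10L, learningRate = 3e-3,
                    refreshInterval = 10000L, seed = 3L)
  ord <- sample(200L)
  sp <- list(train = 1:100, val = 101:200, trainSegments = list(1:100))
  init <- stateLabels(truth, k = 2L)
  fit <- trainSpib(X[ord, ], cfg, sp, initialLabels = stateLabels(
    truth[ord], k = 2L))
  n <- length(fit$lossTrace)
  expect_lt(mean(utils::tail(fit$lossTrace, 3L)),
            mean(utils::head(fit$lossTrace, 3L)))
})
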