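test_that("lagged pair sampling respects bounds and boundaries", {
  sp <- sampleLaggedPairs(c(50L, 30L), tau = 5L, batch = 500L, seed = 1L)
  expect_true(all(sp$t1 == sp$t0 + 5L))
  expect_true(all(sp$t1[sp$traj == 1L] <= 50L))
  expect_true(all(sp$t1[sp$traj == 2L] <= 30L))
  expect_true(all(sp$g1 <= 80L))
  expect_setequal(unique(sp$traj), 1:2)
  expect_error(sampleLaggedPairs(c(10L, 4L), tau = 4L, batch = 10L),
               "shorter")
})

test_that("correlation matrices follow their definitions", {
  set.seed(2)
  A <- matrix(rnorm(40), 20, 2)
  B <- matrix(rnorm(40), 20, 2)
  tr <- correlationMatrices(A, B, center = FALSE)
  expect_equal(tr$C0t, crossprod(A, B) / 20)
  trc <- correlationMatrices(A, B, center = TRUE)
  Ac <- scale(A, scale = FALSE)
  expect_equal(trc$C00, crossprod(Ac) / 20, ignore_attr = TRUE)
  expect_error(correlationMatrices(A, B[1:10, ]), "matching")
})

test_that("inverse square root inverts and regularizes", {
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3)
  S <- crossprod(X) / 20
  W <- invSqrt(S)
  expect_equal(W %*% S %*% W, diag(3), tolerance = 1e-8)
  # rank-deficient input stays finite
  S2 <- S
  S2[3, ] <- S2[, 3] <- 0
  expect_true(all(is.finite(invSqrt(S2))))
  expect_error(invSqrt(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("VAMP-2 score matches the exact two-state oracle", {
  # exact stationary correlations of uncentered one-hot features:
  # C00 = Ctt = diag(pi), C0t = diag(pi) P
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  pi_ <- c(2, 1) / 3
  triple <- list(C00 = diag(pi_), C0t = diag(pi_) %*% P, Ctt = diag(pi_))
  expect_equal(vamp2Score(triple), 1.49, tolerance = 1e-9)
  # score is invariant to invertible linear feature transforms
  M <- matrix(c(2, 1, 0, 1), 2)
  triple2 <- list(C00 = t(M) %*% triple$C00 %*% M,
                  C0t = t(M) %*% triple$C0t %*% M,
                  Ctt = t(M) %*% triple$Ctt %*% M)
  expect_equal(vamp2Score(triple2), 1.49, tolerance = 1e-8)
})

test_that("analytic VAMP-2 gradients match finite differences", {
  set.seed(4)
  A <- matrix(rnorm(90), 30, 3)
  B <- matrix(0.6 * A + rnorm(90, sd = 0.5), 30, 3)
  for (ctr in c(TRUE, FALSE)) {
    r <- vamp2_score_grad(A, B, center = ctr)
    gA <- num_grad(function(v) vamp2_score_grad(v, B, center = ctr)$score,
                   A, 1e-5)
    gB <- num_grad(function(v) vamp2_score_grad(A, v, center = ctr)$score,
                   B, 1e-5)
    expect_lt(max(abs(r$gA - gA)), 1e-6)
    expect_lt(max(abs(r$gB - gB)), 1e-6)
  }
})

vamp_store <- function(TT = 400L, seed = 5L) {
  # tiny feature store whose scalar channels carry a 2-state signal
  ch <- reversibleChain(c(0.5, 0.5), c(1, 0.8))
  s <- simulateMarkovChain(ch, TT, seed = seed)
  sc <- array(0, c(TT, 2L, 3L))
  vec <- array(0, c(TT, 2L, 3L, 3L))
  sc[, 1L, ] <- outer(as.numeric(s == 1L), c(1, -1, 0.5))
  sc[, 2L, ] <- local_seed(seed + 1L, matrix(rnorm(TT * 3L, sd = 0.1), TT))
  list(store = new("FeatureStore", scalars = sc, vectors = vec,
                   metadata = list()), states = s)
}

test_that("VAMPnet training improves the score and stops by patience", {
  vs <- vamp_store()
  split <- temporalSplit(400L, 0.5, 1L, seed = 6L)
  cfg <- suppressWarnings(
    vampTrainConfig(outputDim = 2L, lag = 1L, batchSize = 150L,
                    valEvery = 5L, trainPatience = 40L, valPatience = 4L,
                    maxSteps = 120L, learningRate = 3e-3, seed = 7L))
  mcfg <- mixerConfig("submixer", depth = 1L, modelDim = 8L, seed = 8L)
  fit <- trainVampnet(vs$store, mcfg, cfg, split)
  expect_s3_class(fit, "vampnetFit")
  expect_true(fit$stopReason %in% c("valPatience", "trainPatience",
                                    "maxSteps"))
  # centered convention: the constant mode is removed, so the oracle for
  # this chain is the single non-trivial eigenvalue squared, 0.8^2 = 0.64
  expect_gt(fit$bestValScore, 0.4)
  expect_lt(vampScoreOnFrames(fit, vs$store, split$val), 0.8)
  expect_true(all(is.finite(fit$trace$train_score)))
  cv <- evaluateCVs(fit, vs$store)
  expect_equal(dim(cv), c(400L, 2L))
  # CV 1 should separate the two hidden states
  r <- abs(cor(cv[, 1L], as.numeric(vs$states == 1L)))
  expect_gt(r, 0.8)
  expect_output(print(fit), "VAMP-2")
})

test_that("small batches warn and lag validation errors", {
  expect_warning(vampTrainConfig(batchSize = 100L), "destabilize")
  vs <- vamp_store(60L)
  split <- temporalSplit(60L, 0.5, 1L, seed = 1L)
  cfg <- suppressWarnings(vampTrainConfig(lag = 40L, batchSize = 10L))
  mcfg <- mixerConfig("submixer", depth = 1L, modelDim = 4L)
  expect_error(trainVampnet(vs$store, mcfg, cfg, split), "lag")
})

test_that("canonical CV ordering puts the slowest mode first", {
  # two linear signals with different decorrelation rates; network outputs
  # them in reversed order via fixed linear head
  set.seed(9)
  TT <- 2000L
  slow <- as.numeric(arima.sim(list(ar = 0.97), TT))
  fast <- as.numeric(arima.sim(list(ar = 0.3), TT))
  chi <- cbind(fast, slow)   # raw order: fast first
  A <- chi[1:(TT - 5L), ]
  B <- chi[6:TT, ]
  tr <- correlationMatrices(A, B)
  W0 <- invSqrt(tr$C00)
  K <- W0 %*% tr$C0t %*% invSqrt(tr$Ctt)
  sv <- svd(K)
  proj <- scale(chi, center = colMeans(A), scale = FALSE) %*% W0 %*% sv$u
  # first canonical CV correlates with the slow signal
  expect_gt(abs(cor(proj[, 1L], slow)), abs(cor(proj[, 1L], fast)))
  expect_gt(abs(cor(proj[, 1L], slow)), 0.9)
})
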