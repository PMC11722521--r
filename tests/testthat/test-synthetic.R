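test_that("conformer templates are well separated and chain-like", {
  tm <- conformerTemplates(K = 3L, nResidues = 3L, atomsPerResidue = 4L,
                           jitter = 0.05, seed = 1L)
  expect_length(tm$templates, 3L)
  expect_equal(nAtoms(tm$system), 12L)
  for (a in 1:2) {
    for (b in (a + 1):3) {
      rmsd <- sqrt(mean((tm$templates[[a]] - tm$templates[[b]])^2))
      expect_gt(rmsd, 5 * 0.05)
    }
  }
  confs <- genToyConformers(7L, tm, seed = 2L)
  expect_length(confs, 7L)
  expect_equal(dim(confs[[1L]]$coords), c(12L, 3L))
})

test_that("Markov chain specs validate stochasticity and find pi", {
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  spec <- markovChainSpec(P)
  expect_equal(spec$pi, c(2, 1) / 3, tolerance = 1e-12)
  expect_equal(as.vector(spec$pi %*% P), spec$pi, tolerance = 1e-12)
  expect_equal(Re(spec$eigenvalues), c(1, 0.7), tolerance = 1e-12)
  expect_error(markovChainSpec(matrix(c(0.9, 0.2, 0.2, 0.8), 2)),
               "stochastic")
})

test_that("reversible chains hit the requested spectrum and detailed balance", {
  pi_ <- c(0.5, 0.3, 0.2)
  lam <- c(1, 0.85, 0.6)
  ch <- reversibleChain(pi_, lam)
  P <- ch$P
  expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-12)
  expect_true(all(P >= -1e-12))
  expect_equal(sort(Re(eigen(P, only.values = TRUE)$values),
                    decreasing = TRUE), lam, tolerance = 1e-10)
  expect_equal(pi_ * P, t(pi_ * P), tolerance = 1e-10)  # detailed balance
})

test_that("chain simulation matches its transition matrix empirically", {
  ch <- reversibleChain(rep(1 / 3, 3), c(1, 0.9, 0.7))
  s <- simulateMarkovChain(ch, 50000L, seed = 4L)
  expect_true(all(s %in% 1:3))
  Phat <- buildMSM(s, 1L)$transition
  expect_lt(max(abs(Phat - ch$P)), 0.03)
  expect_identical(simulateMarkovChain(ch, 100L, seed = 9L),
                   simulateMarkovChain(ch, 100L, seed = 9L))
})

test_that("Langevin simulation stays in its wells and flags divergence", {
  spec <- langevinSpec("double_well", nSteps = 3000L)
  xy <- simulateLangevin2d(spec, seed = 5L)
  expect_equal(dim(xy), c(3000L, 2L))
  expect_true(all(abs(xy) < 10))
  b <- basinAssign(spec, xy)
  expect_setequal(unique(b), 1:2)
  expect_equal(b, ifelse(xy[, 1L] < 0, 1L, 2L))
  spec3 <- langevinSpec("triple_well", nSteps = 500L)
  xy3 <- simulateLangevin2d(spec3, seed = 6L)
  expect_true(all(basinAssign(spec3, xy3) %in% 1:3))
  bad <- langevinSpec("double_well", nSteps = 100L, dt = 100)
  expect_error(simulateLangevin2d(bad, seed = 7L), "diverged")
})

test_that("state embedding produces distinct conformers with ground truth", {
  tm <- conformerTemplates(K = 3L, nResidues = 2L, atomsPerResidue = 3L,
                           seed = 8L)
  emb <- embedStatesAsConformers(c(1L, 3L, 1L), tm, seed = 9L)
  expect_length(emb$frames, 3L)
  expect_equal(emb$groundTruth$path, c(1L, 3L, 1L))
  d12 <- sqrt(mean((emb$frames[[1L]] - emb$frames[[2L]])^2))
  d13 <- sqrt(mean((emb$frames[[1L]] - emb$frames[[3L]])^2))
  expect_gt(d12, d13)
  embc <- embedStatesAsConformers(c(0, 0.5, 1), tm, seed = 10L)
  mid <- (tm$templates[[1L]] + tm$templates[[3L]]) / 2
  expect_lt(sqrt(mean((embc$frames[[2L]] - mid)^2)), 5 * tm$jitter)
  expect_error(embedStatesAsConformers(c(1L, 4L), tm), "templates")
  expect_error(embedStatesAsConformers(c(0.2, 1.4), tm), "0, 1")
})

test_that("temporal split reserves the second half for validation", {
  for (sd_ in 1:5) {
    sp <- temporalSplit(101L, 0.4, 3L, seed = sd_)
    expect_true(all(sp$train <= 50L))
    expect_equal(sp$val, 51:101)
    expect_length(sp$trainSegments, 3L)
    expect_equal(sort(unlist(sp$trainSegments)), sort(sp$train))
    for (seg in sp$trainSegments) {
      expect_equal(seg, seg[1L]:seg[length(seg)])  # contiguous
    }
    expect_equal(length(sp$train), 40L, tolerance = 4L)
  }
  expect_error(temporalSplit(100L, 0.7), "0.5")
  sp1 <- temporalSplit(100L, 0.5, 1L, seed = 1L)
  expect_equal(sp1$train, 1:50)
})
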