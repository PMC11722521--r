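enc_small <- function(seed = 7L) {
  encoderInit(encoderConfig(d = 8L, nLayers = 2L, cutoff = 5, nRbf = 8L,
                            seed = seed))
}

test_that("encoder scalars are invariant and vectors equivariant", {
  set.seed(10)
  enc <- enc_small()
  co <- matrix(rnorm(30), 10, 3) * 2
  z <- sample(c(1L, 6L, 7L, 8L), 10, replace = TRUE)
  nf1 <- encode(buildGraph(co, z, 5), enc)
  Q <- random_rotation()
  shift <- matrix(rnorm(3), 10, 3, byrow = TRUE)
  nf2 <- encode(buildGraph(co %*% t(Q) + shift, z, 5), enc)
  expect_lt(max(abs(nf1@scalars - nf2@scalars)), 1e-10)
  for (ch in 1:8) {
    expect_lt(max(abs(nf1@vectors[, , ch] %*% t(Q) - nf2@vectors[, , ch])),
              1e-10)
  }
})

test_that("encoder output permutes with the atoms", {
  set.seed(11)
  enc <- enc_small()
  co <- matrix(rnorm(24), 8, 3) * 2
  z <- rep(c(6L, 8L), 4)
  nf1 <- encode(buildGraph(co, z, 5), enc)
  perm <- sample(8)
  nf2 <- encode(buildGraph(co[perm, ], z[perm], 5), enc)
  expect_lt(max(abs(nf2@scalars - nf1@scalars[perm, ])), 1e-10)
})

test_that("isolated atoms get zero vector features", {
  enc <- enc_small()
  co <- rbind(c(0, 0, 0), c(100, 0, 0))
  nf <- encode(buildGraph(co, c(6L, 6L), 5), enc)
  expect_equal(max(abs(nf@vectors)), 0)
})

test_that("gated head is equivariant and vanishes with zero vectors", {
  set.seed(12)
  enc <- enc_small()
  co <- matrix(rnorm(30), 10, 3) * 2
  z <- rep(6L, 10)
  nf1 <- encode(buildGraph(co, z, 5), enc)
  Q <- random_rotation()
  nf2 <- encode(buildGraph(co %*% t(Q), z, 5), enc)
  hp <- gatedHeadInit(8L, seed = 2L)
  o1 <- gatedEquivariantHead(nf1, hp)
  o2 <- gatedEquivariantHead(nf2, hp)
  expect_lt(max(abs(o1 %*% t(Q) - o2)), 1e-10)
  nf0 <- new("NodeFeatures", scalars = nf1@scalars,
             vectors = array(0, dim(nf1@vectors)))
  expect_equal(max(abs(gatedEquivariantHead(nf0, hp))), 0)
})

test_that("gated head is linear in vectors at fixed gate values", {
  # gates depend only on scalars when the gate MLP ignores the norm inputs,
  # making the head exactly linear in the vector channels
  set.seed(13)
  enc <- enc_small()
  co <- matrix(rnorm(18), 6, 3) * 2
  nf <- encode(buildGraph(co, rep(7L, 6), 5), enc)
  hp <- gatedHeadInit(8L, seed = 3L)
  hp$H_M1[9:16, ] <- 0  # rows fed by the vector norms
  nf2 <- new("NodeFeatures", scalars = nf@scalars,
             vectors = 2 * nf@vectors)
  expect_equal(gatedEquivariantHead(nf2, hp),
               2 * gatedEquivariantHead(nf, hp), tolerance = 1e-10)
})

test_that("checkpoints round-trip and refuse mismatched shapes", {
  enc <- enc_small()
  p <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(enc, p)
  enc2 <- loadCheckpoint(p)
  expect_equal(enc2$params, enc$params)
  expect_equal(enc2$config$d, 8L)
  expect_identical(encoder_hash(enc2), encoder_hash(enc))
  obj <- readRDS(p)
  obj$config$d <- 16L
  saveRDS(obj, p)
  expect_error(loadCheckpoint(p, expectConfig = enc$config),
               "mismatch")
})
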