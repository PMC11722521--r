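rand_tokens <- function(M = 4L, d = 5L, seed = 1L) {
  local_seed(seed, new("TokenArray",
                       scalars = matrix(rnorm(M * d), M, d),
                       vectors = array(rnorm(M * 3L * d), c(M, 3L, d))))
}

test_that("mixer configuration validates its arguments", {
  expect_s3_class(mixerConfig("pool"), "mixerConfig")
  expect_error(mixerConfig("subformer", modelDim = 9L, heads = 2L),
               "divisible")
  expect_error(mixerConfig("nope"), "arg")
})

test_that("GVP enrichment is invariant under rigid rotation", {
  set.seed(30)
  tok <- rand_tokens()
  par <- gvpInit(5L, seed = 2L)
  e1 <- gvpEnrich(tok, par)
  Q <- random_rotation()
  vec2 <- tok@vectors
  for (ch in 1:5) vec2[, , ch] <- tok@vectors[, , ch] %*% t(Q)
  e2 <- gvpEnrich(new("TokenArray", scalars = tok@scalars, vectors = vec2),
                  par)
  expect_lt(max(abs(e1@scalars - e2@scalars)), 1e-10)
  expect_error(gvpEnrich(rand_tokens(d = 3L), par), "width")
})

test_that("global token is invariant under rigid motion of the references", {
  set.seed(31)
  ca <- matrix(rnorm(15), 5, 3)
  par <- globalTokenInit(5L, 8L, seed = 3L)
  g1 <- makeGlobalToken(ca, par)
  Q <- random_rotation()
  g2 <- makeGlobalToken(ca %*% t(Q) + matrix(c(1, 2, 3), 5, 3, TRUE), par)
  expect_equal(g1, g2, tolerance = 1e-10)
  expect_length(g1, 8L)
  expect_error(globalTokenInit(1L, 8L), "two tokens")
})

test_that("every mixer kind produces correct shapes and gradients", {
  set.seed(32)
  B <- 3L; M <- 4L; dIn <- 5L
  Xs <- matrix(rnorm(B * M * dIn), B * M, dIn)
  Xv <- lapply(1:3, function(i) matrix(rnorm(B * M * dIn), B * M, dIn))
  gd <- matrix(rnorm(B * 6L), B)
  for (kind in c("pool", "submixer", "subformer", "subformer_gvp")) {
    cfg <- mixerConfig(kind, depth = 1L, modelDim = 8L, heads = 2L,
                       outputDim = 2L, seed = 5L)
    useG <- grepl("subformer", kind)
    params <- mixer_init(cfg, M, dIn,
                         nGlobalDist = if (useG) 6L else NULL)
    run <- function(pl, grad = FALSE) {
      tape <- ad_tape()
      bp <- if (grad) ad_bind_params(tape, pl) else
        lapply(pl, function(p) ad_const(tape, p))
      out <- mixer_forward(tape, bp, cfg, M, ad_const(tape, Xs),
                           if (grepl("gvp", kind))
                             lapply(Xv, function(v) ad_const(tape, v)),
                           if (useG) ad_const(tape, gd))
      list(out = out, tape = tape, bp = bp)
    }
    r <- run(params, grad = TRUE)
    expect_equal(dim(r$out$feat$val), c(B, 2L))
    loss <- ad_sum(r$tape, ad_square(r$tape, r$out$feat))
    ad_backward(r$tape, loss)
    gr <- ad_collect_grads(r$bp)
    nm <- switch(kind, pool = "W_emb", submixer = "X1_Tok1",
                 subformer = "T1_Wq", subformer_gvp = "G_V1")
    f <- function(v) {
      p2 <- params
      p2[[nm]] <- v
      sum(run(p2)$out$feat$val^2)
    }
    expect_lt(max(abs(gr[[nm]] - num_grad(f, params[[nm]], 1e-5))), 1e-5)
  }
})

test_that("subformer attention maps are (M+1) x (M+1) and row-stochastic", {
  set.seed(33)
  B <- 4L; M <- 5L; dIn <- 6L
  cfg <- mixerConfig("subformer", depth = 2L, modelDim = 8L, heads = 2L,
                     outputDim = 2L, seed = 6L)
  params <- mixer_init(cfg, M, dIn)
  tape <- ad_tape()
  bp <- lapply(params, function(p) ad_const(tape, p))
  Xs <- ad_const(tape, matrix(rnorm(B * M * dIn), B * M, dIn))
  out <- mixer_forward(tape, bp, cfg, M, Xs, want_attention = TRUE)
  expect_length(out$attn, 2L)
  for (l in 1:2) {
    expect_equal(dim(out$attn[[l]]), c(M + 1L, M + 1L, B))
    rs <- apply(out$attn[[l]], c(1L, 3L), sum)
    expect_lt(max(abs(rs - 1)), 1e-9)
    expect_true(all(out$attn[[l]] >= 0))
  }
})

test_that("mixer task outputs are invariant under rigid motion end to end", {
  # full pipeline: coordinates -> encoder -> tokens -> mixer output
  set.seed(34)
  enc <- encoderInit(encoderConfig(d = 6L, nLayers = 1L, cutoff = 5,
                                   nRbf = 4L, seed = 7L))
  co <- matrix(rnorm(24), 8, 3) * 2
  z <- rep(c(6L, 7L), 4)
  part <- list(1:4, 5:8)
  cfg <- mixerConfig("submixer_gvp", depth = 1L, modelDim = 8L,
                     outputDim = 2L, seed = 8L)
  params <- mixer_init(cfg, 2L, 6L)
  outOf <- function(coords) {
    tok <- coarseGrain(encode(buildGraph(coords, z, 5), enc), part)
    tape <- ad_tape()
    bp <- lapply(params, function(p) ad_const(tape, p))
    Xv <- lapply(1:3, function(cc)
      ad_const(tape, vec_slice(tok@vectors, cc)))
    mixer_forward(tape, bp, cfg, 2L, ad_const(tape, tok@scalars),
                  Xv)$feat$val
  }
  Q <- random_rotation()
  expect_lt(max(abs(outOf(co) - outOf(co %*% t(Q) + 5))), 1e-8)
})

test_that("outputHead applies the stored MLP", {
  par <- list(Wh = diag(2), bh = matrix(0, 1, 2),
              Wout = matrix(c(1, 0), 2, 1), bout = matrix(1, 1, 1))
  x <- matrix(c(2, -1), 1)
  silu <- function(v) v / (1 + exp(-v))
  expect_equal(outputHead(x, par)[1, 1], silu(2) + 1, tolerance = 1e-12)
  expect_error(outputHead(matrix(0, 1, 3), par), "width")
})
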