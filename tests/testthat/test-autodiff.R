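test_that("composite expression gradients match finite differences", {
  set.seed(1)
  X <- matrix(rnorm(12), 4, 3)
  W <- matrix(rnorm(6), 3, 2)
  b <- matrix(rnorm(2), 1, 2)
  f <- function(Wv) {
    tape <- ad_tape()
    h <- ad_silu(tape, ad_dense(tape, ad_const(tape, X),
                                ad_param(tape, Wv), ad_param(tape, b)))
    out <- ad_mean(tape, ad_square(tape, ad_softmax_rows(tape, h)))
    out$val[1L]
  }
  tape <- ad_tape()
  Wn <- ad_param(tape, W)
  bn <- ad_param(tape, b)
  h <- ad_silu(tape, ad_dense(tape, ad_const(tape, X), Wn, bn))
  out <- ad_mean(tape, ad_square(tape, ad_softmax_rows(tape, h)))
  ad_backward(tape, out)
  expect_lt(max(abs(Wn$grad - num_grad(f, W))), 1e-7)
})

test_that("layer normalization backward is exact", {
  set.seed(2)
  X <- matrix(rnorm(12), 4, 3)
  g <- matrix(runif(3, 0.5, 1.5), 1, 3)
  be <- matrix(rnorm(3), 1, 3)
  f <- function(Xv) {
    tape <- ad_tape()
    out <- ad_mean(tape, ad_square(tape, ad_layernorm(
      tape, ad_param(tape, Xv), ad_param(tape, g), ad_param(tape, be))))
    out$val[1L]
  }
  tape <- ad_tape()
  a <- ad_param(tape, X)
  out <- ad_mean(tape, ad_square(tape, ad_layernorm(
    tape, a, ad_param(tape, g), ad_param(tape, be))))
  ad_backward(tape, out)
  expect_lt(max(abs(a$grad - num_grad(f, X))), 1e-7)
})

test_that("block token mixing matches a naive per-sample loop", {
  set.seed(3)
  B <- 3L; M <- 4L; D <- 5L
  Xb <- matrix(rnorm(B * M * D), B * M, D)
  Wm <- matrix(rnorm(2L * M), 2L, M)
  tape <- ad_tape()
  xn <- ad_param(tape, Xb)
  wn <- ad_param(tape, Wm)
  bm <- ad_blockmix(tape, xn, wn, M)
  naive <- matrix(0, B * 2L, D)
  for (b in seq_len(B)) {
    for (a in 1:2) {
      naive[(b - 1L) * 2L + a, ] <-
        colSums(Wm[a, ] * Xb[(b - 1L) * M + 1:M, , drop = FALSE])
    }
  }
  expect_equal(bm$val, naive, tolerance = 1e-12)
  out <- ad_sum(tape, ad_square(tape, bm))
  ad_backward(tape, out)
  f <- function(Wv) {
    tape <- ad_tape()
    out <- ad_sum(tape, ad_square(tape, ad_blockmix(
      tape, ad_const(tape, Xb), ad_param(tape, Wv), M)))
    out$val[1L]
  }
  expect_lt(max(abs(wn$grad - num_grad(f, Wm))), 1e-6)
})

test_that("row gather, scatter-add and pick backprop correctly", {
  set.seed(4)
  X <- matrix(rnorm(15), 5, 3)
  idx <- c(2L, 2L, 5L, 1L)
  f <- function(Xv) {
    tape <- ad_tape()
    g <- ad_rows(tape, ad_param(tape, Xv), idx)
    p <- ad_pick(tape, g, c(1L, 3L, 2L, 2L))
    out <- ad_sum(tape, ad_square(tape, p))
    out$val[1L]
  }
  tape <- ad_tape()
  a <- ad_param(tape, X)
  g <- ad_rows(tape, a, idx)
  p <- ad_pick(tape, g, c(1L, 3L, 2L, 2L))
  out <- ad_sum(tape, ad_square(tape, p))
  ad_backward(tape, out)
  expect_lt(max(abs(a$grad - num_grad(f, X))), 1e-7)
})

test_that("log-sum-exp and log-softmax are numerically stable and exact", {
  X <- matrix(c(1000, 1001, -1000, 3), 2, 2)
  tape <- ad_tape()
  l <- ad_logsumexp_rows(tape, ad_const(tape, X))
  expect_true(all(is.finite(l$val)))
  expect_equal(l$val[1L], 1000 + log(1 + exp(-2000)), tolerance = 1e-12)
  ls <- ad_log_softmax_rows(tape, ad_const(tape, X))
  expect_equal(rowSums(exp(ls$val)), c(1, 1), tolerance = 1e-12)
})

test_that("Adam reduces a quadratic objective", {
  params <- list(w = matrix(c(5, -3), 1L))
  opt <- adam_init(params)
  for (i in 1:200) {
    g <- list(w = 2 * params$w)
    st <- adam_step(opt, params, g, lr = 0.1)
    params <- st$params
    opt <- st$state
  }
  expect_lt(sum(params$w^2), 1e-3)
})
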