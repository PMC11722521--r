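test_that("PMF differences are exact count log-ratios", {
  x <- c(rep(0.25, 100L), rep(0.75, 37L))
  p <- pmf2d(cbind(x, 0.5), bins = 2L)
  expect_equal(max(p$F, na.rm = TRUE), log(100 / 37), tolerance = 1e-12)
  expect_equal(min(p$F, na.rm = TRUE), 0)
})

test_that("a uniform sample gives a nearly flat PMF with kT units", {
  u <- local_seed(50L, matrix(runif(2e5), ncol = 2L))
  p <- pmf2d(u, bins = 10L)
  expect_lt(max(p$F, na.rm = TRUE), 0.2)
  expect_equal(p$units, "kT")
})

test_that("empty bins are masked and degenerate grids warn", {
  p <- pmf2d(cbind(c(0, 1), c(0, 1)), bins = 3L)
  expect_true(anyNA(p$F))
  expect_true(all(is.finite(p$F[!is.na(p$F)])))
  expect_warning(pmf2d(matrix(0.5, 10L, 2L), bins = 2L), "single bin")
  expect_error(pmf2d(cbind(1, 1), bins = 2L, units = "kcal_per_mol"),
               "temperature")
  pk <- pmf2d(cbind(c(rep(0, 10), rep(1, 5)), 0), bins = 2L,
              units = "kcal_per_mol", temperature = 300)
  expect_equal(max(pk$F, na.rm = TRUE), 0.0019872041 * 300 * log(2),
               tolerance = 1e-9)
})

test_that("native contacts follow the 4.5 A / >= 3 separation rule", {
  co <- rbind(c(0, 0, 0), c(4.4, 0, 0), c(100, 0, 0), c(0, 4.6, 0))
  sys <- molSystem(c("C", "C", "C", "C"), co,
                   resid = c(1L, 4L, 3L, 8L))
  cd <- contactDefinition(sys)
  # only the 4.4 A pair at separation 3 qualifies; 4.6 A and |i-j|=2 do not
  expect_equal(cd$pairs, matrix(c(1L, 4L), 1L))
  expect_error(contactDefinition(molSystem(c("C", "C"),
    rbind(c(0, 0, 0), c(2, 0, 0)), resid = c(1L, 3L))), "no native")
  expect_error(contactDefinition(molSystem(c("H", "H"),
    rbind(c(0, 0, 0), c(2, 0, 0)), resid = c(1L, 5L))), "heavy")
})

test_that("Q is 1 at the reference and averages over the window", {
  co <- rbind(c(0, 0, 0), c(4.4, 0, 0), c(100, 0, 0), c(0, 4.6, 0))
  sys <- molSystem(rep("C", 4L), co, resid = c(1L, 4L, 3L, 8L))
  cd <- contactDefinition(sys)
  q <- fractionNativeContacts(array(co, c(1L, 4L, 3L)), cd)
  expect_equal(q$Q, 1)
  co2 <- co
  co2[2L, 1L] <- 10
  q2 <- fractionNativeContacts(list(co, co2, co), cd, window = 3L)
  expect_equal(q2$Q, c(1, 0, 1))
  expect_equal(q2$Qbar, c(0.5, 2 / 3, 0.5))
  expect_true(all(q2$Q >= 0 & q2$Q <= 1))
  expect_equal(framesPerWindow(1, 0.2), 5L)
})

test_that("CV surfaces are binned means with identity recovery", {
  set.seed(51)
  x <- runif(2000L)
  cs <- cvSurface(rep(2.5, 2000L), x, runif(2000L), bins = 4L)
  expect_equal(unique(cs$mean[!is.na(cs$mean)]), 2.5)
  cs2 <- cvSurface(x, x, rep(0.5, 2000L), bins = 5L)
  pop <- which(!is.na(cs2$mean), arr.ind = TRUE)
  err <- abs(cs2$mean[pop] - cs2$xMid[pop[, 1L]])
  expect_true(all(err < (max(x) - min(x)) / 5))
  expect_error(cvSurface(1:3, 1:2, 1:3), "equal lengths")
})

test_that("attention summaries recompose exactly and stay stochastic", {
  set.seed(52)
  S <- 4L
  TT <- 30L
  A <- array(abs(rnorm(S * S * TT)), c(S, S, TT))
  for (t in seq_len(TT)) A[, , t] <- A[, , t] / rowSums(A[, , t])
  lab <- sample(1:3, TT, replace = TRUE)
  rp <- attentionReport(list(A, A), lab, tokenNames = c("g", "r1", "r2",
                                                        "r3"))
  L <- rp$layers[[1L]]
  recomp <- Reduce(`+`, Map(`*`, L$perState,
                            as.list(L$stateCounts))) / sum(L$stateCounts)
  expect_lt(max(abs(recomp - L$global)), 1e-9)
  expect_equal(rowSums(L$global), rep(1, S), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(L$rowActivity, rowSums(L$global))
  expect_equal(L$colActivity, colSums(L$global))
  expect_equal(rownames(L$global), c("g", "r1", "r2", "r3"))
  # identical frames: average equals the single map
  A1 <- array(rep(A[, , 1L], 3L), c(S, S, 3L))
  expect_equal(attentionReport(list(A1))$layers[[1L]]$global, A[, , 1L],
               ignore_attr = TRUE)
  expect_error(attentionReport(list(A), lab[1:5]), "match")
  expect_output(print(rp), "2 layer")
})
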