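# central finite-difference gradient of a scalar function of a matrix
num_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim = dim(x))
  for (i in seq_along(x)) {
    xp <- x
    xp[i] <- xp[i] + eps
    xm <- x
    xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

random_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3L, 3L)))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}
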