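# Synthetic benchmark systems with known ground truth: toy conformer
# ensembles for denoising pretraining, hidden Markov chains and 2-D Langevin
# dynamics embedded as molecular trajectories, and the temporal
# train/validation split.  Every generator is seed-reproducible.

## ---- toy conformers --------------------------------------------------------

#' Build a set of chain-molecule conformer templates
#'
#' K template geometries of a small chain molecule with shared bond topology
#' (consecutive atoms bonded at ~1.5 Angstrom), grouped into residues so the
#' residue token partition is meaningful.  Templates are random extended
#' walks, re-drawn until all pairwise RMSDs exceed `5 * jitter` so that
#' states embedded on the templates stay distinguishable.
#'
#' @param K number of templates
#' @param nResidues residues per molecule
#' @param atomsPerResidue atoms per residue
#' @param jitter Cartesian jitter scale (Angstrom) that downstream
#'   perturbations will use
#' @param seed integer seed
#' @return list of class `conformerTemplateSet`: `templates` (list of N x 3
#'   matrices), `z`, `bonds`, `system` (a [MolSystem]), `jitter`
#' @export
conformerTemplates <- function(K = 3L, nResidues = 4L, atomsPerResidue = 4L,
                               jitter = 0.05, seed = 1L) {
  n <- nResidues * atomsPerResidue
  elements <- rep(c("C", "C", "N", "O"), length.out = atomsPerResidue)
  elements <- rep(elements, nResidues)
  resid <- rep(seq_len(nResidues), each = atomsPerResidue)
  make_chain <- function() {
    coords <- matrix(0, n, 3L)
    dir <- c(1, 0, 0)
    for (i in 2:n) {
      dir <- dir + 0.9 * stats::rnorm(3L)
      dir <- dir / sqrt(sum(dir^2))
      coords[i, ] <- coords[i - 1L, ] + 1.5 * dir
    }
    coords
  }
  templates <- local_seed(seed, {
    tpl <- list()
    tries <- 0L
    while (length(tpl) < K && tries < 200L) {
      tries <- tries + 1L
      cand <- make_chain()
      ok <- all(vapply(tpl, function(t0) {
        sqrt(mean((t0 - cand)^2)) > 5 * jitter
      }, logical(1)))
      if (ok) tpl[[length(tpl) + 1L]] <- cand
    }
    if (length(tpl) < K) stop("could not build well-separated templates")
    tpl
  })
  bonds <- cbind(seq_len(n - 1L), 2:n)
  system <- molSystem(elements, templates[[1L]], resid = resid,
                      resname = sprintf("R%02d", resid))
  structure(list(templates = templates, z = elementToZ(elements),
                 bonds = bonds, system = system, jitter = jitter,
                 nResidues = as.integer(nResidues)),
            class = "conformerTemplateSet")
}

#' Generate a toy conformer dataset
#'
#' Each conformer is a randomly chosen template plus small Cartesian jitter
#' (scale `spec$jitter`), which preserves bonded distances to within a few
#' percent of the template values.
#'
#' @param n number of conformers
#' @param spec a [conformerTemplates()] set
#' @param seed integer seed
#' @return list of `n` conformers, each `list(coords, z, template)`
#' @export
genToyConformers <- function(n, spec, seed = 1L) {
  stopifnot(n >= 1, inherits(spec, "conformerTemplateSet"))
  local_seed(seed, {
    lapply(seq_len(n), function(i) {
      k <- sample.int(length(spec$templates), 1L)
      co <- spec$templates[[k]] +
        matrix(stats::rnorm(length(spec$templates[[k]]), 0, spec$jitter),
               ncol = 3L)
      list(coords = co, z = spec$z, template = k)
    })
  })
}

## ---- hidden Markov chains --------------------------------------------------

#' Markov chain specification
#'
#' @param P row-stochastic K x K transition matrix
#' @return list of class `markovChainSpec` with `P`, stationary distribution
#'   `pi`, and transfer-operator `eigenvalues` (eigenvalues of P, sorted by
#'   decreasing modulus)
#' @export
markovChainSpec <- function(P) {
  P <- as.matrix(P)
  if (any(P < -1e-12) || any(abs(rowSums(P) - 1) > 1e-8)) {
    stop("P must be row-stochastic")
  }
  ev <- eigen(t(P))
  i1 <- which.min(abs(ev$values - 1))
  pi_ <- Re(ev$vectors[, i1])
  pi_ <- pi_ / sum(pi_)
  lam <- eigen(P, only.values = TRUE)$values
  lam <- lam[order(-abs(lam))]
  structure(list(P = P, pi = pi_, eigenvalues = lam),
            class = "markovChainSpec")
}

#' Construct a reversible chain with prescribed spectrum
#'
#' Builds P = Pi^{-1/2} U diag(lambda) U' Pi^{1/2} where U is an orthonormal
#' basis whose first column is sqrt(pi).  The result is reversible with
#' stationary distribution `pi` and transfer-operator eigenvalues `lambda`;
#' construction fails if the requested spectrum yields negative transition
#' probabilities.
#'
#' @param pi stationary distribution (positive, sums to 1)
#' @param lambda eigenvalues, first entry must be 1
#' @return a [markovChainSpec()]
#' @examples
#' # the 3-state benchmark chain with eigenvalues 1, 0.9, 0.7
#' reversibleChain(rep(1 / 3, 3), c(1, 0.9, 0.7))$P
#' @export
reversibleChain <- function(pi, lambda) {
  pi <- pi / sum(pi)
  K <- length(pi)
  stopifnot(length(lambda) == K, abs(lambda[1] - 1) < 1e-12)
  U <- matrix(0, K, K)
  U[, 1L] <- sqrt(pi)
  basis <- diag(K)
  j <- 2L
  for (cand in seq_len(K)) {
    if (j > K) break
    v <- basis[, cand]
    for (m in seq_len(j - 1L)) v <- v - sum(v * U[, m]) * U[, m]
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) {
      U[, j] <- v / nv
      j <- j + 1L
    }
  }
  S <- U %*% diag(lambda) %*% t(U)
  P <- diag(1 / sqrt(pi)) %*% S %*% diag(sqrt(pi))
  P[abs(P) < 1e-14] <- 0
  if (any(P < 0)) {
    stop("requested spectrum produces negative transition probabilities")
  }
  markovChainSpec(P)
}

#' Simulate a Markov chain
#'
#' @param spec a [markovChainSpec()]
#' @param T number of steps
#' @param seed integer seed
#' @param start `"stationary"` (default) or an initial state index
#' @return integer state sequence of length T (1-based states)
#' @export
simulateMarkovChain <- function(spec, T, seed = 1L, start = "stationary") {
  stopifnot(inherits(spec, "markovChainSpec"), T >= 1)
  K <- nrow(spec$P)
  local_seed(seed, {
    s <- integer(T)
    s[1L] <- if (identical(start, "stationary")) {
      sample.int(K, 1L, prob = spec$pi)
    } else as.integer(start)
    if (T > 1L) {
      u <- stats::runif(T - 1L)
      cum <- t(apply(spec$P, 1L, cumsum))
      for (t in 2:T) {
        s[t] <- which(u[t - 1L] <= cum[s[t - 1L], ])[1L]
      }
    }
    s
  })
}

## ---- 2-D Langevin dynamics -------------------------------------------------

#' Langevin system specification
#'
#' Overdamped dynamics on a named 2-D potential.  `double_well` has two
#' basins at x = -1 and x = +1 (V = a(x^2-1)^2 + tilt*x + b*y^2/2) and is the
#' benchmark for slow-CV recovery; `triple_well` is the standard
#' three-basin Gaussian-well surface used for metastable-state counting.
#'
#' @param potential `"double_well"` or `"triple_well"`
#' @param kT thermal energy
#' @param dt integration time step
#' @param nSteps number of steps
#' @param friction friction coefficient (gamma)
#' @param params optional potential parameters (double well: `a`, `b`,
#'   `tilt`)
#' @return list of class `langevinSpec`
#' @export
langevinSpec <- function(potential = c("double_well", "triple_well"),
                         kT = 0.35, dt = 0.01, nSteps = 10000L,
                         friction = 1.0, params = list()) {
  potential <- match.arg(potential)
  p <- utils::modifyList(list(a = 1, b = 2, tilt = 0), params)
  spec <- structure(list(potential = potential, kT = kT, dt = dt,
                         nSteps = as.integer(nSteps), friction = friction,
                         params = p),
                    class = "langevinSpec")
  # a zero-noise step from a generic point must not diverge
  x0 <- c(0.5, 0.5)
  g <- langevin_grad(spec, x0)
  if (any(!is.finite(x0 - g * dt / friction))) stop("dt too large")
  spec
}

langevin_potential <- function(spec, xy) {
  x <- xy[, 1L]
  y <- xy[, 2L]
  if (spec$potential == "double_well") {
    p <- spec$params
    p$a * (x^2 - 1)^2 + p$tilt * x + p$b * y^2 / 2
  } else {
    3 * exp(-x^2 - (y - 1 / 3)^2) - 3 * exp(-x^2 - (y - 5 / 3)^2) -
      5 * exp(-(x - 1)^2 - y^2) - 5 * exp(-(x + 1)^2 - y^2) +
      0.2 * x^4 + 0.2 * (y - 1 / 3)^4
  }
}

langevin_grad <- function(spec, xy) {
  xy <- matrix(xy, ncol = 2L)
  x <- xy[, 1L]
  y <- xy[, 2L]
  if (spec$potential == "double_well") {
    p <- spec$params
    cbind(4 * p$a * x * (x^2 - 1) + p$tilt, p$b * y)
  } else {
    e1 <- exp(-x^2 - (y - 1 / 3)^2)
    e2 <- exp(-x^2 - (y - 5 / 3)^2)
    e3 <- exp(-(x - 1)^2 - y^2)
    e4 <- exp(-(x + 1)^2 - y^2)
    gx <- 3 * e1 * (-2 * x) - 3 * e2 * (-2 * x) -
      5 * e3 * (-2 * (x - 1)) - 5 * e4 * (-2 * (x + 1)) + 0.8 * x^3
    gy <- 3 * e1 * (-2 * (y - 1 / 3)) - 3 * e2 * (-2 * (y - 5 / 3)) -
      5 * e3 * (-2 * y) - 5 * e4 * (-2 * y) + 0.8 * (y - 1 / 3)^3
    cbind(gx, gy)
  }
}

#' Simulate overdamped 2-D Langevin dynamics
#'
#' Euler-Maruyama integration of dx = -grad V / gamma dt +
#' sqrt(2 kT dt / gamma) xi.
#'
#' @param spec a [langevinSpec()]
#' @param seed integer seed
#' @param x0 initial position (default a basin minimum)
#' @return numeric nSteps x 2 trajectory
#' @export
simulateLangevin2d <- function(spec, seed = 1L, x0 = NULL) {
  stopifnot(inherits(spec, "langevinSpec"))
  if (is.null(x0)) {
    x0 <- if (spec$potential == "double_well") c(-1, 0) else c(-1, 0)
  }
  T <- spec$nSteps
  dt <- spec$dt
  amp <- sqrt(2 * spec$kT * dt / spec$friction)
  local_seed(seed, {
    xi <- matrix(stats::rnorm(2L * T), T, 2L)
    out <- matrix(0, T, 2L)
    x <- x0
    for (t in seq_len(T)) {
      x <- x - langevin_grad(spec, x)[1L, ] * dt / spec$friction +
        amp * xi[t, ]
      if (any(abs(x) > 50)) {
        stop("Langevin integration diverged at step ", t)
      }
      out[t, ] <- x
    }
    out
  })
}

#' Assign Langevin positions to metastable basins
#'
#' Nearest-center rule: double well uses the sign of x (centers at x = -1,
#' +1); the triple well uses the three basin minima.
#'
#' @param spec a [langevinSpec()]
#' @param xy T x 2 positions
#' @return integer basin labels (1-based)
#' @export
basinAssign <- function(spec, xy) {
  xy <- matrix(xy, ncol = 2L)
  if (spec$potential == "double_well") {
    ifelse(xy[, 1L] < 0, 1L, 2L)
  } else {
    centers <- rbind(c(-1, 0), c(1, 0), c(0, 1.5))
    d2 <- sapply(seq_len(nrow(centers)), function(k) {
      (xy[, 1L] - centers[k, 1L])^2 + (xy[, 2L] - centers[k, 2L])^2
    })
    max.col(-d2)
  }
}

## ---- embedding dynamics as molecular trajectories --------------------------

#' Embed a latent path as a molecular coordinate trajectory
#'
#' Discrete paths (integer states) map each frame to the state's template
#' geometry; continuous paths (values in [0, 1]) interpolate linearly
#' between the first and last template (anchors).  Gaussian jitter of scale
#' `jitter` is added to every frame.  The ground-truth record travels with
#' the trajectory.
#'
#' @param path integer state sequence, or numeric vector in [0, 1]
#' @param templates a [conformerTemplates()] set; for a discrete path the
#'   template count must equal the number of states
#' @param jitter Cartesian noise scale (Angstrom); default `templates$jitter`
#' @param seed integer seed
#' @return list: `frames` (list of N x 3 matrices), `system` ([MolSystem]),
#'   `groundTruth` (list with `path`, `kind`)
#' @export
embedStatesAsConformers <- function(path, templates, jitter = NULL,
                                    seed = 1L) {
  stopifnot(inherits(templates, "conformerTemplateSet"))
  if (is.null(jitter)) jitter <- templates$jitter
  K <- length(templates$templates)
  discrete <- is.integer(path) || all(path == round(path) & path >= 1)
  if (discrete) {
    path <- as.integer(path)
    if (max(path) > K) {
      stop("path has ", max(path), " states but only ", K, " templates")
    }
  } else {
    if (any(path < -1e-9 | path > 1 + 1e-9)) {
      stop("continuous path values must lie in [0, 1]")
    }
    path <- pmin(pmax(path, 0), 1)
  }
  n <- nrow(templates$templates[[1L]])
  frames <- local_seed(seed, {
    lapply(seq_along(path), function(t) {
      base <- if (discrete) {
        templates$templates[[path[t]]]
      } else {
        (1 - path[t]) * templates$templates[[1L]] +
          path[t] * templates$templates[[K]]
      }
      base + matrix(stats::rnorm(3L * n, 0, jitter), n, 3L)
    })
  })
  list(frames = frames, system = templates$system,
       groundTruth = list(path = path,
                          kind = if (discrete) "discrete" else "continuous"))
}

#' Map a slow coordinate to interpolation weights in [0, 1]
#'
#' Clipped affine rescaling used to drive continuous template interpolation
#' from a Langevin slow coordinate.
#'
#' @param x numeric vector
#' @param lo,hi values mapped to 0 and 1 (defaults: range of x)
#' @return numeric vector in [0, 1]
#' @export
rescale01 <- function(x, lo = min(x), hi = max(x)) {
  pmin(pmax((x - lo) / (hi - lo), 0), 1)
}

## ---- temporal split --------------------------------------------------------

#' Temporal train/validation split
#'
#' The validation set is always the second half of the trajectory; training
#' indices come only from the first half.  With `nSegments > 1`, the first
#' half is divided into equal segments and whole segments are drawn at
#' random until the requested fraction of the total trajectory is covered.
#' Random (frame-level) splits are deliberately not offered: successive
#' frames are strongly correlated, and a random split lets a network score
#' well on validation data it has effectively memorized.
#'
#' @param T number of frames
#' @param trainFraction fraction of the *total* trajectory used for
#'   training; at most 0.5
#' @param nSegments number of equal segments the first half is divided into
#' @param seed integer seed for segment selection
#' @return list: `train` (integer indices), `val` (integer indices),
#'   `trainSegments` (list of contiguous index runs; lagged pairs must not
#'   span segment boundaries)
#' @export
temporalSplit <- function(T, trainFraction = 0.5, nSegments = 1L, seed = 1L) {
  stopifnot(T >= 2)
  if (trainFraction <= 0 || trainFraction > 0.5 + 1e-12) {
    stop("trainFraction must be in (0, 0.5]: the second half is validation")
  }
  H <- floor(T / 2)
  val <- (H + 1L):T
  if (nSegments <= 1L) {
    train <- seq_len(max(1L, floor(trainFraction * T)))
    segs <- list(train)
  } else {
    L <- floor(H / nSegments)
    if (L < 1L) stop("too many segments for the trajectory length")
    # smallest number of whole segments covering the requested fraction
    k <- ceiling(trainFraction / 0.5 * nSegments - 1e-9)
    k <- max(1L, min(nSegments, k))
    pick <- local_seed(seed, sort(sample.int(nSegments, k)))
    segs <- lapply(pick, function(s) ((s - 1L) * L + 1L):(s * L))
    train <- unlist(segs)
  }
  list(train = train, val = val, trainSegments = segs)
}
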