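# Reporting analyses: free-energy surfaces over collective variables,
# fraction of native contacts, binned CV surfaces, and attention-map
# summaries.

#' Two-dimensional potential of mean force
#'
#' F = -ln(histogram density), shifted so the minimum is 0.  Empty bins are
#' `NA` (masked), never `-ln 0`.  Units default to kT; pass
#' `units = "kcal_per_mol"` with a temperature to convert by k_B T.
#'
#' @param cvPairs T x 2 matrix of CV samples
#' @param bins number of bins per axis (>= 2)
#' @param units `"kT"` or `"kcal_per_mol"`
#' @param temperature temperature in Kelvin (required for kcal/mol)
#' @return list of class `pmf2d`: `F` (bins x bins matrix), `xBreaks`,
#'   `yBreaks`, `xMid`, `yMid`, `units`
#' @export
pmf2d <- function(cvPairs, bins = 50L, units = c("kT", "kcal_per_mol"),
                  temperature = NULL) {
  units <- match.arg(units)
  cvPairs <- as.matrix(cvPairs)
  stopifnot(ncol(cvPairs) == 2L, nrow(cvPairs) >= 1L, bins >= 2L)
  kBT <- 1
  if (units == "kcal_per_mol") {
    if (is.null(temperature)) {
      stop("kcal/mol units require an explicit temperature")
    }
    kBT <- 0.0019872041 * temperature
  }
  xb <- seq(min(cvPairs[, 1L]), max(cvPairs[, 1L]), length.out = bins + 1L)
  yb <- seq(min(cvPairs[, 2L]), max(cvPairs[, 2L]), length.out = bins + 1L)
  if (xb[1L] == xb[bins + 1L]) xb <- xb + seq(-0.5, 0.5, length.out = bins + 1L)
  if (yb[1L] == yb[bins + 1L]) yb <- yb + seq(-0.5, 0.5, length.out = bins + 1L)
  ix <- pmin(pmax(findInterval(cvPairs[, 1L], xb, all.inside = TRUE), 1L),
             bins)
  iy <- pmin(pmax(findInterval(cvPairs[, 2L], yb, all.inside = TRUE), 1L),
             bins)
  H <- matrix(0, bins, bins)
  tab <- table(factor(ix, levels = seq_len(bins)),
               factor(iy, levels = seq_len(bins)))
  H[] <- as.matrix(unclass(tab))
  if (sum(H > 0) == 1L) {
    warning("all samples fall in a single bin; PMF grid is degenerate")
  }
  FF <- matrix(NA_real_, bins, bins)
  FF[H > 0] <- -log(H[H > 0] / sum(H)) * kBT
  FF <- FF - min(FF, na.rm = TRUE)
  structure(list(F = FF, xBreaks = xb, yBreaks = yb,
                 xMid = (xb[-1L] + xb[-(bins + 1L)]) / 2,
                 yMid = (yb[-1L] + yb[-(bins + 1L)]) / 2, units = units),
            class = "pmf2d")
}

#' Define native contacts from a reference structure
#'
#' A native contact is a residue pair at sequence separation >= `minSep`
#' with at least one heavy-atom (non-hydrogen) distance below `threshold`
#' in the reference coordinates.
#'
#' @param system a [MolSystem] holding the reference coordinates
#' @param threshold heavy-atom distance threshold in Angstrom
#' @param minSep minimum residue-index separation
#' @return list of class `contactDefinition`: `pairs` (n x 2 residue-index
#'   matrix, first column < second), `threshold`, `minSep`, `heavyIdx`
#' @export
contactDefinition <- function(system, threshold = 4.5, minSep = 3L) {
  stopifnot(is(system, "MolSystem"))
  heavy <- which(system@atomicNumber != 1L)
  if (length(heavy) == 0L) stop("reference has no heavy atoms")
  res <- sort(unique(system@resid))
  byres <- split(heavy, system@resid[heavy])
  pairs <- NULL
  for (a in seq_along(res)) {
    for (b in seq_along(res)) {
      if (b <= a || abs(res[b] - res[a]) < minSep) next
      ia <- byres[[as.character(res[a])]]
      ib <- byres[[as.character(res[b])]]
      if (is.null(ia) || is.null(ib)) next
      dmin <- min_cross_dist(system@coords[ia, , drop = FALSE],
                             system@coords[ib, , drop = FALSE])
      if (dmin < threshold) pairs <- rbind(pairs, c(res[a], res[b]))
    }
  }
  if (is.null(pairs)) stop("reference structure has no native contacts")
  structure(list(pairs = pairs, threshold = threshold,
                 minSep = as.integer(minSep), heavyIdx = heavy,
                 resid = system@resid),
            class = "contactDefinition")
}

min_cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Fraction of native contacts per frame
#'
#' Q_t is the fraction of reference contacts whose heavy-atom minimum
#' distance is below the (same) threshold in frame t; Qbar is the centered
#' moving average over `window` frames.
#'
#' @param frames T x N x 3 array or list of N x 3 matrices
#' @param contacts a [contactDefinition()] result
#' @param window moving-average window in frames (odd values center
#'   exactly); see [framesPerWindow()] to derive it from a time span
#' @return list with `Q` and `Qbar`, both length T in [0, 1]
#' @export
fractionNativeContacts <- function(frames, contacts, window = 5L) {
  stopifnot(inherits(contacts, "contactDefinition"))
  if (is.list(frames)) {
    TT <- length(frames)
    getf <- function(t) frames[[t]]
  } else {
    TT <- dim(frames)[1L]
    getf <- function(t) matrix(frames[t, , ], ncol = 3L)
  }
  heavy_by_res <- split(contacts$heavyIdx,
                        contacts$resid[contacts$heavyIdx])
  np <- nrow(contacts$pairs)
  Q <- numeric(TT)
  for (t in seq_len(TT)) {
    co <- getf(t)
    hit <- 0L
    for (p in seq_len(np)) {
      ia <- heavy_by_res[[as.character(contacts$pairs[p, 1L])]]
      ib <- heavy_by_res[[as.character(contacts$pairs[p, 2L])]]
      if (min_cross_dist(co[ia, , drop = FALSE],
                         co[ib, , drop = FALSE]) < contacts$threshold) {
        hit <- hit + 1L
      }
    }
    Q[t] <- hit / np
  }
  list(Q = Q, Qbar = moving_average(Q, window))
}

# centered moving average; shrinks the window at the edges
moving_average <- function(x, window) {
  half <- (window - 1L) %/% 2L
  vapply(seq_along(x), function(t) {
    mean(x[max(1L, t - half):min(length(x), t + half)])
  }, numeric(1))
}

#' Frames per time window
#'
#' @param windowTime window length in time units (e.g. ns)
#' @param timePerFrame trajectory cadence in the same units
#' @return integer frame count (>= 1)
#' @export
framesPerWindow <- function(windowTime, timePerFrame) {
  max(1L, as.integer(round(windowTime / timePerFrame)))
}

#' Binned mean of a CV over two physical coordinates
#'
#' @param cv numeric vector, length T
#' @param coordX,coordY numeric vectors, length T
#' @param bins number of bins per axis
#' @return list: `mean` (bins x bins, `NA` where empty), `xMid`, `yMid`
#' @export
cvSurface <- function(cv, coordX, coordY, bins = 50L) {
  TT <- length(cv)
  if (length(coordX) != TT || length(coordY) != TT) {
    stop("cv, coordX and coordY must have equal lengths")
  }
  xb <- seq(min(coordX), max(coordX), length.out = bins + 1L)
  yb <- seq(min(coordY), max(coordY), length.out = bins + 1L)
  ix <- pmin(pmax(findInterval(coordX, xb, all.inside = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(coordY, yb, all.inside = TRUE), 1L), bins)
  sum_ <- matrix(0, bins, bins)
  cnt <- matrix(0, bins, bins)
  for (t in seq_len(TT)) {
    sum_[ix[t], iy[t]] <- sum_[ix[t], iy[t]] + cv[t]
    cnt[ix[t], iy[t]] <- cnt[ix[t], iy[t]] + 1
  }
  M <- matrix(NA_real_, bins, bins)
  M[cnt > 0] <- sum_[cnt > 0] / cnt[cnt > 0]
  list(mean = M, xMid = (xb[-1L] + xb[-(bins + 1L)]) / 2,
       yMid = (yb[-1L] + yb[-(bins + 1L)]) / 2)
}

#' Summarize attention maps globally and per state
#'
#' Averages per-frame, head-averaged attention maps over all frames and,
#' when labels are given, over the frames of each populated state.  The
#' per-state averages, weighted by state frame counts, recompose the
#' global average exactly.  Token activity follows the row/column-sum
#' convention: row sums measure how much a token attends, column sums how
#' much it is attended to.
#'
#' @param maps list of per-layer arrays S x S x T (as returned by
#'   [attentionMaps()])
#' @param labels optional [StateLabels] or integer vector aligned with the
#'   frame axis
#' @param tokenNames optional length-S character vector of token names
#' @return list of class `attentionReport`: per layer, `global` (S x S),
#'   `perState` (named list of S x S), `rowActivity`, `colActivity`,
#'   `stateCounts`
#' @export
attentionReport <- function(maps, labels = NULL, tokenNames = NULL) {
  stopifnot(is.list(maps), length(maps) >= 1L)
  TT <- dim(maps[[1L]])[3L]
  lab <- NULL
  if (!is.null(labels)) {
    lab <- if (is(labels, "StateLabels")) labelVector(labels) else
      as.integer(labels)
    if (length(lab) != TT) {
      stop("labels length (", length(lab), ") does not match frame count (",
           TT, ")")
    }
  }
  layer_report <- function(A) {
    S <- dim(A)[1L]
    if (!is.null(tokenNames) && length(tokenNames) == S) {
      dimnames(A) <- list(tokenNames, tokenNames, NULL)
    }
    glob <- apply(A, c(1L, 2L), mean)
    out <- list(global = glob, rowActivity = rowSums(glob),
                colActivity = colSums(glob))
    if (!is.null(lab)) {
      states <- sort(unique(lab))
      out$perState <- lapply(states, function(s) {
        apply(A[, , lab == s, drop = FALSE], c(1L, 2L), mean)
      })
      names(out$perState) <- states
      out$stateCounts <- as.vector(table(factor(lab, levels = states)))
      names(out$stateCounts) <- states
    }
    out
  }
  structure(list(layers = lapply(maps, layer_report), nFrames = TT),
            class = "attentionReport")
}

#' @export
print.attentionReport <- function(x, ...) {
  cat(sprintf("Attention report: %d layer(s), %d frame(s)\n",
              length(x$layers), x$nFrames))
  for (l in seq_along(x$layers)) {
    cat(sprintf("layer %d row activity: %s\n", l,
                paste(sprintf("%.3f", x$layers[[l]]$rowActivity),
                      collapse = " ")))
  }
  invisible(x)
}
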