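# Markov state model estimation from discrete state labels.

#' Build a Markov state model from state labels
#'
#' Count-based, row-normalized transition matrix over the populated states
#' at the given lag, plus the empirical occupancy (label frequencies).
#' Transitions are counted within each trajectory segment only, never
#' across segment boundaries.
#'
#' @param labels a [StateLabels] or integer label vector (1-based)
#' @param lag lag time in frames (>= 1)
#' @param segments optional list of frame-index vectors delimiting
#'   independent trajectory segments; default one contiguous trajectory
#' @return list of class `msmModel`: `transition` (row-stochastic matrix
#'   over populated states), `occupancy`, `states` (the populated label
#'   values, in increasing order), `counts`, `lag`
#' @export
buildMSM <- function(labels, lag = 1L, segments = NULL) {
  lab <- if (is(labels, "StateLabels")) labelVector(labels) else
    as.integer(labels)
  TT <- length(lab)
  if (TT <= lag) stop("need more than lag = ", lag, " frames")
  if (is.null(segments)) segments <- list(seq_len(TT))
  states <- sort(unique(lab))
  K <- length(states)
  idx <- match(lab, states)
  counts <- matrix(0, K, K, dimnames = list(states, states))
  for (seg in segments) {
    if (length(seg) <= lag) next
    from <- idx[seg[seq_len(length(seg) - lag)]]
    to <- idx[seg[-seq_len(lag)]]
    tab <- table(factor(from, levels = seq_len(K)),
                 factor(to, levels = seq_len(K)))
    counts <- counts + as.matrix(unclass(tab))
  }
  rs <- rowSums(counts)
  zero_rows <- which(rs == 0)
  if (length(zero_rows) > 0L) {
    warning("state(s) ", paste(states[zero_rows], collapse = ", "),
            " have no outgoing transitions at lag ", lag,
            "; imputing self-loops")
    counts[cbind(zero_rows, zero_rows)] <- 1
    rs <- rowSums(counts)
  }
  P <- counts / rs
  occ <- as.vector(table(factor(idx, levels = seq_len(K)))) / TT
  names(occ) <- states
  structure(list(transition = P, occupancy = occ, states = states,
                 counts = counts, lag = as.integer(lag)),
            class = "msmModel")
}

#' @export
print.msmModel <- function(x, ...) {
  cat(sprintf("MSM: %d states at lag %d\n", length(x$states), x$lag))
  cat("occupancy:", paste(sprintf("%s=%.3f", x$states, x$occupancy),
                          collapse = " "), "\n")
  print(round(x$transition, 3))
  invisible(x)
}

#' Implied relaxation timescales of an MSM
#'
#' t_i = -lag / log |lambda_i| for the non-unit eigenvalues of the
#' transition matrix, sorted slowest first.
#'
#' @param msm an `msmModel`
#' @return numeric vector of length (#states - 1)
#' @export
impliedTimescales <- function(msm) {
  ev <- eigen(msm$transition)$values
  ev <- sort(Mod(ev), decreasing = TRUE)[-1L]
  -msm$lag / log(pmin(ev, 1 - 1e-12))
}
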