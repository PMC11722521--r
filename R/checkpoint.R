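# Encoder checkpoints: single-file archives with a config header and named
# parameter arrays.  Loading refuses config mismatches so a downstream task
# can never silently consume features from the wrong encoder.

.CHECKPOINT_VERSION <- 1L

#' Save an encoder checkpoint
#'
#' @param model a `gnnEncoder` (from [encoderInit()] or [trainDenoiser()])
#' @param path file path to write
#' @return `path`, invisibly
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(inherits(model, "gnnEncoder"))
  obj <- list(format_version = .CHECKPOINT_VERSION,
              config = model$config,
              params = model$params)
  saveRDS(obj, path)
  invisible(path)
}

#' Load an encoder checkpoint
#'
#' @param path checkpoint file written by [saveCheckpoint()]
#' @param expectConfig optional [encoderConfig()]; loading fails if the
#'   stored architecture (d, nLayers, cutoff, nRbf) differs
#' @return a `gnnEncoder`
#' @export
loadCheckpoint <- function(path, expectConfig = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$format_version, .CHECKPOINT_VERSION)) {
    stop("unsupported checkpoint format version: ", obj$format_version)
  }
  if (!is.null(expectConfig)) {
    for (f in c("d", "nLayers", "cutoff", "nRbf")) {
      if (!identical(obj$config[[f]], expectConfig[[f]])) {
        stop("checkpoint config mismatch on '", f, "': stored ",
             obj$config[[f]], ", expected ", expectConfig[[f]])
      }
    }
  }
  structure(list(config = obj$config, params = obj$params),
            class = "gnnEncoder")
}

# Stable identity of an encoder (config + parameters)
encoder_hash <- function(model) {
  object_hash(list(model$config, model$params))
}

#' @export
print.gnnEncoder <- function(x, ...) {
  cat(sprintf(
    "Equivariant GNN encoder: d = %d, %d layers, cutoff %.1f A, %d RBFs\n",
    x$config$d, x$config$nLayers, x$config$cutoff, x$config$nRbf))
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("  %d parameters, hash %s\n", np,
              substr(encoder_hash(x), 1, 12)))
  invisible(x)
}
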