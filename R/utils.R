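# Internal helpers: element tables, hashing, seeded evaluation.

.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe"
)

#' Convert element symbols to atomic numbers
#'
#' @param element character vector of element symbols (e.g. "C", "N", "O")
#' @return integer vector of atomic numbers
#' @export
elementToZ <- function(element) {
  z <- match(toupper(element), toupper(.ELEMENTS))
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(z)]), collapse = ", "))
  }
  as.integer(z)
}

#' Convert atomic numbers to element symbols
#'
#' @param z integer vector of atomic numbers
#' @return character vector of element symbols
#' @export
zToElement <- function(z) {
  if (any(z < 1L | z > length(.ELEMENTS))) stop("atomic number out of range")
  .ELEMENTS[z]
}

# md5 hash of an arbitrary R object (provenance keys for caches/checkpoints)
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2L)
  close(con)
  unname(tools::md5sum(f))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}

# Derive a substream seed below 2^31 from a base seed and a stream index.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(stream)) %%
               2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
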