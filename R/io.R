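# Structure and trajectory I/O.  PDB and DCD are handled through bio3d;
# XYZ is parsed directly (the format is three trivial record types).
# Coordinates are Angstrom throughout.

#' Read a molecular structure file
#'
#' Supported formats: PDB (`.pdb`) and XYZ (`.xyz`), inferred from the file
#' extension.
#'
#' @param path file path
#' @return a [MolSystem]
#' @export
readStructure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    at <- pdb$atom
    el <- at$elesy
    if (any(is.na(el) | !nzchar(el))) {
      el <- substr(trimws(at$elety), 1L, 1L)
    }
    molSystem(element = trimws(el),
              coords = cbind(at$x, at$y, at$z),
              resid = as.integer(at$resno),
              resname = trimws(at$resid))
  } else if (ext == "xyz") {
    fr <- read_xyz_frames(path, maxFrames = 1L)
    molSystem(element = fr$elements, coords = fr$frames[[1L]])
  } else {
    stop("unrecognized structure format: .", ext,
         " (supported: .pdb, .xyz)")
  }
}

# parse a (possibly multi-frame) XYZ file
read_xyz_frames <- function(path, maxFrames = Inf) {
  lines <- readLines(path)
  frames <- list()
  elements <- NULL
  i <- 1L
  while (i <= length(lines) && length(frames) < maxFrames) {
    if (!nzchar(trimws(lines[i]))) {
      i <- i + 1L
      next
    }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) {
      stop("XYZ parse error at line ", i, ": expected atom count, got '",
           lines[i], "'")
    }
    if (i + 1L + n > length(lines)) {
      stop("XYZ parse error: truncated frame starting at line ", i)
    }
    block <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(toks, length, integer(1)) < 4L)
    if (length(bad) > 0L) {
      stop("XYZ parse error at line ", i + 1L + bad[1L],
           ": need element and three coordinates")
    }
    el <- vapply(toks, `[[`, character(1), 1L)
    # coercion NAs are reported as a contextual parse error below
    xyz <- matrix(suppressWarnings(
      as.numeric(vapply(toks, function(t) t[2:4], character(3)))),
      ncol = 3L, byrow = TRUE)
    if (anyNA(xyz)) {
      stop("XYZ parse error: non-numeric coordinate in frame starting ",
           "at line ", i)
    }
    if (is.null(elements)) {
      elements <- el
    } else if (!identical(el, elements)) {
      stop("XYZ frames have inconsistent atom lists")
    }
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  if (length(frames) == 0L) stop("no frames found in ", path)
  list(elements = elements, frames = frames)
}

#' Read a trajectory file
#'
#' Supported: multi-frame XYZ (`.xyz`), multi-model PDB (`.pdb`), and DCD
#' (`.dcd`, requires `topology`).  XTC is not supported; convert to DCD
#' first.
#'
#' @param path trajectory file
#' @param topology a [MolSystem] giving atom metadata (required for DCD,
#'   used for atom-count validation otherwise)
#' @return numeric T x N x 3 coordinate array (Angstrom)
#' @export
readTrajectory <- function(path, topology = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  frames <- if (ext == "xyz") {
    read_xyz_frames(path)$frames
  } else if (ext == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    lapply(seq_len(nrow(xyz)), function(t) {
      matrix(xyz[t, ], ncol = 3L, byrow = TRUE)
    })
  } else if (ext == "dcd") {
    if (is.null(topology)) stop("DCD trajectories need a topology")
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    lapply(seq_len(nrow(xyz)), function(t) {
      matrix(xyz[t, ], ncol = 3L, byrow = TRUE)
    })
  } else if (ext == "xtc") {
    stop("XTC is not supported; convert to DCD first")
  } else {
    stop("unrecognized trajectory format: .", ext)
  }
  n <- unique(vapply(frames, nrow, integer(1)))
  if (length(n) != 1L) stop("trajectory frames have varying atom counts")
  if (!is.null(topology) && n != nAtoms(topology)) {
    stop("trajectory has ", n, " atoms but topology has ",
         nAtoms(topology))
  }
  arr <- array(0, dim = c(length(frames), n, 3L))
  for (t in seq_along(frames)) arr[t, , ] <- frames[[t]]
  arr
}

#' Write coordinates to an XYZ file
#'
#' @param coords N x 3 matrix, or T x N x 3 array / list of matrices for a
#'   multi-frame file
#' @param elements character element symbols, length N
#' @param path output path
#' @param comment per-frame comment line (recycled)
#' @return `path`, invisibly
#' @export
writeXYZ <- function(coords, elements, path, comment = "") {
  frames <- if (is.list(coords)) {
    coords
  } else if (length(dim(coords)) == 3L) {
    lapply(seq_len(dim(coords)[1L]), function(t) matrix(coords[t, , ],
                                                        ncol = 3L))
  } else {
    list(as.matrix(coords))
  }
  comment <- rep_len(comment, length(frames))
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_along(frames)) {
    fr <- frames[[t]]
    if (nrow(fr) != length(elements)) stop("element count mismatch")
    writeLines(c(as.character(nrow(fr)), comment[t],
                 sprintf("%s %.6f %.6f %.6f", elements, fr[, 1L],
                         fr[, 2L], fr[, 3L])), con)
  }
  invisible(path)
}

#' Write a system (optionally multi-frame) to a PDB file
#'
#' @param system a [MolSystem] (supplies atom metadata)
#' @param path output path
#' @param frames optional T x N x 3 array; default the system's own
#'   coordinates as a single model
#' @return `path`, invisibly
#' @export
writePDB <- function(system, path, frames = NULL) {
  stopifnot(is(system, "MolSystem"))
  if (is.null(frames)) {
    frames <- array(system@coords, dim = c(1L, nAtoms(system), 3L))
  }
  # bio3d expects frame rows of (x1,y1,z1,x2,...)
  xyz <- t(apply(frames, 1L, function(fr) as.vector(t(fr))))
  if (nrow(xyz) == 1L) xyz <- as.vector(xyz)
  bio3d::write.pdb(file = path, xyz = xyz, resno = system@resid,
                   resid = system@resname, elety = system@element,
                   elesy = system@element)
  invisible(path)
}

#' Write a trajectory with its ground-truth sidecar
#'
#' Writes the frames as multi-frame XYZ plus a JSON sidecar
#' (`<path>.truth.json`) recording the generator's hidden-state sequence
#' and parameters, so downstream analyses can score recovery without
#' re-simulating.
#'
#' @param embedded result of [embedStatesAsConformers()]
#' @param path output `.xyz` path
#' @return list with `trajectory` and `sidecar` paths, invisibly
#' @export
writeSyntheticTrajectory <- function(embedded, path) {
  writeXYZ(embedded$frames, embedded$system@element, path)
  sidecar <- paste0(path, ".truth.json")
  jsonlite::write_json(embedded$groundTruth, sidecar, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(trajectory = path, sidecar = sidecar))
}
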