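toy_system <- function() {
  molSystem(c("C", "H", "N", "O", "H", "C"),
            matrix(rnorm(18), 6, 3),
            resid = c(1L, 1L, 1L, 2L, 2L, 2L))
}

test_that("atom selection rules behave as documented", {
  set.seed(20)
  sys <- toy_system()
  expect_equal(selectAtoms(sys, "all"), 1:6)
  expect_equal(selectAtoms(sys, "non-hydrogen"), c(1L, 3L, 4L, 6L))
  expect_equal(selectAtoms(sys, "heavy"), c(1L, 3L, 4L, 6L))
  expect_equal(selectAtoms(sys, c(3, 1, 3)), c(1L, 3L))
  expect_equal(selectAtoms(sys, list(resid = 2L)), 4:6)
  expect_equal(selectAtoms(sys, list(resid = 1L, element = "H")), 2L)
  expect_error(selectAtoms(sys, 7L), "out of range")
  expect_error(selectAtoms(sys, list(element = "Fe")), "no atoms")
  expect_error(selectAtoms(sys, "bogus"), "unknown selection")
})

test_that("residue partition covers the selection disjointly", {
  set.seed(21)
  sys <- toy_system()
  sel <- selectAtoms(sys, "non-hydrogen")
  part <- partitionByResidue(sys, sel)
  expect_length(part, 2L)
  expect_equal(sort(unname(unlist(part))), seq_along(sel))
  expect_error(check_partition(list(1:2, 2:3), 3L), "overlap")
  expect_error(check_partition(list(1:2), 3L), "cover")
  expect_error(check_partition(list(integer(0), 1:3), 3L), "non-empty")
})

test_that("coarse-graining is an exact sum and conserves totals", {
  set.seed(22)
  nf <- new("NodeFeatures", scalars = matrix(rnorm(24), 6, 4),
            vectors = array(rnorm(72), c(6, 3, 4)))
  part <- list(c(1L, 4L), c(2L, 3L, 5L), 6L)
  tok <- coarseGrain(nf, part)
  expect_equal(nTokens(tok), 3L)
  expect_equal(tok@scalars[2L, ], colSums(nf@scalars[c(2, 3, 5), ]))
  expect_equal(tok@scalars[3L, ], nf@scalars[6L, ])
  # partition conservation: summing tokens == summing atoms
  expect_equal(colSums(tok@scalars), colSums(nf@scalars))
  expect_equal(apply(tok@vectors, c(2, 3), sum),
               apply(nf@vectors, c(2, 3), sum))
  # sum pooling of tokens equals pooling atoms directly
  pool <- globalPool(tok, "sum")
  expect_equal(pool$scalars, colSums(nf@scalars))
  pm <- globalPool(tok, "mean")
  expect_equal(pm$scalars, colSums(nf@scalars) / 3)
})

test_that("trajectory inference stacks frozen-encoder tokens with provenance", {
  set.seed(23)
  sys <- toy_system()
  enc <- encoderInit(encoderConfig(d = 4L, nLayers = 1L, cutoff = 5,
                                   nRbf = 4L, seed = 3L))
  frames <- lapply(1:5, function(t) sys@coords + 0.05 * matrix(rnorm(18), 6))
  before <- enc$params
  store <- inferTrajectory(frames, sys, enc, selection = "all")
  expect_identical(enc$params, before)
  expect_equal(nFrames(store), 5L)
  expect_equal(nTokens(store), 2L)
  md <- storeMetadata(store)
  expect_identical(md$checkpoint_hash, encoder_hash(enc))
  expect_equal(md$units, "Angstrom")
  # matches single-frame encode + coarse-grain exactly
  sel <- selectAtoms(sys, "all")
  nf <- encode(buildGraph(frames[[3L]][sel, ], sys@atomicNumber[sel], 5),
               enc)
  tok <- coarseGrain(nf, partitionByResidue(sys, sel))
  expect_equal(store@scalars[3L, , ], tok@scalars, tolerance = 1e-10)
  expect_equal(store@vectors[3L, , , ], tok@vectors, tolerance = 1e-10)
  # stride
  st2 <- inferTrajectory(frames, sys, enc, selection = "all", stride = 2L)
  expect_equal(nFrames(st2), 3L)
  expect_equal(st2@scalars[2L, , ], store@scalars[3L, , ])
  expect_error(inferTrajectory(frames[1:2], molSystem("C", matrix(0, 1, 3)),
                               enc), "atom count")
})

test_that("partition files parse one token per line", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 2 3", "", "4 5"), p)
  part <- readPartitionFile(p)
  expect_equal(part, list(1:3, 4:5))
})
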