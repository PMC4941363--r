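test_that("rolling-ball subtraction matches brute-force grayscale opening", {
  set.seed(21)
  img <- matrix(runif(64 * 64, 0, 1000), 64, 64)
  for (radius in c(3, 7)) {
    bg <- oracleOpening(img, radius)
    expect_equal(rollingBallSubtract(img, radius), pmax(img - bg, 0))
  }
  # constant image -> all zeros; zeros -> zeros
  expect_equal(rollingBallSubtract(matrix(5, 40, 40), 10),
               matrix(0, 40, 40))
  expect_equal(rollingBallSubtract(matrix(0, 40, 40), 10),
               matrix(0, 40, 40))
  # oversized radius warns and degenerates to the global minimum
  expect_warning(out <- rollingBallSubtract(matrix(1:16 / 4, 4, 4), 99),
                 "radius")
  expect_equal(out, matrix(1:16 / 4, 4, 4) - min(1:16 / 4))
})

test_that("rolling ball removes a ramp but keeps a compact bright spot", {
  ramp <- outer(rep(1, 64), seq(0, 100, length.out = 64))
  img <- ramp
  img[31:33, 31:33] <- img[31:33, 31:33] + 500  # 3-px-wide spot
  out <- rollingBallSubtract(img, 25)
  # background gone (away from the high-side border, where a truncated
  # structuring element inevitably under-reaches on a ramp)
  bgRegion <- out[, 1:38]; bgRegion[31:33, 31:33] <- 0
  expect_lt(max(bgRegion) / 500, 0.05)
  expect_gt(out[32, 32] / 500, 0.95)                    # amplitude kept
})

test_that("adaptive mean threshold matches the brute-force local mean", {
  set.seed(22)
  img <- matrix(runif(64 * 64, 0, 100), 64, 64)
  for (window in c(5, 31)) {
    lm <- oracleLocalMean(img, window)
    expect_identical(adaptiveMeanThreshold(img, window, 3), img > lm + 3)
  }
  expect_false(any(adaptiveMeanThreshold(matrix(7, 32, 32), 15, 1)))
  expect_true(all(adaptiveMeanThreshold(img, 15, -1e9)))
  expect_error(adaptiveMeanThreshold(img, 16, 0), "odd")
  # bright disc on zero background, window 31, offset 0: interior foreground
  disc <- matrix(0, 64, 64)
  disc[discMask(64, 64, cbind(32, 32, 5.5))] <- 1000
  fg <- adaptiveMeanThreshold(disc, 31, 0)
  expect_true(all(fg[disc > 0]))
})

test_that("minimum-area filter uses strict less-than semantics", {
  m <- matrix(FALSE, 40, 80)
  m[2:6, 2] <- TRUE                 # area 5
  m[10, 10:28] <- TRUE              # area 19
  m[20, 20:39] <- TRUE              # area 20
  out <- filterSmallObjects(m, 20)
  expect_equal(attr(out, "discarded"), 2L)
  expect_false(any(out[2:6, 2]))
  expect_false(any(out[10, 10:28]))
  expect_true(all(out[20, 20:39]))
  # area exactly 20 survives at the default
  # empty mask passes through; filtering is idempotent
  empty <- matrix(FALSE, 8, 8)
  expect_equal(sum(filterSmallObjects(empty)), 0)
  expect_equal(filterSmallObjects(out, 20), out, ignore_attr = TRUE)
  # label input: survivors renumbered to a contiguous set
  lab <- matrix(0L, 40, 80)
  lab[2:6, 2] <- 1L; lab[20, 20:39] <- 2L
  flab <- filterSmallObjects(lab, 20)
  expect_identical(sort(unique(flab[flab > 0])), 1L)
})

test_that("seeded watershed splits touching nuclei and only those", {
  # single isolated disc -> one label covering the disc
  m1 <- discMask(64, 64, cbind(32, 32, 10))
  l1 <- splitTouchingNuclei(m1)
  expect_equal(max(l1), 1)
  expect_true(all(l1[m1] == 1))
  # dumbbell: discs of radius 10, centers 16 px apart -> exactly 2 labels,
  # split along the neck (each center keeps its own label; the two halves
  # partition the dumbbell)
  m2 <- discMask(80, 80, rbind(c(40, 32, 10), c(40, 48, 10)))
  l2 <- splitTouchingNuclei(m2)
  expect_equal(max(l2), 2)
  expect_true(all(sort(unique(l2[m2])) == 1:2))
  expect_false(l2[40, 32] == l2[40, 48])
  # oracle: flood assignment by nearest distance maximum - away from the
  # equidistant midline every pixel goes with its nearer center
  idx <- which(m2, arr.ind = TRUE)
  d1 <- (idx[, 1] - 40)^2 + (idx[, 2] - 32)^2
  d2 <- (idx[, 1] - 40)^2 + (idx[, 2] - 48)^2
  off <- abs(sqrt(d1) - sqrt(d2)) > 1.5   # exclude the ridge neighborhood
  expected <- ifelse(d1 < d2, l2[40, 32], l2[40, 48])
  got <- l2[idx]
  expect_true(all(got[off] == expected[off]))
  # two disjoint discs -> identical to connected components
  m3 <- discMask(80, 120, rbind(c(40, 30, 10), c(40, 80, 10)))
  l3 <- splitTouchingNuclei(m3)
  expect_equal(max(l3), 2)
  expect_true(all((l3 > 0) == m3))
  # empty mask -> empty labels
  expect_equal(max(splitTouchingNuclei(matrix(FALSE, 16, 16))), 0)
})

test_that("contested dilation equals the exhaustive nearest-seed oracle", {
  # isolated nucleus, radius 8: equals brute-force disc dilation
  lab1 <- matrix(0L, 48, 48)
  lab1[discMask(48, 48, cbind(24, 24, 6))] <- 1L
  cm1 <- makeCellMasks(lab1, 8)
  expect_identical(cm1, oracleNearestSeed(lab1, 8))
  expect_true(all(cm1[lab1 > 0] == 1L))
  # radius 0: cell mask equals nuclear mask
  expect_identical(makeCellMasks(lab1, 0), lab1)
  # two nuclei 10 px apart, radius 8: midline split by nearest-nucleus rule
  lab2 <- matrix(0L, 60, 60)
  lab2[discMask(60, 60, cbind(30, 25, 4))] <- 1L
  d2 <- discMask(60, 60, cbind(30, 35, 4)) & lab2 == 0L
  lab2[d2] <- 2L
  cm2 <- makeCellMasks(lab2, 8)
  expect_identical(cm2, oracleNearestSeed(lab2, 8))
  # union equals the unconstrained dilation of the two nuclei
  un <- oracleNearestSeed(lab2 > 0, 8)  # single-label dilation
  expect_identical(cm2 > 0, un > 0)
})

test_that("edge-cell removal is governed by the cell mask and idempotent", {
  mkSeg <- function(nucCenter, dil) {
    lab <- matrix(0L, 40, 40)
    lab[discMask(40, 40, cbind(nucCenter[1], nucCenter[2], 4))] <- 1L
    new("SegmentationResult", nuclearMask = lab,
        cellMask = makeCellMasks(lab, dil), discardedSmall = 0L,
        discardedEdge = 0L, parameters = list())
  }
  # interior cell: unchanged
  s1 <- removeEdgeCells(mkSeg(c(20, 20), 8))
  expect_equal(nCells(s1), 1)
  expect_equal(s1@discardedEdge, 0L)
  # nucleus interior but its dilated cell mask reaches column 1: removed
  s2raw <- mkSeg(c(20, 10), 9)   # nucleus spans cols 6..14, cell cols 1..
  expect_true(any(s2raw@cellMask[, 1] > 0))
  expect_false(any(s2raw@nuclearMask[, 1] > 0))
  s2 <- removeEdgeCells(s2raw)
  expect_equal(nCells(s2), 0)
  expect_equal(s2@discardedEdge, 1L)
  expect_true(all(s2@nuclearMask == 0))
  # idempotence
  expect_equal(removeEdgeCells(s1)@discardedEdge, s1@discardedEdge)
  expect_identical(removeEdgeCells(s1)@nuclearMask, s1@nuclearMask)
})

test_that("full segmentation recovers simulated fields", {
  # zero-noise field of interior nuclei: exact label count, algebra holds
  cfg <- quietConfig(controlCondition(replicates = 1L), cellsPerField = 50,
                     touchingFraction = 0, seed = 31)
  plate <- simulatePlate(cfg)
  f <- plate$fields[[1]]
  seg <- segmentField(f, segmentationParams(offset = 50))
  expect_equal(nCells(seg), nrow(plate$truth))
  expectMaskAlgebra(seg)
  # blank field -> zero labels
  cfgB <- plateSimConfig(controlCondition(densityScale = 0, replicates = 1L),
                         fieldSize = 128)
  pB <- simulatePlate(cfgB)
  segB <- segmentField(pB$fields[[1]])
  expect_equal(nCells(segB), 0)
  # touching pairs among 40 nuclei at default noise: every pair split
  cfgP <- plateSimConfig(controlCondition(replicates = 1L),
                         cellsPerField = 40, touchingFraction = 0.25,
                         seed = 33)
  pP <- simulatePlate(cfgP)
  segP <- segmentField(pP$fields[[1]])
  expectMaskAlgebra(segP)
  tr <- pP$truth
  expect_equal(nCells(segP), nrow(tr))
  m <- matchTruthToLabels(tr, segP)
  for (p in setdiff(unique(tr$pair_id), 0)) {
    two <- m[tr$pair_id == p]
    expect_true(all(two > 0) && two[1] != two[2])
  }
  # missing DAPI channel rejected
  f2 <- FieldImage(list(marker = matrix(1, 8, 8)))
  expect_error(segmentField(f2), "DAPI")
})
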