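test_that("in-plane IoU matches brute-force pixel counting and is symmetric", {
  a <- box2d(0, 0, 10, 0, 10)
  expect_equal(iou2d(a, a), 1.0)
  expect_equal(iou2d(a, box2d(0, 20, 30, 0, 10)), 0.0)
  b <- box2d(1, 5, 15, 0, 10)
  expect_equal(iou2d(a, b), 1 / 3)
  expect_equal(iou2d(a, b), iouCountOracle2d(a, b))
  withr::with_seed(1, {
    for (i in 1:25) {
      p <- box2d(0, sample(0:50, 1), sample(60:120, 1), sample(0:50, 1), sample(60:120, 1))
      q <- box2d(0, sample(0:50, 1), sample(60:120, 1), sample(0:50, 1), sample(60:120, 1))
      expect_equal(iou2d(p, q), iou2d(q, p))
      expect_equal(iou2d(p, q), iouCountOracle2d(p, q))
    }
  })
  expect_error(iou2d(list(x0 = 0, x1 = 0, z0 = 0, z1 = 5), a), "degenerate")
})

test_that("3D IoU is voxel-wise overlap of half-open cuboids", {
  a <- list(s0 = 0, s1 = 4, x0 = 0, x1 = 10, z0 = 0, z1 = 10)
  expect_equal(iou3d(a, a), 1.0)
  expect_equal(iou3d(a, list(s0 = 4, s1 = 8, x0 = 0, x1 = 10, z0 = 0, z1 = 10)), 0.0)
  ## half of each volume shared -> 1/3
  b <- list(s0 = 2, s1 = 6, x0 = 0, x1 = 10, z0 = 0, z1 = 10)
  expect_equal(iou3d(a, b), 1 / 3)
  ## brute-force voxel counting oracle
  cells <- expand.grid(s = 0:9, x = 0:14, z = 0:14)
  inA <- with(cells, s >= a$s0 & s < a$s1 & x >= a$x0 & x < a$x1 & z >= a$z0 & z < a$z1)
  inB <- with(cells, s >= b$s0 & s < b$s1 & x >= b$x0 & x < b$x1 & z >= b$z0 & z < b$z1)
  expect_equal(iou3d(a, b), sum(inA & inB) / sum(inA | inB))
  expect_error(iou3d(a, list(s0 = 1, s1 = 1, x0 = 0, x1 = 5, z0 = 0, z1 = 5)), "degenerate")
})

test_that("score fusion is the product with the B-scan score", {
  bx <- scoredBoxes(box2d(3, 0, 10, 0, 10), 0.8)
  expect_equal(fuseScores(bx, 0.5)$score, 0.4)
  expect_identical(fuseScores(bx, 0.5)$source, "fused")
  expect_equal(fuseScores(bx, 1.0)$score, 0.8) # identity
  expect_equal(fuseScores(bx, 0.0)$score, 0.0) # annihilator
  expect_identical(fuseScores(bx, 0.5)[, 1:5], bx[, 1:5]) # geometry unchanged
  expect_error(fuseScores(bx, 1.5), "outside")
  bad <- bx
  bad$score <- 2
  expect_error(fuseScores(bad, 0.5), "outside")
})

test_that("within-slice suppression keeps the higher-scoring of overlapping boxes", {
  b <- rbind(
    scoredBoxes(box2d(0, 0, 10, 0, 10), 0.7),
    scoredBoxes(box2d(0, 1, 10, 0, 10), 0.6)
  )
  expect_equal(iou2d(b[1, ], b[2, ]), 0.9)
  out <- suppressBoxes(b, 0.5)
  expect_identical(nrow(out), 1L)
  expect_equal(out$score, 0.7)
  ## disjoint boxes both survive
  b2 <- rbind(b[1, ], scoredBoxes(box2d(0, 50, 60, 0, 10), 0.1))
  expect_identical(nrow(suppressBoxes(b2, 0.5)), 2L)
})

test_that("adjacent-slice merging builds tight max-confidence cuboids", {
  ## identical box on slices 3,4,5 with scores .2/.9/.4 -> one cuboid
  bx <- rbind(
    scoredBoxes(box2d(3, 10, 30, 5, 25), 0.2),
    scoredBoxes(box2d(4, 10, 30, 5, 25), 0.9),
    scoredBoxes(box2d(5, 10, 30, 5, 25), 0.4)
  )
  cu <- mergeAcrossScans(bx, 0.5)
  expect_identical(nrow(cu), 1L)
  expect_equal(unlist(cu[c("s0", "s1")]), c(s0 = 3, s1 = 6))
  expect_equal(cu$confidence, 0.9)
  ## same-slice boxes are never merged with each other
  same <- rbind(
    scoredBoxes(box2d(2, 0, 10, 0, 10), 0.5),
    scoredBoxes(box2d(2, 1, 10, 0, 10), 0.6)
  )
  expect_identical(nrow(mergeAcrossScans(same, 0.5)), 2L)
  ## IoU exactly at the threshold is NOT merged (strict inequality)
  atThr <- rbind(
    scoredBoxes(box2d(0, 0, 10, 0, 10), 0.5),
    scoredBoxes(box2d(1, 0, 10, 5, 15), 0.6) # IoU = 50/150... construct exactly 0.5
  )
  ## boxes with IoU exactly 0.5: [0,10) vs [0,10) x, z [0,10) vs [0,15):
  atThr <- rbind(
    scoredBoxes(box2d(0, 0, 10, 0, 10), 0.5),
    scoredBoxes(box2d(1, 0, 10, 0, 20), 0.6)
  )
  expect_equal(iou2d(atThr[1, ], atThr[2, ]), 0.5)
  expect_identical(nrow(mergeAcrossScans(atThr, 0.5)), 2L)
  ## a one-slice gap breaks the chain
  gap <- rbind(
    scoredBoxes(box2d(0, 0, 10, 0, 10), 0.5),
    scoredBoxes(box2d(2, 0, 10, 0, 10), 0.6)
  )
  expect_identical(nrow(mergeAcrossScans(gap, 0.5)), 2L)
  ## transitive chains across many slices collapse into one cuboid
  chain <- do.call(rbind, lapply(0:9, function(s) {
    scoredBoxes(box2d(s, 10 + s, 40 + s, 0, 20), 0.1 * s)
  }))
  cuChain <- mergeAcrossScans(chain, 0.5)
  expect_identical(nrow(cuChain), 1L)
  expect_equal(unlist(cuChain[c("s0", "s1", "x0", "x1")]), c(s0 = 0, s1 = 10, x0 = 10, x1 = 49))
  ## empty input
  expect_identical(nrow(mergeAcrossScans(SubsideOCT:::emptyScoredBoxes())), 0L)
})

test_that("merging equals the graph-flood oracle and is permutation invariant", {
  withr::with_seed(99, {
    for (trial in 1:60) {
      bx <- randomScoredBoxes(sample(0:40, 1), nSlices = 8)
      cu <- mergeAcrossScans(bx, 0.5)
      orc <- mergeOracle(bx, 0.5)
      expect_identical(nrow(cu), length(orc))
      orcDf <- do.call(rbind, lapply(orc, as.data.frame))
      if (length(orc)) {
        expect_identical(cuboidKey(cu), cuboidKey(orcDf))
      }
      if (nrow(bx) > 1) {
        perm <- sample(nrow(bx))
        expect_identical(cuboidKey(mergeAcrossScans(bx[perm, ], 0.5)), cuboidKey(cu))
      }
    }
  })
})

test_that("cuboids are tight: shrinking any face excludes a member box", {
  withr::with_seed(7, {
    bx <- randomScoredBoxes(30, nSlices = 6)
    cu <- mergeAcrossScans(bx, 0.5, includeMembers = TRUE)
    for (i in seq_len(nrow(cu))) {
      g <- cu$members[[i]]
      expect_equal(cu$s0[i], min(g$slice))
      expect_equal(cu$s1[i], max(g$slice) + 1)
      expect_equal(cu$x0[i], min(g$x0))
      expect_equal(cu$x1[i], max(g$x1))
      expect_equal(cu$z0[i], min(g$z0))
      expect_equal(cu$z1[i], max(g$z1))
      expect_equal(cu$confidence[i], max(g$score))
    }
  })
})

test_that("raising the merge threshold never decreases the cuboid count", {
  withr::with_seed(21, {
    for (trial in 1:10) {
      bx <- randomScoredBoxes(40, nSlices = 8)
      counts <- vapply(
        c(0.1, 0.3, 0.5, 0.7, 0.9),
        function(t) nrow(mergeAcrossScans(bx, t)), numeric(1)
      )
      expect_true(all(diff(counts) >= 0))
    }
  })
})

test_that("volume confidence is the max cuboid confidence, 0 when empty", {
  cu <- data.frame(
    s0 = c(0, 2), s1 = c(1, 4), x0 = 0, x1 = 1, z0 = 0, z1 = 1,
    confidence = c(0.3, 0.7)
  )
  expect_equal(volumeConfidence(cu), 0.7)
  expect_equal(volumeConfidence(cu[0, ]), 0.0)
  expect_equal(volumeConfidence(cu[cu$confidence == 0.3, , drop = FALSE][1, , drop = FALSE]), 0.3)
})

test_that("score monotonicity: raising any candidate score never lowers the volume score", {
  withr::with_seed(13, {
    bx <- randomScoredBoxes(25, nSlices = 6)
    base <- volumeConfidence(mergeAcrossScans(bx, 0.5))
    for (i in seq_len(nrow(bx))) {
      up <- bx
      up$score[i] <- min(1, up$score[i] + 0.3)
      expect_gte(volumeConfidence(mergeAcrossScans(up, 0.5)), base)
    }
  })
})

test_that("predictVolume equals the manual composition of its stages and is pure", {
  ds <- tinyDataset()
  m <- tinyModels()
  v <- loadVolume(ds$index$volumePath[which(ds$index$hasSubsidence)[1]])
  p1 <- predictVolume(v, m$cm, m$dm)
  ## manual composition
  fused <- SubsideOCT:::emptyScoredBoxes()
  for (s in seq_len(nSlices(v)) - 1L) {
    st <- makeNeighborStack(v, s, m$dm$inputSize)
    cand <- dmDetect(m$dm, st)
    if (!nrow(cand)) next
    stC <- makeNeighborStack(v, s, m$cm$inputSize)
    fused <- rbind(fused, fuseScores(cand, cmScore(m$cm, stC)))
  }
  manual <- mergeAcrossScans(fused, 0.5)
  expect_equal(p1$cuboids, manual)
  expect_equal(p1$score, volumeConfidence(manual))
  ## deterministic across repeated calls
  p2 <- predictVolume(v, m$cm, m$dm)
  expect_identical(p1, p2)
})
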