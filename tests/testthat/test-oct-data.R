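test_that("OCTVolume validity enforces shape, range and identity fields", {
  expect_error(OCTVolume(matrix(0, 4, 4)), "3D")
  expect_error(OCTVolume(array(-1, c(2, 4, 4))), "non-negative")
  expect_error(OCTVolume(array(0.5, c(2, 4, 4)), eye = "up"), "eye")
  expect_error(OCTVolume(array(2, c(2, 4, 4))), "\\[0, 1\\]")
  expect_error(OCTVolume(array(0.5, c(2, 4, 4)), bitDepth = 8L), "whole numbers")
  v <- OCTVolume(array(7L, c(3, 4, 5)), bitDepth = 8L, participantId = "P1")
  expect_identical(nSlices(v), 3L)
  expect_identical(axialSize(v), 4L)
  expect_identical(lateralSize(v), 5L)
  expect_identical(dim(getSlice(v, 2)), c(4L, 5L))
  expect_error(getSlice(v, 3), "out of range")
})

test_that("TIFF volumes round-trip bit-identically with metadata, at 8 and 16 bit", {
  for (bd in c(8L, 16L)) {
    vox <- array(sample(0:(2^bd - 1), 3 * 20 * 24, replace = TRUE), c(3, 20, 24))
    v <- OCTVolume(vox,
      participantId = "P09", eye = "right", visitId = "V2", bitDepth = bd
    )
    path <- file.path(tempdir(), sprintf("rt%d.tiff", bd))
    saveVolume(v, path)
    v2 <- loadVolume(path)
    expect_identical(voxels(v2), voxels(v))
    expect_identical(bitDepth(v2), bd)
    expect_identical(participantId(v2), "P09")
    expect_identical(eyeSide(v2), "right")
    expect_identical(visitId(v2), "V2")
  }
})

test_that("a 49-slice stack loads with n_slices 49 and a single-slice stack with 1", {
  for (n in c(49L, 1L)) {
    v <- OCTVolume(array(sample(0:255, n * 8 * 10, TRUE), c(n, 8, 10)), bitDepth = 8L)
    p <- file.path(tempdir(), sprintf("n%d.tiff", n))
    saveVolume(v, p)
    expect_identical(nSlices(loadVolume(p)), n)
  }
})

test_that("NIfTI volumes round-trip exactly, including float volumes", {
  vox <- array(runif(2 * 10 * 12), c(2, 10, 12))
  v <- OCTVolume(vox, participantId = "P2", eye = "left")
  p <- file.path(tempdir(), "rt.nii.gz")
  saveVolume(v, p)
  v2 <- loadVolume(p)
  expect_equal(voxels(v2), voxels(v), tolerance = 0)
  expect_true(is.na(bitDepth(v2)))
  ## integer volume via NIfTI keeps values and bit depth
  vi <- OCTVolume(array(sample(0:65535, 2 * 6 * 6, TRUE), c(2, 6, 6)), bitDepth = 16L)
  pi_ <- file.path(tempdir(), "rt16.nii")
  saveVolume(vi, pi_)
  expect_identical(voxels(loadVolume(pi_)), voxels(vi))
})

test_that("loader raises distinct errors for missing files, bad metadata and floats to TIFF", {
  expect_error(loadVolume(file.path(tempdir(), "nope.tiff")), "not found")
  v <- OCTVolume(array(1L, c(2, 4, 4)), bitDepth = 8L)
  p <- file.path(tempdir(), "meta.tiff")
  saveVolume(v, p)
  writeLines("{not json", file.path(tempdir(), "meta.json"))
  expect_error(loadVolume(p), "metadata")
  vf <- OCTVolume(array(0.5, c(2, 4, 4)))
  expect_error(saveVolume(vf, file.path(tempdir(), "f.tiff")), "NIfTI")
  expect_error(saveVolume(v, file.path(tempdir(), "f.png")), "unsupported")
})

test_that("save_volume creates missing directories", {
  v <- OCTVolume(array(1L, c(1, 4, 4)), bitDepth = 8L)
  p <- file.path(tempdir(), "newdir-a", "newdir-b", "v.tiff")
  saveVolume(v, p)
  expect_true(file.exists(p))
})

test_that("annotations round-trip through JSON and reject invalid runs", {
  runs <- data.frame(
    lesionId = c(1L, 1L, 2L), slice = c(5L, 6L, 5L),
    x0 = c(10L, 12L, 40L), x1 = c(30L, 28L, 55L)
  )
  ann <- SubsidenceAnnotation(runs)
  p <- file.path(tempdir(), "ann.json")
  writeAnnotation(ann, p)
  ann2 <- readAnnotation(p)
  expect_identical(annotationRuns(ann2), annotationRuns(ann))
  expect_identical(nLesions(ann2), 2L)
  ## empty annotation round-trips too
  p0 <- file.path(tempdir(), "ann0.json")
  writeAnnotation(SubsidenceAnnotation(), p0)
  expect_false(hasSubsidence(readAnnotation(p0)))
  ## overlapping runs of one lesion on one slice are invalid
  bad <- data.frame(
    lesionId = c(1L, 1L), slice = c(0L, 0L), x0 = c(0L, 5L), x1 = c(10L, 15L)
  )
  expect_error(SubsidenceAnnotation(bad), "overlapping")
  expect_error(
    SubsidenceAnnotation(data.frame(lesionId = 1L, slice = 0L, x0 = 5L, x1 = 5L)),
    "x0 < x1"
  )
})

test_that("annotation_to_boxes maps runs to boxes with the requested depth window", {
  ann <- SubsidenceAnnotation(data.frame(
    lesionId = c(1L, 1L, 1L), slice = c(7L, 7L, 8L),
    x0 = c(100L, 160L, 100L), x1 = c(141L, 180L, 140L)
  ))
  bx <- annotationToBoxes(ann, c(200, 300))
  expect_identical(nrow(bx), 3L)
  one <- bx[bx$slice == 7 & bx$x0 == 100, ]
  expect_equal(
    unlist(one[c("x0", "x1", "z0", "z1")]),
    c(x0 = 100, x1 = 141, z0 = 200, z1 = 300)
  )
  ## two disjoint runs on one slice, one lesion -> two boxes, same lesion id
  expect_identical(unique(bx$lesionId[bx$slice == 7]), 1L)
  expect_identical(sum(bx$slice == 7), 2L)
  ## empty annotation -> empty box list
  expect_identical(nrow(annotationToBoxes(SubsidenceAnnotation(), c(0, 10))), 0L)
  ## windows must be valid and inside the volume
  expect_error(annotationToBoxes(ann, c(300, 200)), "depth window")
  expect_error(annotationToBoxes(ann, c(200, 300), volumeDepth = 250), "bounds")
  ## per-run window function
  bx2 <- annotationToBoxes(ann, function(s, x0, x1) c(s * 10, s * 10 + 5))
  expect_equal(bx2$z0, bx2$slice * 10)
})

test_that("annotation boxes cover exactly the annotated columns (randomised)", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      nRuns <- sample(1:6, 1)
      rows <- NULL
      for (r in seq_len(nRuns)) {
        x0 <- sample(0:80, 1)
        rows <- rbind(rows, data.frame(
          lesionId = r, slice = sample(0:5, 1), x0 = x0,
          x1 = x0 + sample(1:20, 1)
        ))
      }
      ann <- SubsidenceAnnotation(rows)
      bx <- annotationToBoxes(ann, c(10, 20))
      expect_identical(nrow(bx), nrow(annotationRuns(ann)))
      for (s in unique(bx$slice)) {
        cols <- unlist(lapply(which(bx$slice == s), function(i) bx$x0[i]:(bx$x1[i] - 1)))
        annCols <- unlist(lapply(
          which(annotationRuns(ann)$slice == s),
          function(i) annotationRuns(ann)$x0[i]:(annotationRuns(ann)$x1[i] - 1)
        ))
        expect_setequal(cols, annCols)
      }
    }
  })
})

test_that("annotation cuboids are the tight per-lesion bounds", {
  ann <- SubsidenceAnnotation(data.frame(
    lesionId = c(1L, 1L, 2L), slice = c(3L, 4L, 9L),
    x0 = c(10L, 14L, 50L), x1 = c(30L, 26L, 70L)
  ))
  cu <- annotationToCuboids(ann, c(40, 90))
  expect_identical(nrow(cu), 2L)
  l1 <- cu[cu$lesionId == 1, ]
  expect_equal(
    unlist(l1[c("s0", "s1", "x0", "x1", "z0", "z1")]),
    c(s0 = 3, s1 = 5, x0 = 10, x1 = 30, z0 = 40, z1 = 90)
  )
})

test_that("detections JSON round-trips geometry and confidence at full precision", {
  cu <- data.frame(
    s0 = c(1L, 5L, 7L), s1 = c(3L, 6L, 10L),
    x0 = c(10.25, 0, 40.125), x1 = c(30.5, 12, 66),
    z0 = c(40.1, 3, 8), z1 = c(90.9, 20, 60),
    confidence = c(0.4000000059604645, 1e-17, 0.9999999999999999)
  )
  p <- file.path(tempdir(), "det.json")
  writeDetections(cu, p)
  cu2 <- readDetections(p)
  expect_identical(cu2$confidence, cu$confidence)
  expect_identical(cu2$x0, cu$x0)
  ## empty list is valid JSON with zero records
  p0 <- file.path(tempdir(), "det0.json")
  writeDetections(emptyCuboids <- data.frame(
    s0 = integer(0), s1 = integer(0), x0 = numeric(0), x1 = numeric(0),
    z0 = numeric(0), z1 = numeric(0), confidence = numeric(0)
  ), p0)
  expect_identical(nrow(readDetections(p0)), 0L)
  writeLines("{\"cuboids\": oops", p)
  expect_error(readDetections(p), "malformed")
})

test_that("dataset index round-trips and rejects duplicate identities", {
  idx <- data.frame(
    participantId = c("P1", "P1"), eye = c("left", "right"),
    visitId = c("V0", "V0"), volumePath = c("a.tiff", "b.tiff"),
    annotationPath = c("a.json", "b.json"), hasSubsidence = c(TRUE, FALSE)
  )
  p <- file.path(tempdir(), "idx.csv")
  writeDatasetIndex(idx, p)
  expect_identical(readDatasetIndex(p), idx)
  dup <- idx
  dup$eye <- "left"
  expect_error(writeDatasetIndex(dup, p), "duplicate")
  expect_error(SubsideOCT:::checkDatasetIndex(idx[, -6]), "missing columns")
})
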