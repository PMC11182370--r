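gtCub <- function(lesionId, s0, s1, x0, x1, z0 = 0, z1 = 50) {
  n <- length(s0)
  data.frame(
    lesionId = as.integer(lesionId), s0 = s0, s1 = s1, x0 = x0, x1 = x1,
    z0 = rep_len(z0, n), z1 = rep_len(z1, n)
  )
}
predCub <- function(s0, s1, x0, x1, conf, z0 = 0, z1 = 50) {
  n <- length(s0)
  data.frame(
    s0 = s0, s1 = s1, x0 = x0, x1 = x1,
    z0 = rep_len(z0, n), z1 = rep_len(z1, n),
    confidence = conf
  )
}

test_that("matching applies the highest-confidence duplicate rule", {
  gt <- gtCub(1, 0, 4, 0, 40)
  ## two candidates over the same lesion: best is TP, other ignored, no FP
  cand <- rbind(
    predCub(0, 4, 10, 50, 0.6), # IoU 0.6 with GT
    predCub(0, 4, 5, 45, 0.9)
  )
  m <- matchDetections(cand, gt, iouMin = 0.25)
  expect_identical(nrow(m$tp), 1L)
  expect_equal(m$tp$confidence, 0.9)
  expect_identical(nrow(m$ignored), 1L)
  expect_equal(m$ignored$confidence, 0.6)
  expect_identical(nrow(m$fp), 0L)
  expect_identical(length(m$fnLesions), 0L)
  ## a candidate with no overlap is FP; a lesion with no candidate is FN
  m2 <- matchDetections(predCub(10, 12, 100, 140, 0.5), gt)
  expect_identical(nrow(m2$fp), 1L)
  expect_identical(m2$fnLesions, 1L)
  ## matching at the threshold is non-strict (IoU exactly 0.25 matches)
  candAt <- predCub(0, 4, 0, 160, 0.5) # IoU = 40/160 = 0.25
  expect_equal(SubsideOCT:::iouMatrix3d(candAt, gt)[1, 1], 0.25)
  expect_identical(nrow(matchDetections(candAt, gt, 0.25)$tp), 1L)
})

test_that("a candidate over two lesions goes to the higher-IoU one (tie: lower id)", {
  gt <- rbind(gtCub(1, 0, 4, 0, 20), gtCub(2, 0, 4, 30, 60))
  cand <- predCub(0, 4, 10, 55, 0.8) # IoU: lesion1 10/55..., lesion2 25/...
  m <- matchDetections(cand, gt, iouMin = 0.1)
  expect_identical(m$tp$lesionId, 2L)
  expect_identical(m$fnLesions, 1L)
  ## exact tie -> lower lesion id
  gtT <- rbind(gtCub(1, 0, 4, 0, 20), gtCub(2, 0, 4, 30, 50))
  candT <- predCub(0, 4, 10, 40, 0.8) # 10 columns overlap with each
  iouT <- SubsideOCT:::iouMatrix3d(candT, gtT)
  expect_equal(iouT[1, 1], iouT[1, 2])
  expect_identical(matchDetections(candT, gtT, 0.1)$tp$lesionId, 1L)
})

test_that("TP + FN always equals the lesion count (randomised volumes)", {
  withr::with_seed(5, {
    for (trial in 1:60) {
      nG <- sample(0:4, 1)
      gt <- if (nG) {
        do.call(rbind, lapply(seq_len(nG), function(j) {
          x0 <- runif(1, 0, 200)
          gtCub(j, sample(0:5, 1), sample(6:10, 1), x0, x0 + runif(1, 5, 50))
        }))
      } else {
        gtCub(integer(0), integer(0), integer(0), numeric(0), numeric(0))
      }
      nC <- sample(0:8, 1)
      cand <- if (nC) {
        do.call(rbind, lapply(seq_len(nC), function(j) {
          x0 <- runif(1, 0, 200)
          predCub(sample(0:5, 1), sample(6:10, 1), x0, x0 + runif(1, 5, 60), runif(1))
        }))
      } else {
        predCub(integer(0), integer(0), numeric(0), numeric(0), numeric(0))
      }
      m <- matchDetections(cand, gt)
      expect_identical(nrow(m$tp) + length(m$fnLesions), nrow(gt))
      expect_identical(nrow(m$tp) + nrow(m$fp) + nrow(m$ignored), nrow(cand))
      ## candidate order invariance
      if (nrow(cand) > 1) {
        m2 <- matchDetections(cand[sample(nrow(cand)), ], gt)
        expect_identical(nrow(m2$tp), nrow(m$tp))
        expect_identical(sort(m2$fnLesions), sort(m$fnLesions))
      }
    }
  })
})

test_that("the FROC curve follows the hand-enumerated 3-candidate scenario", {
  ## 2 volumes, 2 GT lesions; candidates: TP 0.9, FP 0.8, TP 0.4
  gt1 <- gtCub(1, 0, 4, 0, 40)
  m1 <- matchDetections(rbind(predCub(0, 4, 0, 40, 0.9), predCub(0, 4, 100, 140, 0.8)), gt1)
  gt2 <- gtCub(1, 0, 4, 0, 40)
  m2 <- matchDetections(predCub(0, 4, 2, 42, 0.4), gt2)
  fr <- frocCurve(list(m1, m2))
  pts <- fr$points
  expect_equal(pts$sensitivity[pts$threshold == 0.9], 0.5)
  expect_equal(pts$fpPerVolume[pts$threshold == 0.9], 0)
  ## at t in (0.4, 0.8]: sens 0.5 at 0.5 FP/volume
  expect_equal(pts$sensitivity[pts$threshold == 0.8], 0.5)
  expect_equal(pts$fpPerVolume[pts$threshold == 0.8], 0.5)
  ## at t <= 0.4: sens 1.0 at 0.5 FP/volume
  expect_equal(pts$sensitivity[pts$threshold == 0.4], 1.0)
  expect_equal(pts$fpPerVolume[pts$threshold == 0.4], 0.5)
  expect_equal(unname(fr$sensAt["1"]), 1.0)
})

test_that("FROC endpoints: perfect detector and all-FP detector", {
  gt <- gtCub(1, 0, 4, 0, 40)
  perfect <- frocCurve(list(matchDetections(predCub(0, 4, 0, 40, 0.99), gt)))
  expect_equal(perfect$points$sensitivity[1], 1.0)
  expect_equal(perfect$points$fpPerVolume[1], 0.0)
  allFp <- frocCurve(list(
    matchDetections(predCub(0, 4, 100, 140, 0.7), gt)
  ))
  expect_true(all(allFp$points$sensitivity == 0))
  expect_error(frocCurve(list(matchDetections(
    predCub(0, 4, 0, 40, 0.5),
    gtCub(integer(0), integer(0), integer(0), numeric(0), numeric(0))
  ))), "ground-truth")
  ## sensitivity is non-decreasing along the FP axis
  expect_true(all(diff(perfect$points$sensitivity) >= -1e-12))
})

test_that("ROC AUC equals pairwise concordance with ties counting half", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  ## pos {0.9, 0.4}, neg {0.6, 0.1} -> 3/4 concordant pairs
  expect_equal(rocAuc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))$auc, 0.75)
  expect_error(rocAuc(c(1, 2), c(1, 1)), "both classes")
  withr::with_seed(31, {
    for (trial in 1:30) {
      n <- sample(2:60, 1)
      sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # many ties
      lb <- sample(0:1, n, replace = TRUE)
      if (length(unique(lb)) < 2) next
      expect_equal(rocAuc(sc, lb)$auc, aucPairOracle(sc, lb))
    }
    ## random labels at n = 10^4: AUC 0.5 within 0.02
    sc <- runif(10000)
    lb <- sample(0:1, 10000, replace = TRUE)
    expect_lt(abs(rocAuc(sc, lb)$auc - 0.5), 0.02)
  })
})

test_that("ROC AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    sc <- runif(200)
    lb <- sample(0:1, 200, replace = TRUE)
    ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(lb, sc, direction = "<"))))
    expect_equal(rocAuc(sc, lb)$auc, ref)
  })
})

test_that("average precision is the recall-weighted mean of precisions", {
  expect_equal(prAp(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$ap, 1.0)
  expect_equal(prAp(c(runif(10, 0.5, 1), runif(90, 0, 0.5)), rep(1:0, c(10, 90)))$baseline, 0.1)
  ## scores {pos .9, neg .8, pos .7} -> AP = 5/6
  r <- prAp(c(0.9, 0.8, 0.7), c(1, 0, 1))
  expect_equal(r$ap, 5 / 6)
  expect_equal(r$points$recall, c(0.5, 0.5, 1.0))
  expect_equal(r$points$precision, c(1.0, 0.5, 2 / 3))
  expect_error(prAp(c(0.5, 0.4), c(0, 0)), "positive")
  ## property: equals the independent per-positive step oracle
  withr::with_seed(17, {
    for (trial in 1:30) {
      n <- sample(3:80, 1)
      sc <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
      lb <- sample(0:1, n, replace = TRUE)
      if (!any(lb == 1)) next
      expect_equal(prAp(sc, lb)$ap, apStepOracle(sc, lb))
    }
  })
})

test_that("hierarchical aggregation takes the max within eye and participant", {
  vs <- data.frame(
    participantId = c("P1", "P1", "P1", "P2"),
    eye = c("left", "left", "right", "left"),
    visitId = c("V0", "V1", "V0", "V0"),
    score = c(0.2, 0.8, 0.3, 0.5),
    label = c(TRUE, FALSE, FALSE, FALSE)
  )
  eye <- aggregateConfidence(vs, "eye")
  expect_equal(sort(eye$score), c(0.3, 0.5, 0.8))
  expect_true(eye$label[eye$participantId == "P1" & eye$eye == "left"])
  part <- aggregateConfidence(vs, "participant")
  expect_equal(part$score[part$participantId == "P1"], 0.8)
  expect_true(part$label[part$participantId == "P1"])
  ## volume level is the identity mapping
  vol <- aggregateConfidence(vs, "volume")
  expect_identical(nrow(vol), 4L)
  expect_setequal(vol$score, vs$score)
  ## idempotence at a fixed level
  part2 <- aggregateConfidence(
    transform(part, eye = "left", visitId = "V0"), "participant"
  )
  expect_equal(part2$score, part$score[order(part$participantId)])
  ## rank metrics are unchanged under monotone transforms of scores
  vs2 <- transform(vs, score = score^3)
  expect_equal(
    rank(aggregateConfidence(vs2, "participant")$score),
    rank(part$score)
  )
  expect_error(aggregateConfidence(vs[0, ], "eye"), "empty")
})

test_that("stratified folds partition participants with balanced positives", {
  ## index replicating the development cohort: 140 participants, 46 positive
  idx <- do.call(rbind, lapply(1:140, function(i) {
    data.frame(
      participantId = sprintf("P%03d", i), eye = c("left", "right"),
      visitId = "V0",
      volumePath = sprintf("v%03d_%s.tiff", i, c("l", "r")),
      annotationPath = sprintf("a%03d_%s.json", i, c("l", "r")),
      hasSubsidence = c(i <= 46, FALSE)
    )
  }))
  fa <- stratifiedFolds(idx, k = 10, seed = 4)
  a <- fa$assignment
  expect_identical(nrow(a), 140L)
  sizes <- table(a$fold)
  expect_true(all(sizes == 14))
  posPerFold <- tapply(a$positive, a$fold, sum)
  expect_true(all(posPerFold %in% c(4, 5)))
  expect_equal(sum(posPerFold), 46)
  ## all volumes/eyes of a participant share the fold by construction
  foldOf <- setNames(a$fold, a$participantId)
  expect_true(all(tapply(foldOf[idx$participantId], idx$participantId, function(x) length(unique(x))) == 1))
  ## determinism and seed sensitivity
  expect_identical(stratifiedFolds(idx, 10, seed = 4)$assignment, a)
  expect_error(stratifiedFolds(idx, k = 1), "at least 2")
  expect_error(stratifiedFolds(idx, k = 141), "exceeds")
})

test_that("cross-validated evaluation runs end to end on a small dataset", {
  ds <- tinyDataset()
  cv <- runCvEvaluation(
    ds$index,
    cmCfg = cmConfig(inputSize = 96, epochs = 6, seed = 2),
    dmCfg = dmConfig(inputSize = 96, epochs = 5, seed = 2),
    k = 2, seed = 11, depthWindow = ds$depthWindow
  )
  expect_length(cv$folds, 2L)
  expect_true(all(c("metric", "mean", "sd") %in% names(cv$summary)))
  expect_true("auc.volume" %in% cv$summary$metric)
  ## mean across folds is the arithmetic mean of per-fold values
  aucs <- vapply(cv$folds, function(f) f$levels$volume$roc$auc, numeric(1))
  expect_equal(cv$summary$mean[cv$summary$metric == "auc.volume"], mean(aucs))
  ## per-fold sensitivity at 1 FP lies within the fold envelope of the mean
  sens <- vapply(cv$folds, function(f) unname(f$froc$sensAt["1"]), numeric(1))
  m <- cv$summary$mean[cv$summary$metric == "sensitivity@1FP"]
  expect_gte(m, min(sens) - 1e-12)
  expect_lte(m, max(sens) + 1e-12)
  ## pooled volume-level curves exist and are in range
  expect_true(cv$pooled$roc$auc >= 0 && cv$pooled$roc$auc <= 1)
  ## every volume was scored exactly once
  expect_identical(nrow(cv$volumeScores), nrow(ds$index))
})
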