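## Evaluation protocol: 3D IoU matching with the highest-confidence
## duplicate rule, FROC (sensitivity vs FP/volume), ROC/AUC, PR/AP with
## the P/(P+N) baseline, hierarchical max-aggregation to eye and
## participant level, and stratified participant-level k-fold CV.

iouMatrix3d <- function(A, B) {
  if (!nrow(A) || !nrow(B)) {
    return(matrix(0, nrow(A), nrow(B)))
  }
  is_ <- pmax(0, outer(A$s1, B$s1, pmin) - outer(A$s0, B$s0, pmax))
  ix <- pmax(0, outer(A$x1, B$x1, pmin) - outer(A$x0, B$x0, pmax))
  iz <- pmax(0, outer(A$z1, B$z1, pmin) - outer(A$z0, B$z0, pmax))
  inter <- is_ * ix * iz
  volA <- (A$s1 - A$s0) * (A$x1 - A$x0) * (A$z1 - A$z0)
  volB <- (B$s1 - B$s0) * (B$x1 - B$x0) * (B$z1 - B$z0)
  inter / (outer(volA, volB, `+`) - inter)
}

#' Match predicted cuboids against ground-truth lesions
#'
#' For each ground-truth lesion, among the predicted cuboids with 3D
#' IoU at least \code{iouMin} (non-strict), the highest-confidence one
#' is the true positive and the remaining overlapping candidates are
#' ignored (counted neither TP nor FP). Cuboids overlapping no lesion
#' are false positives; lesions with no candidate are false negatives.
#' A cuboid overlapping several lesions is assigned to the lesion with
#' the highest IoU (ties to the lower lesion id). Ties in confidence
#' are broken by higher IoU, then input order.
#'
#' @param cuboids predicted cuboid data.frame (one volume).
#' @param gtCuboids ground-truth cuboids with \code{lesionId} (see
#'   \code{\link{annotationToCuboids}}).
#' @param iouMin matching threshold (default 0.25, non-strict).
#' @return a \code{MatchResult}: list with \code{tp} (data.frame of
#'   cuboid/lesion pairs with confidence), \code{fp}, \code{ignored}
#'   (cuboid data.frames), \code{fnLesions} (lesion ids) and \code{nGT}.
#' @export
matchDetections <- function(cuboids, gtCuboids, iouMin = 0.25) {
  nC <- nrow(cuboids)
  gtCuboids <- gtCuboids[order(gtCuboids$lesionId), , drop = FALSE]
  nG <- nrow(gtCuboids)
  assigned <- rep(NA_integer_, nC)
  assignedIou <- rep(0, nC)
  if (nC && nG) {
    iou <- iouMatrix3d(cuboids, gtCuboids)
    for (i in seq_len(nC)) {
      ok <- which(iou[i, ] >= iouMin)
      if (length(ok)) {
        j <- ok[which.max(iou[i, ok])] # ties: first = lower lesionId
        assigned[i] <- j
        assignedIou[i] <- iou[i, j]
      }
    }
  }
  tp <- NULL
  ignored <- emptyCuboids()
  fn <- integer(0)
  for (j in seq_len(nG)) {
    cand <- which(assigned == j)
    if (!length(cand)) {
      fn <- c(fn, gtCuboids$lesionId[j])
      next
    }
    best <- cand[order(-cuboids$confidence[cand], -assignedIou[cand], cand)][1L]
    tp <- rbind(tp, data.frame(
      cuboidIndex = best, lesionId = gtCuboids$lesionId[j],
      confidence = cuboids$confidence[best], iou = assignedIou[best]
    ))
    ignored <- rbind(ignored, cuboids[setdiff(cand, best),
      c("s0", "s1", "x0", "x1", "z0", "z1", "confidence"),
      drop = FALSE
    ])
  }
  fp <- if (nC) {
    cuboids[is.na(assigned), c("s0", "s1", "x0", "x1", "z0", "z1", "confidence"), drop = FALSE]
  } else {
    emptyCuboids()
  }
  structure(
    list(
      tp = if (is.null(tp)) {
        data.frame(
          cuboidIndex = integer(0), lesionId = integer(0),
          confidence = numeric(0), iou = numeric(0)
        )
      } else {
        tp
      },
      fp = fp, ignored = ignored, fnLesions = fn, nGT = nG
    ),
    class = "MatchResult"
  )
}

#' FROC curve over a set of volumes
#'
#' Matching is computed once with every candidate retained (threshold
#' 0); the confidence threshold is then swept over the sorted candidate
#' confidences. At each threshold, sensitivity is the fraction of all
#' ground-truth lesions whose true-positive candidate survives, and the
#' abscissa is the number of surviving false positives divided by the
#' number of volumes. Sensitivity at 1, 2 and 3 FP/volume is linearly
#' interpolated between curve points (constant beyond the ends).
#'
#' @param matchResults list of \code{MatchResult}, one per evaluated
#'   volume (positives and negatives alike).
#' @return list with \code{points} (threshold, fpPerVolume,
#'   sensitivity) and \code{sensAt} (named vector at 1, 2, 3
#'   FP/volume).
#' @export
frocCurve <- function(matchResults) {
  nVol <- length(matchResults)
  totalGT <- sum(vapply(matchResults, function(m) m$nGT, numeric(1)))
  if (totalGT == 0) {
    stop("FROC requires at least one ground-truth lesion")
  }
  tpConf <- unlist(lapply(matchResults, function(m) m$tp$confidence))
  fpConf <- unlist(lapply(matchResults, function(m) m$fp$confidence))
  thr <- sort(unique(c(tpConf, fpConf)), decreasing = TRUE)
  if (!length(thr)) {
    pts <- data.frame(threshold = Inf, fpPerVolume = 0, sensitivity = 0)
  } else {
    pts <- data.frame(
      threshold = thr,
      fpPerVolume = vapply(thr, function(t) sum(fpConf >= t), numeric(1)) / nVol,
      sensitivity = vapply(thr, function(t) sum(tpConf >= t), numeric(1)) / totalGT
    )
  }
  sensAtFp <- function(fp) {
    if (nrow(pts) == 1L) {
      return(if (fp >= pts$fpPerVolume[1L]) pts$sensitivity[1L] else 0)
    }
    ## step curve upper envelope: keep max sensitivity per abscissa
    env <- tapply(pts$sensitivity, pts$fpPerVolume, max)
    x <- as.numeric(names(env))
    y <- as.numeric(env)
    if (length(x) == 1L) {
      return(if (fp >= x) y else 0)
    }
    approx(x, y, xout = fp, rule = 2)$y
  }
  list(
    points = pts,
    sensAt = c(`1` = sensAtFp(1), `2` = sensAtFp(2), `3` = sensAtFp(3))
  )
}

#' ROC curve and AUC
#'
#' AUC is the probability that a random positive outranks a random
#' negative, with ties counting one half (rank statistic); 0.5 is a
#' random predictor, 1 a perfect classifier.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (logical or 0/1).
#' @return list with \code{points} (threshold, fpr, tpr) and
#'   \code{auc}.
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.numeric(labels)
  nPos <- sum(labels == 1)
  nNeg <- sum(labels == 0)
  if (nPos == 0 || nNeg == 0) {
    stop("ROC requires both classes")
  }
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, vapply(thr, function(t) sum(scores >= t & labels == 0), numeric(1)) / nNeg),
    tpr = c(0, vapply(thr, function(t) sum(scores >= t & labels == 1), numeric(1)) / nPos)
  )
  list(points = pts, auc = auc)
}

#' Precision-recall curve and average precision
#'
#' AP is the weighted mean of the precisions achieved at each
#' threshold, weighted by the increase in recall from the previous
#' threshold; the chance baseline is P/(P+N).
#'
#' @inheritParams rocAuc
#' @return list with \code{points} (threshold, recall, precision),
#'   \code{ap} and \code{baseline}.
#' @export
prAp <- function(scores, labels) {
  labels <- as.numeric(labels)
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0) {
    stop("PR requires at least one positive")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0), numeric(1))
  recall <- tp / P
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 1)
  ap <- sum(diff(c(0, recall)) * precision)
  list(
    points = data.frame(threshold = thr, recall = recall, precision = precision),
    ap = ap, baseline = P / (P + N)
  )
}

#' Aggregate volume scores hierarchically
#'
#' Each eye is attributed the maximum confidence over its volumes; each
#' participant the maximum over the volumes of both eyes. A unit is
#' labelled positive if any member volume contains a lesion.
#'
#' @param volumeScores data.frame with columns
#'   \code{participantId, eye, visitId, score, label}.
#' @param level \code{"volume"}, \code{"eye"} or \code{"participant"}.
#' @return data.frame of scored units with \code{score} and
#'   \code{label}.
#' @export
aggregateConfidence <- function(volumeScores, level = c("volume", "eye", "participant")) {
  level <- match.arg(level)
  if (!nrow(volumeScores)) {
    stop("empty score table")
  }
  key <- switch(level,
    volume = paste(volumeScores$participantId, volumeScores$eye, volumeScores$visitId),
    eye = paste(volumeScores$participantId, volumeScores$eye),
    participant = volumeScores$participantId
  )
  parts <- split(volumeScores, key)
  out <- do.call(rbind, lapply(parts, function(g) {
    data.frame(
      participantId = g$participantId[1L],
      eye = if (level == "participant") NA_character_ else g$eye[1L],
      visitId = if (level == "volume") g$visitId[1L] else NA_character_,
      score = max(g$score), label = any(g$label)
    )
  }))
  rownames(out) <- NULL
  out
}

#' Stratified participant-level fold assignment
#'
#' Partitions participants (never volumes or eyes, so both eyes and all
#' visits of a participant share a fold) into k folds while keeping the
#' number of subsidence-positive participants per fold within one of
#' each other; negative participants are dealt to equalise fold sizes.
#' Deterministic given the seed.
#'
#' @param index dataset index data.frame.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return a \code{FoldAssignment}: list with \code{assignment}
#'   (participantId, positive, fold in \code{[0, k)}) and \code{k}.
#' @export
stratifiedFolds <- function(index, k = 10, seed = 1L) {
  checkDatasetIndex(index)
  posByPart <- tapply(index$hasSubsidence, index$participantId, any)
  parts <- names(posByPart)
  if (k < 2) {
    stop("k must be at least 2")
  }
  if (k > length(parts)) {
    stop("k exceeds the number of participants")
  }
  withSeed(deriveSeed(seed, "folds"), {
    posParts <- sample(parts[posByPart])
    negParts <- sample(parts[!posByPart])
    fold <- setNames(integer(0), character(0))
    ## deal positives round-robin
    if (length(posParts)) {
      fold[posParts] <- (seq_along(posParts) - 1L) %% k
    }
    ## deal negatives to the currently smallest fold (ties: lower index)
    sizes <- tabulate(fold + 1L, nbins = k)
    for (p in negParts) {
      f <- which.min(sizes) - 1L
      fold[p] <- f
      sizes[f + 1L] <- sizes[f + 1L] + 1L
    }
    structure(
      list(
        assignment = data.frame(
          participantId = names(fold),
          positive = as.logical(posByPart[names(fold)]),
          fold = as.integer(fold)
        ),
        k = as.integer(k)
      ),
      class = "FoldAssignment"
    )
  })
}

#' Cross-validated training and evaluation of the full pipeline
#'
#' Runs stratified participant-level k-fold cross-validation: per fold,
#' CM and DM are trained on the training participants, every held-out
#' volume is predicted, predicted cuboids are matched to ground-truth
#' lesions (3D IoU >= \code{iouMin}, highest-confidence duplicate
#' rule), and per-fold FROC plus volume/eye/participant ROC and PR
#' curves are computed. The summary reports per-fold and mean +/- sd of
#' sensitivity at 1/2/3 FP per volume and of AUC/AP at each level;
#' volume-level pooled-over-folds curves are also provided.
#'
#' @param index dataset index data.frame.
#' @param cmCfg,dmCfg module configurations (per-fold seeds are derived
#'   from \code{seed}).
#' @param k number of folds.
#' @param seed integer seed (folds + per-fold training).
#' @param depthWindow ground-truth depth window (see
#'   \code{\link{annotationToBoxes}}).
#' @param iouMin detection matching threshold.
#' @param mergeIou adjacent-slice merge threshold (strict).
#' @param verbose emit progress messages.
#' @return list with \code{folds} (per-fold curves), \code{summary}
#'   (data.frame of mean/sd metrics), \code{pooled} (volume-level
#'   pooled ROC/PR), \code{volumeScores} and \code{foldAssignment}.
#' @export
runCvEvaluation <- function(index, cmCfg = cmConfig(), dmCfg = dmConfig(),
                            k = 10, seed = 1L, depthWindow,
                            iouMin = 0.25, mergeIou = 0.5, verbose = FALSE) {
  checkDatasetIndex(index)
  fa <- stratifiedFolds(index, k = k, seed = seed)
  foldOf <- setNames(fa$assignment$fold, fa$assignment$participantId)
  folds <- list()
  allScores <- NULL
  for (f in seq_len(k) - 1L) {
    testIdx <- index[foldOf[index$participantId] == f, , drop = FALSE]
    trainIdx <- index[foldOf[index$participantId] != f, , drop = FALSE]
    if (verbose) {
      message(sprintf(
        "fold %d: %d train / %d test volumes", f, nrow(trainIdx), nrow(testIdx)
      ))
    }
    cmCfgF <- cmCfg
    cmCfgF$seed <- deriveSeed(seed, paste0("cm-fold", f))
    dmCfgF <- dmCfg
    dmCfgF$seed <- deriveSeed(seed, paste0("dm-fold", f))
    cm <- trainCM(trainIdx, cmCfgF)
    dm <- trainDM(trainIdx, dmCfgF, depthWindow = depthWindow)
    matches <- list()
    scores <- NULL
    for (i in seq_len(nrow(testIdx))) {
      vol <- loadVolume(testIdx$volumePath[i])
      ann <- readAnnotation(testIdx$annotationPath[i])
      pred <- predictVolume(vol, cm, dm, iouThreshold = mergeIou)
      gt <- annotationToCuboids(ann, depthWindow, volumeDepth = axialSize(vol))
      matches[[i]] <- matchDetections(pred$cuboids, gt, iouMin = iouMin)
      scores <- rbind(scores, data.frame(
        participantId = testIdx$participantId[i], eye = testIdx$eye[i],
        visitId = testIdx$visitId[i], score = pred$score,
        label = testIdx$hasSubsidence[i], fold = f
      ))
    }
    froc <- if (sum(vapply(matches, function(m) m$nGT, numeric(1))) > 0) {
      frocCurve(matches)
    } else {
      NULL
    }
    levelCurves <- lapply(
      c(volume = "volume", eye = "eye", participant = "participant"),
      function(lv) {
        u <- aggregateConfidence(scores, lv)
        if (length(unique(u$label)) < 2L) {
          return(NULL)
        }
        list(roc = rocAuc(u$score, u$label), pr = prAp(u$score, u$label))
      }
    )
    folds[[f + 1L]] <- list(
      foldId = f, froc = froc, levels = levelCurves,
      cmLog = cm$log, dmLog = dm$log
    )
    allScores <- rbind(allScores, scores)
  }
  ## summary: mean +/- sd across folds
  pick <- function(fn) vapply(folds, function(fd) fn(fd) %||% NA_real_, numeric(1))
  rows <- list(
    c(metric = "sensitivity@1FP", fn = function(fd) unname(fd$froc$sensAt["1"])),
    c(metric = "sensitivity@2FP", fn = function(fd) unname(fd$froc$sensAt["2"])),
    c(metric = "sensitivity@3FP", fn = function(fd) unname(fd$froc$sensAt["3"]))
  )
  summary <- NULL
  addRow <- function(metric, vals) {
    data.frame(
      metric = metric, mean = mean(vals, na.rm = TRUE),
      sd = if (sum(!is.na(vals)) > 1) sd(vals, na.rm = TRUE) else NA_real_,
      nFolds = sum(!is.na(vals))
    )
  }
  for (r in rows) {
    summary <- rbind(summary, addRow(r$metric, pick(function(fd) {
      if (is.null(fd$froc)) NA_real_ else r$fn(fd)
    })))
  }
  for (lv in c("volume", "eye", "participant")) {
    summary <- rbind(
      summary,
      addRow(paste0("auc.", lv), pick(function(fd) {
        if (is.null(fd$levels[[lv]])) NA_real_ else fd$levels[[lv]]$roc$auc
      })),
      addRow(paste0("ap.", lv), pick(function(fd) {
        if (is.null(fd$levels[[lv]])) NA_real_ else fd$levels[[lv]]$pr$ap
      }))
    )
  }
  pooled <- NULL
  if (length(unique(allScores$label)) == 2L) {
    pooled <- list(
      roc = rocAuc(allScores$score, allScores$label),
      pr = prAp(allScores$score, allScores$label)
    )
  }
  list(
    folds = folds, summary = summary, pooled = pooled,
    volumeScores = allScores, foldAssignment = fa
  )
}
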