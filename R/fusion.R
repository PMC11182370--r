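## Prediction-stage fusion: candidate confidences are the product of
## the detector score and the B-scan classification score; candidates
## overlapping on adjacent B-scans (in-plane IoU strictly above 0.5)
## are merged transitively into minimum enclosing cuboids whose
## confidence is the maximum member confidence.

#' Fuse detector candidates with the B-scan classification score
#'
#' Each candidate's confidence becomes \code{dmScore * cmScore}; the
#' geometry and ordering are unchanged, and the source tag flips to
#' \code{"fused"}. The fused confidence is high only when both modules
#' agree.
#'
#' @param dmBoxes scored box data.frame for one B-scan
#'   (\code{source = "dm_raw"}).
#' @param cmScoreS the B-scan's classification score in [0, 1].
#' @return the fused scored box data.frame.
#' @export
fuseScores <- function(dmBoxes, cmScoreS) {
  if (cmScoreS < 0 || cmScoreS > 1) {
    stop("classification score outside [0, 1]")
  }
  if (nrow(dmBoxes) && any(dmBoxes$score < 0 | dmBoxes$score > 1)) {
    stop("detector score outside [0, 1]")
  }
  dmBoxes$score <- dmBoxes$score * cmScoreS
  if (nrow(dmBoxes)) dmBoxes$source <- "fused"
  dmBoxes
}

#' Merge candidates across neighboring B-scans into cuboids
#'
#' Builds a graph with candidate boxes as nodes and edges between boxes
#' on adjacent slices (slice distance exactly 1) whose in-plane IoU
#' strictly exceeds the threshold; connected components become cuboids.
#' Each cuboid is the minimum enclosing extent of its members (tight
#' slice interval and lateral/depth bounds) and carries the maximum
#' member confidence. Boxes on the same slice are never merged with
#' each other directly; isolated boxes become single-slice cuboids. A
#' slice gap breaks a component (no gap bridging).
#'
#' @param boxes scored box data.frame over all slices of one volume.
#' @param iouThreshold merge threshold (default 0.5, strict: a pair at
#'   exactly the threshold is \emph{not} merged).
#' @param includeMembers attach the member boxes of each cuboid as a
#'   list column.
#' @return cuboid data.frame
#'   (\code{s0, s1, x0, x1, z0, z1, confidence}).
#' @export
mergeAcrossScans <- function(boxes, iouThreshold = 0.5, includeMembers = FALSE) {
  n <- nrow(boxes)
  if (!n) {
    return(emptyCuboids())
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i)
    rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  bySlice <- split(seq_len(n), boxes$slice)
  sliceIds <- as.integer(names(bySlice))
  for (k in seq_along(sliceIds)) {
    nxt <- which(sliceIds == sliceIds[k] + 1L)
    if (!length(nxt)) next
    A <- bySlice[[k]]
    B <- bySlice[[nxt]]
    iou <- iouMatrix2d(
      boxes[A, , drop = FALSE], boxes[B, , drop = FALSE]
    )
    hits <- which(iou > iouThreshold, arr.ind = TRUE)
    for (h in seq_len(nrow(hits))) {
      union_(A[hits[h, 1L]], B[hits[h, 2L]])
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- lapply(unique(comp), function(cid) {
    boxes[comp == cid, , drop = FALSE]
  })
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(
      s0 = min(g$slice), s1 = max(g$slice) + 1L,
      x0 = min(g$x0), x1 = max(g$x1),
      z0 = min(g$z0), z1 = max(g$z1),
      confidence = max(g$score)
    )
  }))
  ord <- order(out$s0, out$x0, out$z0)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (includeMembers) {
    out$members <- I(groups[ord])
  }
  out
}

#' Volume-level subsidence confidence
#'
#' The maximum cuboid confidence; 0 for an empty candidate list ("no
#' evidence").
#'
#' @param cuboids cuboid data.frame.
#' @return numeric score in [0, 1].
#' @export
volumeConfidence <- function(cuboids) {
  if (is.null(cuboids) || !nrow(cuboids)) {
    return(0)
  }
  max(cuboids$confidence)
}

#' Run the full two-stage pipeline on one volume
#'
#' For every B-scan, builds the neighbor stack, runs the detector and
#' the classifier, multiplies the candidate scores by the B-scan score,
#' then merges candidates across adjacent B-scans into cuboids. Equals
#' the manual composition of \code{\link{dmDetect}},
#' \code{\link{cmScore}}, \code{\link{fuseScores}} and
#' \code{\link{mergeAcrossScans}}; deterministic at inference.
#'
#' @param volume an \linkS4class{OCTVolume}.
#' @param cm,dm trained model handles.
#' @param iouThreshold adjacent-slice merge threshold (strict).
#' @return list with \code{cuboids} and the volume-level \code{score}.
#' @export
predictVolume <- function(volume, cm, dm, iouThreshold = 0.5) {
  fusedAll <- emptyScoredBoxes()
  volCache <- new.env(parent = emptyenv())
  for (s in seq_len(nSlices(volume)) - 1L) {
    stDm <- makeNeighborStack(volume, s, dm$inputSize, cache = volCache)
    cand <- dmDetect(dm, stDm)
    if (!nrow(cand)) next
    stCm <- if (cm$inputSize == dm$inputSize) {
      stDm
    } else {
      makeNeighborStack(volume, s, cm$inputSize, cache = volCache)
    }
    fusedAll <- rbind(fusedAll, fuseScores(cand, cmScore(cm, stCm)))
  }
  cuboids <- mergeAcrossScans(fusedAll, iouThreshold)
  list(cuboids = cuboids, score = volumeConfidence(cuboids))
}
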