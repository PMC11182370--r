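## Axis-aligned boxes and cuboids are exchanged as plain data.frames:
##   2D boxes:  slice, x0, x1, z0, z1 [, score, source]
##   cuboids:   s0, s1, x0, x1, z0, z1, confidence [, members (list column)]
## All coordinates 0-based, all intervals half-open, so
## area = (x1-x0)*(z1-z0) and volume = (s1-s0)*(x1-x0)*(z1-z0).

#' Construct per-B-scan candidate boxes
#'
#' Builds the data.frame representation of axis-aligned per-slice boxes.
#' \code{box2d} creates unscored boxes; \code{scoredBoxes} attaches
#' confidences (in \code{[0,1]}) and a provenance tag (\code{"dm_raw"}
#' for raw detector output, \code{"fused"} after multiplication with the
#' B-scan classification score).
#'
#' @param slice,x0,x1,z0,z1 box coordinates (vectors recycle); lateral
#'   extent \code{[x0,x1)} in columns, depth extent \code{[z0,z1)} in rows.
#' @return data.frame with one row per box.
#' @examples
#' box2d(slice = 7, x0 = 100, x1 = 141, z0 = 200, z1 = 300)
#' @export
box2d <- function(slice, x0, x1, z0, z1) {
  df <- data.frame(
    slice = as.integer(slice), x0 = as.numeric(x0), x1 = as.numeric(x1),
    z0 = as.numeric(z0), z1 = as.numeric(z1)
  )
  if (nrow(df) && (any(df$x0 >= df$x1) || any(df$z0 >= df$z1))) {
    stop("degenerate box: need x0 < x1 and z0 < z1")
  }
  df
}

#' @rdname box2d
#' @param boxes data.frame of boxes as returned by \code{box2d}.
#' @param score numeric confidence(s) in [0, 1].
#' @param source provenance, \code{"dm_raw"} or \code{"fused"}.
#' @export
scoredBoxes <- function(boxes, score, source = "dm_raw") {
  source <- match.arg(source, c("dm_raw", "fused"))
  if (any(score < 0 | score > 1)) {
    stop("box scores must lie in [0, 1]")
  }
  boxes$score <- as.numeric(score)
  boxes$source <- rep_len(source, nrow(boxes))
  boxes
}

emptyScoredBoxes <- function() {
  data.frame(
    slice = integer(0), x0 = numeric(0), x1 = numeric(0),
    z0 = numeric(0), z1 = numeric(0), score = numeric(0),
    source = character(0)
  )
}

#' Intersection-over-union of two 2D boxes
#'
#' Overlap of the lateral x depth extents of two boxes with half-open
#' interval semantics (the \code{slice} field, if present, is ignored:
#' the measure is purely in-plane, as used when deciding whether
#' candidates on adjacent B-scans belong to the same lesion).
#'
#' @param a,b single boxes: one-row data.frames (or lists) with fields
#'   \code{x0, x1, z0, z1}.
#' @return IoU in [0, 1]; symmetric in its arguments.
#' @examples
#' a <- box2d(0, 0, 10, 0, 10)
#' b <- box2d(1, 5, 15, 0, 10)
#' iou2d(a, b) # 50 / 150 = 1/3
#' @export
iou2d <- function(a, b) {
  areaA <- (a$x1 - a$x0) * (a$z1 - a$z0)
  areaB <- (b$x1 - b$x0) * (b$z1 - b$z0)
  if (any(areaA <= 0) || any(areaB <= 0)) {
    stop("degenerate box: zero area")
  }
  ix <- pmax(0, pmin(a$x1, b$x1) - pmax(a$x0, b$x0))
  iz <- pmax(0, pmin(a$z1, b$z1) - pmax(a$z0, b$z0))
  inter <- ix * iz
  inter / (areaA + areaB - inter)
}

## Pairwise IoU matrix between two box tables (vectorised; used by the
## detector's suppression, the merger and the matcher).
iouMatrix2d <- function(A, B) {
  if (!nrow(A) || !nrow(B)) {
    return(matrix(0, nrow(A), nrow(B)))
  }
  ix <- pmax(
    0,
    outer(A$x1, B$x1, pmin) - outer(A$x0, B$x0, pmax)
  )
  iz <- pmax(
    0,
    outer(A$z1, B$z1, pmin) - outer(A$z0, B$z0, pmax)
  )
  inter <- ix * iz
  areaA <- (A$x1 - A$x0) * (A$z1 - A$z0)
  areaB <- (B$x1 - B$x0) * (B$z1 - B$z0)
  inter / (outer(areaA, areaB, `+`) - inter)
}

#' Intersection-over-union of two 3D cuboids
#'
#' Voxel-wise overlap of two axis-aligned cuboids (slice interval x
#' lateral extent x depth extent, all half-open). This is the measure
#' used to decide whether a predicted cuboid matches a ground-truth
#' lesion (match threshold 0.25, non-strict).
#'
#' @param a,b one-row data.frames (or lists) with fields
#'   \code{s0, s1, x0, x1, z0, z1}.
#' @return IoU in [0, 1].
#' @export
iou3d <- function(a, b) {
  volA <- (a$s1 - a$s0) * (a$x1 - a$x0) * (a$z1 - a$z0)
  volB <- (b$s1 - b$s0) * (b$x1 - b$x0) * (b$z1 - b$z0)
  if (any(volA <= 0) || any(volB <= 0)) {
    stop("degenerate cuboid: zero volume")
  }
  is_ <- pmax(0, pmin(a$s1, b$s1) - pmax(a$s0, b$s0))
  ix <- pmax(0, pmin(a$x1, b$x1) - pmax(a$x0, b$x0))
  iz <- pmax(0, pmin(a$z1, b$z1) - pmax(a$z0, b$z0))
  inter <- is_ * ix * iz
  inter / (volA + volB - inter)
}

emptyCuboids <- function() {
  data.frame(
    s0 = integer(0), s1 = integer(0), x0 = numeric(0), x1 = numeric(0),
    z0 = numeric(0), z1 = numeric(0), confidence = numeric(0)
  )
}

#' Greedy non-maximum suppression of same-slice boxes
#'
#' Keeps the higher-scoring box of any pair overlapping above the IoU
#' threshold; applied within one B-scan to the detector's raw output so
#' that duplicated candidates do not inflate downstream counts.
#'
#' @param boxes scored box data.frame (single slice).
#' @param iouThreshold suppression threshold (default 0.5, non-strict:
#'   a pair at exactly the threshold is suppressed).
#' @return the surviving subset of \code{boxes}, highest score first.
#' @export
suppressBoxes <- function(boxes, iouThreshold = 0.5) {
  if (nrow(boxes) <= 1L) {
    return(boxes)
  }
  ord <- order(-boxes$score)
  boxes <- boxes[ord, , drop = FALSE]
  keep <- logical(nrow(boxes))
  iou <- iouMatrix2d(boxes, boxes)
  alive <- rep(TRUE, nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    drop <- alive & iou[i, ] >= iouThreshold
    drop[i] <- FALSE
    alive[drop] <- FALSE
  }
  out <- boxes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
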