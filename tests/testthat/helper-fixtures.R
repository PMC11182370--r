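# Shared fixtures: a miniature phantom configuration small enough to
# train in seconds, lazily-built cached datasets/models reused across
# test files, and independent brute-force oracles.

tinySimConfig <- function(nVolumes = 8, nSlices = 11, seed = 7, ...) {
  args <- list(
    nVolumes = nVolumes, nSlices = nSlices, depth = 112, width = 128,
    positiveFraction = 0.5, eventsPerVolume = c(1, 2),
    lateralRadius = c(9, 16), sliceRadius = c(1.5, 3),
    amplitude = c(15, 24), drusenCount = c(1, 3), drusenRadius = c(5, 10),
    drusenHeight = c(3, 6), seed = seed
  )
  do.call(simulationConfig, utils::modifyList(args, list(...)))
}

.fixtureCache <- new.env(parent = emptyenv())

# Tiny generated dataset, built once per test session.
tinyDataset <- function() {
  if (is.null(.fixtureCache$tiny)) {
    dir <- file.path(tempdir(), "subsideoct-tiny")
    cfg <- tinySimConfig(nVolumes = 10, nSlices = 11, seed = 7)
    idx <- generateDataset(cfg, dir)
    .fixtureCache$tiny <- list(
      dir = dir, config = cfg, index = idx,
      depthWindow = unlist(readDatasetMeta(dir)$depth_window)
    )
  }
  .fixtureCache$tiny
}

# CM/DM trained on the tiny dataset, built once per test session.
tinyModels <- function() {
  if (is.null(.fixtureCache$models)) {
    ds <- tinyDataset()
    cm <- trainCM(ds$index, cmConfig(inputSize = 96, epochs = 8, seed = 3))
    dm <- trainDM(ds$index, dmConfig(inputSize = 96, epochs = 6, seed = 3),
      depthWindow = ds$depthWindow
    )
    .fixtureCache$models <- list(cm = cm, dm = dm)
  }
  .fixtureCache$models
}

randomScoredBoxes <- function(n, nSlices = 10, width = 100, depth = 80) {
  if (n == 0) {
    return(scoredBoxes(box2d(integer(0), numeric(0), numeric(0), numeric(0), numeric(0)), numeric(0)))
  }
  x0 <- runif(n, 0, width - 10)
  z0 <- runif(n, 0, depth - 10)
  b <- box2d(
    slice = sample(0:(nSlices - 1), n, replace = TRUE),
    x0 = x0, x1 = x0 + runif(n, 2, 40),
    z0 = z0, z1 = z0 + runif(n, 2, 30)
  )
  scoredBoxes(b, runif(n))
}

# Independent merge oracle: explicit adjacency matrix + BFS flood fill.
mergeOracle <- function(boxes, iouThreshold = 0.5) {
  n <- nrow(boxes)
  if (!n) {
    return(list())
  }
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && abs(boxes$slice[i] - boxes$slice[j]) == 1 &&
        iou2d(boxes[i, ], boxes[j, ]) > iouThreshold) {
        adj[i, j] <- TRUE
      }
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      u <- queue[1L]
      queue <- queue[-1L]
      if (!is.na(comp[u])) next
      comp[u] <- cid
      queue <- c(queue, which(adj[u, ] & is.na(comp)))
    }
  }
  lapply(split(seq_len(n), comp), function(ix) {
    g <- boxes[ix, , drop = FALSE]
    list(
      s0 = min(g$slice), s1 = max(g$slice) + 1L,
      x0 = min(g$x0), x1 = max(g$x1), z0 = min(g$z0), z1 = max(g$z1),
      confidence = max(g$score)
    )
  })
}

# Canonical string form of a cuboid set, for set comparison.
cuboidKey <- function(df) {
  sort(sprintf(
    "%d|%d|%.6f|%.6f|%.6f|%.6f|%.6f",
    df$s0, df$s1, df$x0, df$x1, df$z0, df$z1, df$confidence
  ))
}

# Exhaustive pairwise-concordance AUC oracle.
aucPairOracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  tot / (length(pos) * length(neg))
}

# Independent AP oracle: per-positive step integration of the PR curve,
# grouping tied scores at one threshold.
apStepOracle <- function(scores, labels) {
  P <- sum(labels == 1)
  ord <- order(-scores)
  s <- scores[ord]
  y <- labels[ord]
  ap <- 0
  tp <- 0
  fp <- 0
  i <- 1L
  while (i <= length(s)) {
    j <- i
    while (j < length(s) && s[j + 1L] == s[i]) j <- j + 1L
    tpPrev <- tp
    tp <- tp + sum(y[i:j] == 1)
    fp <- fp + sum(y[i:j] == 0)
    prec <- tp / (tp + fp)
    ap <- ap + (tp - tpPrev) / P * prec
    i <- j + 1L
  }
  ap
}

# Brute-force IoU by counting unit cells on the integer grid.
iouCountOracle2d <- function(a, b, lim = 200) {
  g <- expand.grid(x = 0:(lim - 1), z = 0:(lim - 1))
  inA <- g$x >= a$x0 & g$x < a$x1 & g$z >= a$z0 & g$z < a$z1
  inB <- g$x >= b$x0 & g$x < b$x1 & g$z >= b$z0 & g$z < b$z1
  sum(inA & inB) / sum(inA | inB)
}
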