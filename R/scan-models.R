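## Classification module (CM): per-B-scan subsidence presence score in
## [0,1] (sigmoid head). Detection module (DM): per-B-scan candidate
## boxes with objectness scores and box regression over dense anchors.
## Both consume 3-channel neighbor stacks (previous/current/next B-scan)
## through a pluggable backbone and are trained with seeded minibatch
## SGD following the documented recipe (class-balanced batches of 16 for
## CM with best-validation-AUC checkpointing; per-epoch learning-rate
## decay and final-epoch checkpoint for DM).

#' CM training configuration
#'
#' Desk-scale defaults train in minutes on one CPU; \code{cmReferenceConfig}
#' records the GPU-scale reference recipe (224 px input, learning rate
#' 1e-4, 1000 epochs, batch 16, ImageNet-pretrained backbone) for users
#' with such a backbone registered.
#'
#' @param inputSize square model input size in px.
#' @param lr learning rate of the SGD head.
#' @param epochs training epochs.
#' @param batchSize samples per batch (class-balanced: half positive,
#'   half negative B-scans).
#' @param augmentation named logical switches
#'   (\code{translate, rotate, scale, intensity}).
#' @param valFraction fraction of training participants held out for
#'   checkpoint selection by validation AUC.
#' @param backbone registered backbone name.
#' @param seed integer seed for all training randomness.
#' @return a \code{CMConfig} list.
#' @export
cmConfig <- function(inputSize = 128, lr = 0.05, epochs = 30,
                     batchSize = 16,
                     augmentation = c(
                       translate = TRUE, rotate = FALSE,
                       scale = FALSE, intensity = TRUE
                     ),
                     valFraction = 0.2, backbone = "profile", seed = 1L) {
  stopifnot(inputSize > 0, lr > 0, epochs > 0, batchSize >= 2)
  structure(
    list(
      inputSize = as.integer(inputSize), lr = lr, epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), augmentation = augmentation,
      valFraction = valFraction, backbone = backbone, seed = as.integer(seed)
    ),
    class = "CMConfig"
  )
}

#' @rdname cmConfig
#' @export
cmReferenceConfig <- function(backbone = "convnext", seed = 1L) {
  cfg <- cmConfig(
    inputSize = 224, lr = 1e-4, epochs = 1000, batchSize = 16,
    augmentation = c(
      translate = TRUE, rotate = TRUE, scale = TRUE, intensity = TRUE
    ),
    backbone = backbone, seed = seed
  )
  cfg
}

#' DM training configuration
#'
#' @inheritParams cmConfig
#' @param lrDecay multiplicative per-epoch learning-rate decay.
#' @param scoreThreshold minimum objectness for emitting a candidate
#'   (low by design: the detector is the high-sensitivity stage).
#' @param nmsIoU within-slice duplicate-suppression IoU (non-strict).
#' @param posIoU,negIoU anchor labelling thresholds against ground-truth
#'   boxes.
#' @param anchorWidths,anchorStride coverage-grid anchor lateral widths
#'   and stride in native columns (run proposals are added by the
#'   backbone).
#' @param maxPerSlice cap on emitted candidates per B-scan after
#'   suppression (top scores kept), the usual proposal budget of a
#'   region-proposal detector.
#' @return a \code{DMConfig} list.
#' @export
dmConfig <- function(inputSize = 256, lr = 0.05, lrDecay = 0.95,
                     epochs = 20, batchSize = 16, scoreThreshold = 0.05,
                     nmsIoU = 0.5, posIoU = 0.5, negIoU = 0.25,
                     anchorWidths = c(24, 48, 96), anchorStride = 8,
                     maxPerSlice = 8L, backbone = "profile", seed = 1L) {
  stopifnot(
    inputSize > 0, lr > 0, lrDecay > 0, lrDecay <= 1, epochs > 0,
    batchSize >= 2, scoreThreshold >= 0, scoreThreshold <= 1
  )
  structure(
    list(
      inputSize = as.integer(inputSize), lr = lr, lrDecay = lrDecay,
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      scoreThreshold = scoreThreshold, nmsIoU = nmsIoU,
      posIoU = posIoU, negIoU = negIoU, anchorWidths = anchorWidths,
      anchorStride = anchorStride, maxPerSlice = as.integer(maxPerSlice),
      backbone = backbone, seed = as.integer(seed)
    ),
    class = "DMConfig"
  )
}

#' @rdname dmConfig
#' @export
dmReferenceConfig <- function(backbone = "convnext", seed = 1L) {
  dmConfig(
    inputSize = 256, lr = 1e-4, lrDecay = 0.95, epochs = 100,
    batchSize = 16, backbone = backbone, seed = seed
  )
}

#' Build the 3-channel neighbor stack for one B-scan
#'
#' Channels are the previous, current and next B-scan; at the first and
#' last slice the missing neighbour is replaced by repeating the edge
#' B-scan. Each channel is resized to \code{targetSize x targetSize};
#' the native-to-model scale factors are recorded so detector boxes map
#' back to native coordinates.
#'
#' @param volume an \linkS4class{OCTVolume}.
#' @param s 0-based slice index.
#' @param targetSize model input size in px.
#' @param cache optional environment shared by the stacks of one volume
#'   to memoise backbone intermediates (adjacent stacks share two of
#'   their three channels); purely a performance aid.
#' @return a \code{NeighborStack}: list with \code{channels}
#'   (targetSize x targetSize x 3 array in [0,1]), \code{scale}
#'   (\code{sz, sx}: native px per model px), \code{nativeDim},
#'   \code{sliceIndex} and \code{volumeId}.
#' @export
makeNeighborStack <- function(volume, s, targetSize = 128L, cache = NULL) {
  n <- nSlices(volume)
  if (s < 0 || s >= n) {
    stop("slice index out of range: ", s)
  }
  s <- as.integer(s)
  idx <- c(max(0L, s - 1L), s, min(n - 1L, s + 1L))
  bd <- bitDepth(volume)
  denom <- if (is.na(bd)) 1 else 2^bd - 1
  ch <- array(0, c(targetSize, targetSize, 3L))
  for (k in 1:3) {
    key <- sprintf("ch%d_%d", idx[k], targetSize)
    m <- if (!is.null(cache)) cache[[key]] else NULL
    if (is.null(m)) {
      m <- resizeMatrix(getSlice(volume, idx[k]) / denom, targetSize, targetSize)
      if (!is.null(cache)) cache[[key]] <- m
    }
    ch[, , k] <- m
  }
  structure(
    list(
      channels = ch,
      scale = c(
        sz = axialSize(volume) / targetSize,
        sx = lateralSize(volume) / targetSize
      ),
      nativeDim = c(axialSize(volume), lateralSize(volume)),
      sliceIndex = as.integer(s),
      channelSlices = idx,
      volumeId = paste(participantId(volume), eyeSide(volume), visitId(volume)),
      cache = cache
    ),
    class = "NeighborStack"
  )
}

#' Augment a neighbor stack (and its training boxes)
#'
#' One geometric transform (translation, small rotation, isotropic
#' scaling about the image center) is applied identically to all three
#' channels and to any supplied training boxes (corner transform and
#' axis-aligned re-bounding, clipped to the native frame); intensity
#' jitter (gain and offset) is applied channel-wise. Parameters are
#' drawn from the seed, or can be given explicitly via \code{params}
#' (\code{tx, tz} native px, \code{angle} degrees, \code{zoom}, per-channel
#' \code{gain, bias}); all-identity parameters leave the stack unchanged.
#'
#' @param stack a \code{NeighborStack}.
#' @param seed integer seed used when \code{params} is \code{NULL}.
#' @param switches named logical vector enabling transform families.
#' @param params explicit transform parameters (overrides sampling).
#' @param boxes optional data.frame of boxes in native coordinates.
#' @return list with the augmented \code{stack} and transformed
#'   \code{boxes}.
#' @export
augmentStack <- function(stack, seed = 1L,
                         switches = c(
                           translate = TRUE, rotate = FALSE,
                           scale = FALSE, intensity = TRUE
                         ),
                         params = NULL, boxes = NULL) {
  stack$cache <- NULL # channels are about to change; drop memoised state
  sw <- function(nm) isTRUE(unname(switches[nm]))
  if (is.null(params)) {
    params <- withSeed(deriveSeed(seed, "augment"), list(
      tx = if (sw("translate")) round(runif(1, -10, 10)) else 0,
      tz = if (sw("translate")) round(runif(1, -6, 6)) else 0,
      angle = if (sw("rotate")) runif(1, -5, 5) else 0,
      zoom = if (sw("scale")) runif(1, 0.9, 1.1) else 1,
      gain = if (sw("intensity")) runif(3, 0.85, 1.15) else rep(1, 3),
      bias = if (sw("intensity")) runif(3, -0.03, 0.03) else rep(0, 3)
    ))
  }
  Hn <- stack$nativeDim[1L]
  Wn <- stack$nativeDim[2L]
  sz <- stack$scale[["sz"]]
  sx <- stack$scale[["sx"]]
  m <- dim(stack$channels)[1L]
  identityGeom <- params$tx == 0 && params$tz == 0 &&
    params$angle == 0 && params$zoom == 1
  if (!identityGeom) {
    ## inverse warp at model scale, nearest neighbour
    th <- params$angle * pi / 180
    cz <- (m + 1) / 2
    cx <- (m + 1) / 2
    txm <- params$tx / sx
    tzm <- params$tz / sz
    grid <- expand.grid(z = seq_len(m), x = seq_len(m))
    dz <- grid$z - cz - tzm
    dx <- grid$x - cx - txm
    srcZ <- round(cz + (cos(th) * dz - sin(th) * dx) / params$zoom)
    srcX <- round(cx + (sin(th) * dz + cos(th) * dx) / params$zoom)
    ok <- srcZ >= 1 & srcZ <= m & srcX >= 1 & srcX <= m
    for (k in 1:3) {
      old <- stack$channels[, , k]
      new <- matrix(0, m, m)
      new[cbind(grid$z[ok], grid$x[ok])] <- old[cbind(srcZ[ok], srcX[ok])]
      stack$channels[, , k] <- new
    }
  }
  for (k in 1:3) {
    stack$channels[, , k] <- pmin(pmax(
      stack$channels[, , k] * params$gain[k] + params$bias[k], 0
    ), 1)
  }
  if (!is.null(boxes) && nrow(boxes)) {
    th <- params$angle * pi / 180
    czn <- (Hn + 1) / 2
    cxn <- (Wn + 1) / 2
    fw <- function(x, z) {
      list(
        x = cxn + params$zoom * (cos(th) * (x - cxn) + sin(th) * (z - czn)) + params$tx,
        z = czn + params$zoom * (-sin(th) * (x - cxn) + cos(th) * (z - czn)) + params$tz
      )
    }
    for (i in seq_len(nrow(boxes))) {
      cs <- expand.grid(
        x = c(boxes$x0[i], boxes$x1[i]),
        z = c(boxes$z0[i], boxes$z1[i])
      )
      tc <- fw(cs$x, cs$z)
      boxes$x0[i] <- max(0, min(tc$x))
      boxes$x1[i] <- min(Wn, max(tc$x))
      boxes$z0[i] <- max(0, min(tc$z))
      boxes$z1[i] <- min(Hn, max(tc$z))
    }
    boxes <- boxes[boxes$x1 > boxes$x0 & boxes$z1 > boxes$z0, , drop = FALSE]
  }
  list(stack = stack, boxes = boxes)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

## Minibatch SGD for a logistic head. Returns weights, bias,
## standardisation, per-epoch log (loss, lr, batch composition audit,
## validation AUC) and, if keepBest, the best-validation checkpoint.
trainLogisticSGD <- function(X, y, epochs, batchSize, lr, lrDecay = 1,
                             balanced = TRUE, valX = NULL, valY = NULL,
                             keepBest = FALSE, seed = 1L) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl < 1e-8] <- 1
  Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  Zv <- if (!is.null(valX)) sweep(sweep(valX, 2L, ctr), 2L, scl, "/") else NULL
  p <- ncol(Z)
  w <- rep(0, p)
  b <- 0
  pos <- which(y == 1)
  neg <- which(y == 0)
  nBatches <- max(1L, ceiling(nrow(Z) / batchSize))
  log <- NULL
  best <- list(metric = -Inf, w = w, b = b, epoch = NA_integer_)
  withSeed(deriveSeed(seed, "sgd"), {
    for (e in seq_len(epochs) - 1L) {
      lrE <- lr * lrDecay^e
      lossSum <- 0
      posMin <- Inf
      posMax <- -Inf
      order_ <- sample(nrow(Z))
      for (bi in seq_len(nBatches)) {
        if (balanced) {
          half <- batchSize %/% 2L
          take <- c(
            sample(pos, half, replace = length(pos) < half),
            sample(neg, batchSize - half, replace = length(neg) < batchSize - half)
          )
        } else {
          take <- order_[((bi - 1L) * batchSize + 1L):min(bi * batchSize, nrow(Z))]
        }
        Zb <- Z[take, , drop = FALSE]
        yb <- y[take]
        posMin <- min(posMin, sum(yb == 1))
        posMax <- max(posMax, sum(yb == 1))
        pr <- sigmoid(Zb %*% w + b)
        err <- pr - yb
        w <- w - lrE * (crossprod(Zb, err) / length(take))[, 1L]
        b <- b - lrE * mean(err)
        eps <- 1e-12
        lossSum <- lossSum + mean(-yb * log(pr + eps) - (1 - yb) * log(1 - pr + eps))
      }
      valAuc <- NA_real_
      if (!is.null(Zv) && length(unique(valY)) == 2L) {
        valAuc <- rocAuc(as.numeric(Zv %*% w + b), valY)$auc
        if (keepBest && valAuc > best$metric) {
          best <- list(metric = valAuc, w = w, b = b, epoch = e)
        }
      }
      log <- rbind(log, data.frame(
        epoch = e, lr = lrE, loss = lossSum / nBatches,
        batchPosMin = posMin, batchPosMax = posMax, valAuc = valAuc
      ))
    }
  })
  if (keepBest && is.finite(best$metric)) {
    w <- best$w
    b <- best$b
  }
  list(w = w, b = b, center = ctr, scale = scl, log = log, best = best)
}

## Per-slice labels (any annotated run) for one volume's annotation.
sliceLabels <- function(annotation, nSlices) {
  lab <- logical(nSlices)
  r <- annotationRuns(annotation)
  if (nrow(r)) lab[r$slice + 1L] <- TRUE
  lab
}

#' Train the classification module
#'
#' Trains the per-B-scan presence scorer. Following the two-stage
#' design, the training/validation pool is restricted to volumes that
#' contain at least one subsidence (within those, annotated B-scans are
#' the positives and the remaining B-scans the negatives); every batch
#' holds equal numbers of positive and negative B-scans; the checkpoint
#' with the best validation AUC is kept. The validation split is at the
#' participant level.
#'
#' @param index dataset index data.frame (see
#'   \code{\link{readDatasetIndex}}).
#' @param config a \code{\link{cmConfig}}.
#' @return a \code{CMModel} handle (weights, standardisation, backbone
#'   name, config, per-epoch training log).
#' @export
trainCM <- function(index, config = cmConfig()) {
  checkDatasetIndex(index)
  posVols <- index[index$hasSubsidence, , drop = FALSE]
  if (!nrow(posVols)) {
    stop("CM training requires at least one volume with subsidence")
  }
  bb <- getBackbone(config$backbone)
  ## participant-level validation split within the positive volumes
  parts <- unique(posVols$participantId)
  nVal <- max(if (length(parts) > 1L) 1L else 0L, floor(length(parts) * config$valFraction))
  valParts <- withSeed(
    deriveSeed(config$seed, "cmval"),
    if (nVal > 0) sample(parts, nVal) else character(0)
  )
  feat <- list()
  lab <- list()
  isVal <- list()
  for (i in seq_len(nrow(posVols))) {
    vol <- loadVolume(posVols$volumePath[i])
    ann <- readAnnotation(posVols$annotationPath[i])
    labs <- sliceLabels(ann, nSlices(vol))
    inVal <- posVols$participantId[i] %in% valParts
    volCache <- new.env(parent = emptyenv())
    for (s in seq_len(nSlices(vol)) - 1L) {
      st <- makeNeighborStack(vol, s, config$inputSize, cache = volCache)
      feat[[length(feat) + 1L]] <- bb$cmFeatures(st)
      lab[[length(lab) + 1L]] <- labs[s + 1L]
      isVal[[length(isVal) + 1L]] <- inVal
      if (!inVal && any(config$augmentation)) {
        aug <- augmentStack(st,
          seed = deriveSeed(config$seed, paste0("aug", i, "_", s)),
          switches = config$augmentation
        )
        feat[[length(feat) + 1L]] <- bb$cmFeatures(aug$stack)
        lab[[length(lab) + 1L]] <- labs[s + 1L]
        isVal[[length(isVal) + 1L]] <- FALSE
      }
    }
  }
  X <- do.call(rbind, feat)
  y <- as.numeric(unlist(lab))
  vmask <- unlist(isVal)
  if (!any(y[!vmask] == 1) || !any(y[!vmask] == 0)) {
    stop("CM training needs both annotated and clean B-scans within positive volumes")
  }
  fit <- trainLogisticSGD(
    X[!vmask, , drop = FALSE], y[!vmask],
    epochs = config$epochs, batchSize = config$batchSize, lr = config$lr,
    balanced = TRUE,
    valX = if (any(vmask)) X[vmask, , drop = FALSE] else NULL,
    valY = if (any(vmask)) y[vmask] else NULL,
    keepBest = TRUE, seed = config$seed
  )
  structure(
    list(
      module = "cm", backbone = config$backbone, inputSize = config$inputSize,
      w = fit$w, b = fit$b, center = fit$center, scale = fit$scale,
      config = config, log = fit$log, bestEpoch = fit$best$epoch
    ),
    class = "CMModel"
  )
}

#' Score one B-scan with the classification module
#'
#' Pure function at inference: the sigmoid presence score of the stack's
#' current B-scan, in [0, 1].
#'
#' @param model a \code{CMModel} from \code{\link{trainCM}} (or
#'   \code{\link{loadModel}}).
#' @param stack a \code{NeighborStack} built at the model's input size.
#' @return numeric score in [0, 1].
#' @export
cmScore <- function(model, stack) {
  stopifnot(inherits(model, "CMModel"))
  if (dim(stack$channels)[1L] != model$inputSize) {
    stop(
      "input shape mismatch: stack is ", dim(stack$channels)[1L],
      " px, model expects ", model$inputSize
    )
  }
  f <- getBackbone(model$backbone)$cmFeatures(stack)
  z <- (f - model$center) / model$scale
  as.numeric(sigmoid(sum(z * model$w) + model$b))
}

#' Train the detection module
#'
#' Trains the per-B-scan candidate detector on annotated B-scans only
#' (the high-sensitivity stage sees no empty B-scans). Dense anchors are
#' labelled by IoU against the ground-truth boxes
#' (\code{\link{annotationToBoxes}} with the dataset depth window); an
#' objectness head is trained by SGD with per-epoch learning-rate decay
#' (final-epoch checkpoint) and a ridge box-regression head refines the
#' anchor extents.
#'
#' @param index dataset index data.frame.
#' @param config a \code{\link{dmConfig}}.
#' @param depthWindow ground-truth box depth extent \code{c(z0, z1)} (or
#'   per-run function), as for \code{\link{annotationToBoxes}}.
#' @return a \code{DMModel} handle.
#' @export
trainDM <- function(index, config = dmConfig(), depthWindow) {
  checkDatasetIndex(index)
  bb <- getBackbone(config$backbone)
  anchorParams <- list(
    widths = config$anchorWidths, stride = config$anchorStride
  )
  feats <- list()
  labs <- list()
  regT <- list()
  nAnnotated <- 0L
  for (i in seq_len(nrow(index))) {
    if (!index$hasSubsidence[i]) next
    vol <- loadVolume(index$volumePath[i])
    ann <- readAnnotation(index$annotationPath[i])
    gt <- annotationToBoxes(ann, depthWindow, volumeDepth = axialSize(vol))
    volCache <- new.env(parent = emptyenv())
    for (s in sort(unique(gt$slice))) {
      nAnnotated <- nAnnotated + 1L
      st <- makeNeighborStack(vol, s, config$inputSize, cache = volCache)
      at <- bb$anchorTable(st, anchorParams)
      g <- gt[gt$slice == s, , drop = FALSE]
      iou <- iouMatrix2d(at$boxes, g)
      bestIou <- apply(iou, 1L, max)
      bestGt <- apply(iou, 1L, which.max)
      lab <- rep(NA_real_, nrow(at$boxes))
      lab[bestIou >= config$posIoU] <- 1
      lab[bestIou <= config$negIoU] <- 0
      ## force-match the best anchor of each ground-truth box
      for (j in seq_len(nrow(g))) lab[which.max(iou[, j])] <- 1
      keep <- !is.na(lab)
      feats[[length(feats) + 1L]] <- at$features[keep, , drop = FALSE]
      labs[[length(labs) + 1L]] <- lab[keep]
      ## regression learns from looser matches too, so that imprecise
      ## proposals are pulled onto the lesion extent at inference
      regKeep <- which(bestIou >= 0.3 | (lab %in% 1))
      for (r in regKeep) {
        a <- at$boxes[r, ]
        gb <- g[bestGt[r], ]
        aw <- a$x1 - a$x0
        ah <- a$z1 - a$z0
        regT[[length(regT) + 1L]] <- list(
          f = at$features[r, ],
          t = c(
            (gb$x0 - a$x0) / aw, (gb$x1 - a$x1) / aw,
            (gb$z0 - a$z0) / ah, (gb$z1 - a$z1) / ah
          )
        )
      }
    }
  }
  if (nAnnotated == 0L) {
    stop("DM training requires at least one annotated B-scan")
  }
  X <- do.call(rbind, feats)
  y <- unlist(labs)
  fit <- trainLogisticSGD(X, y,
    epochs = config$epochs, batchSize = config$batchSize,
    lr = config$lr, lrDecay = config$lrDecay, balanced = TRUE,
    keepBest = FALSE, seed = config$seed
  )
  ## ridge box regression on matched anchors (standardised features)
  Xr <- do.call(rbind, lapply(regT, function(r) r$f))
  Tr <- do.call(rbind, lapply(regT, function(r) r$t))
  Zp <- sweep(sweep(Xr, 2L, fit$center), 2L, fit$scale, "/")
  Zp <- cbind(1, Zp)
  lambda <- 1e-3 * nrow(Zp)
  reg <- solve(crossprod(Zp) + lambda * diag(ncol(Zp)), crossprod(Zp, Tr))
  structure(
    list(
      module = "dm", backbone = config$backbone, inputSize = config$inputSize,
      w = fit$w, b = fit$b, center = fit$center, scale = fit$scale,
      reg = reg, config = config, log = fit$log
    ),
    class = "DMModel"
  )
}

#' Detect subsidence candidates on one B-scan
#'
#' Scores the dense anchors, refines their extents with the regression
#' head, drops candidates below the emit threshold and suppresses
#' within-slice duplicates (IoU >= \code{nmsIoU}, higher score kept).
#' Boxes are returned in native slice coordinates.
#'
#' @param model a \code{DMModel} from \code{\link{trainDM}}.
#' @param stack a \code{NeighborStack} at the model's input size.
#' @return scored box data.frame (\code{source = "dm_raw"}), possibly
#'   empty.
#' @export
dmDetect <- function(model, stack) {
  stopifnot(inherits(model, "DMModel"))
  if (dim(stack$channels)[1L] != model$inputSize) {
    stop(
      "input shape mismatch: stack is ", dim(stack$channels)[1L],
      " px, model expects ", model$inputSize
    )
  }
  cfg <- model$config
  at <- getBackbone(model$backbone)$anchorTable(
    stack, list(widths = cfg$anchorWidths, stride = cfg$anchorStride)
  )
  Z <- sweep(sweep(at$features, 2L, model$center), 2L, model$scale, "/")
  scores <- as.numeric(sigmoid(Z %*% model$w + model$b))
  keep <- scores >= cfg$scoreThreshold
  if (!any(keep)) {
    return(emptyScoredBoxes())
  }
  boxes <- at$boxes[keep, , drop = FALSE]
  off <- cbind(1, Z[keep, , drop = FALSE]) %*% model$reg
  off <- pmin(pmax(off, -0.5), 0.5)
  aw <- boxes$x1 - boxes$x0
  ah <- boxes$z1 - boxes$z0
  H <- stack$nativeDim[1L]
  W <- stack$nativeDim[2L]
  boxes$x0 <- pmin(pmax(boxes$x0 + off[, 1L] * aw, 0), W - 2)
  boxes$x1 <- pmax(pmin(boxes$x1 + off[, 2L] * aw, W), boxes$x0 + 2)
  boxes$z0 <- pmin(pmax(boxes$z0 + off[, 3L] * ah, 0), H - 2)
  boxes$z1 <- pmax(pmin(boxes$z1 + off[, 4L] * ah, H), boxes$z0 + 2)
  out <- scoredBoxes(boxes, scores[keep], source = "dm_raw")
  out <- suppressBoxes(out, cfg$nmsIoU)
  if (!is.null(cfg$maxPerSlice) && nrow(out) > cfg$maxPerSlice) {
    out <- out[seq_len(cfg$maxPerSlice), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Save and load model handles
#'
#' A model directory holds the full handle (\code{weights.rds}), a
#' readable \code{config.json} and the per-epoch training log
#' (\code{log.csv}). Reloaded models give bit-identical predictions.
#'
#' @param model a \code{CMModel} or \code{DMModel}.
#' @param dir model directory (created if needed).
#' @export
saveModel <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "weights.rds"))
  cfg <- model$config
  jsonlite::write_json(
    cfg[!vapply(cfg, is.function, logical(1))],
    file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = NA
  )
  if (!is.null(model$log)) {
    write.csv(model$log, file.path(dir, "log.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  p <- file.path(dir, "weights.rds")
  if (!file.exists(p)) {
    stop("model weights not found in ", dir)
  }
  readRDS(p)
}
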