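## Desk-scale backbone: a fixed multi-scale feature extractor over
## B-scan neighbor stacks. It computes per-column boundary profiles
## (depth of the OPL/ONL junction, depth of the outer band) by small
## separable smoothing filters and step detection, and derives the
## per-column "dip" of the OPL/ONL junction relative to a robust running
## baseline -- the image signature of OPL subsidence. The trained parts
## of CM/DM (logistic and linear heads) sit on top of these features.
## Backbones are pluggable through a registry keyed by name.

.backboneRegistry <- new.env(parent = emptyenv())

#' Backbone registry
#'
#' CM and DM consume images through a backbone: a pair of feature maps
#' (\code{cmFeatures(stack)} returning a numeric vector per neighbor
#' stack, and \code{anchorTable(stack, params)} returning candidate
#' anchor boxes in native coordinates with per-anchor feature rows).
#' Swapping backbones changes scores but no interface contract.
#'
#' @param name backbone identifier.
#' @param backbone list with functions \code{cmFeatures} and
#'   \code{anchorTable}.
#' @return \code{backboneNames} returns the registered identifiers.
#' @export
registerBackbone <- function(name, backbone) {
  stopifnot(
    is.function(backbone$cmFeatures),
    is.function(backbone$anchorTable)
  )
  assign(name, backbone, envir = .backboneRegistry)
  invisible(name)
}

#' @rdname registerBackbone
#' @export
backboneNames <- function() ls(.backboneRegistry)

getBackbone <- function(name) {
  if (!exists(name, envir = .backboneRegistry)) {
    stop(
      "backbone '", name, "' is not registered (available: ",
      paste(backboneNames(), collapse = ", "), ")"
    )
  }
  get(name, envir = .backboneRegistry)
}

## Nearest-neighbour matrix resize.
resizeMatrix <- function(m, h, w) {
  ri <- pmin(nrow(m), floor((seq_len(h) - 0.5) * nrow(m) / h) + 1L)
  ci <- pmin(ncol(m), floor((seq_len(w) - 0.5) * ncol(m) / w) + 1L)
  m[ri, ci, drop = FALSE]
}

## Column-wise cumulative sums (C speed, no per-column R dispatch).
colCumsum <- function(m) {
  cs <- matrix(cumsum(m), nrow(m), ncol(m))
  if (ncol(m) > 1L) {
    carry <- rep(c(0, cs[nrow(m), -ncol(m)]), each = nrow(m))
    cs <- cs - carry
  }
  cs
}

## Column-wise boxcar smoothing along depth via cumulative sums.
colBoxcar <- function(m, w) {
  H <- nrow(m)
  cs <- colCumsum(m)
  lo <- pmax(0L, seq_len(H) - w)
  hi <- pmin(H, seq_len(H) + w)
  up <- cs[hi, , drop = FALSE]
  dn <- rbind(0, cs)[lo + 1L, , drop = FALSE]
  (up - dn) / (hi - lo)
}

## Per-column boundary profiles of one B-scan (model-scale matrix in
## [0,1]); returns depths in model rows.
boundaryProfiles <- function(m) {
  H <- nrow(m)
  W <- ncol(m)
  ## lateral smoothing first: speckle is uncorrelated across columns
  m <- t(colBoxcar(t(m), 2L))
  pad <- rbind(0, colCumsum(m))
  z <- seq_len(H)
  ## depth boxcar (half-width 2) from the same cumulative sums
  lo <- pmax(0L, z - 2L)
  hi <- pmin(H, z + 2L)
  ms <- (pad[hi + 1L, , drop = FALSE] - pad[lo + 1L, , drop = FALSE]) / (hi - lo)
  ## outer band: brightest depth per column (smoothed)
  outerRow <- max.col(t(ms), ties.method = "first")
  ## largest downward step above the outer band: top of the dark ONL,
  ## i.e. the OPL/ONL junction
  w <- max(2L, round(H / 42))
  loA <- pmax(0L, z - w)
  hiB <- pmin(H, z + w - 1L)
  above <- (pad[z, , drop = FALSE] - pad[loA + 1L, , drop = FALSE]) /
    pmax(1L, z - loA)
  below <- (pad[hiB + 1L, , drop = FALSE] - pad[z, , drop = FALSE]) /
    pmax(1L, hiB - z + 1L)
  drop_ <- above - below
  ## valid search range: below the top margin, above the outer band
  zi <- matrix(z, H, W)
  upper <- matrix(pmax(outerRow - max(3L, w), 4L), H, W, byrow = TRUE)
  drop_[zi < 3L | zi > upper] <- -Inf
  onlTop <- max.col(t(drop_), ties.method = "first")
  list(onlTop = onlTop, outerRow = outerRow)
}

oddK <- function(k, n) {
  k <- min(k, if (n %% 2L == 1L) n else n - 1L)
  if (k %% 2L == 0L) k <- k - 1L
  max(3L, k)
}

## Per-column subsidence dip (native px): depth of the OPL/ONL junction
## minus a robust running-median baseline.
dipProfile <- function(m, scaleZ) {
  bp <- boundaryProfiles(m)
  W <- length(bp$onlTop)
  onl <- as.numeric(stats::runmed(bp$onlTop, oddK(5L, W), endrule = "keep"))
  kb <- oddK(151L, W)
  baseline <- as.numeric(stats::runmed(onl, kb, endrule = "keep"))
  ## constant extension at the ends (the slow median end rule buys
  ## nothing here: the edge guard below zeroes the outermost columns)
  h <- kb %/% 2L
  if (h > 0L && W > kb) {
    baseline[seq_len(h)] <- baseline[h + 1L]
    baseline[(W - h + 1L):W] <- baseline[W - h]
  } else if (W <= kb) {
    baseline[] <- stats::median(onl)
  }
  dip <- (onl - baseline) * scaleZ
  ## boundary estimates at the lateral image edges are unreliable
  guard <- min(3L, W)
  dip[c(seq_len(guard), W - seq_len(guard) + 1L)] <- 0
  list(
    dip = dip,
    onlTop = onl * scaleZ,
    baseline = baseline * scaleZ,
    outerRow = bp$outerRow * scaleZ
  )
}

.dipTau <- 4 # native px; feature support threshold (below tauVis)

## Dip profile of one stack channel, memoised in the stack's per-volume
## cache when one is attached (channels are shared between the stacks
## of adjacent slices, and CM and DM reuse the same profiles).
stackDipProfile <- function(stack, k) {
  key <- sprintf("dp%d_%d", stack$channelSlices[k], dim(stack$channels)[1L])
  if (!is.null(stack$cache)) {
    hit <- stack$cache[[key]]
    if (!is.null(hit)) {
      return(hit)
    }
  }
  dp <- dipProfile(stack$channels[, , k], stack$scale[["sz"]])
  if (!is.null(stack$cache)) {
    stack$cache[[key]] <- dp
  }
  dp
}

channelDipStats <- function(dp) {
  d <- dp$dip
  pos <- pmax(d, 0)
  supp <- d > .dipTau
  runs <- rle(supp)
  maxRun <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0
  c(
    maxDip = max(d),
    q95 = as.numeric(quantile(d, 0.95)),
    mass = sum(pmax(d - .dipTau, 0)),
    frac = mean(supp),
    maxRun = maxRun,
    spread = sd(d)
  )
}

profileCmFeatures <- function(stack) {
  dps <- lapply(seq_len(3L), function(k) stackDipProfile(stack, k))
  st <- vapply(dps, channelDipStats, numeric(6L))
  cur <- st[, 2L]
  nb <- (st[, 1L] + st[, 3L]) / 2
  persis <- apply(st, 1L, min)
  dcor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) 0 else stats::cor(a, b)
  }
  c(
    cur,
    nbMaxDip = nb[["maxDip"]], nbMass = nb[["mass"]], nbFrac = nb[["frac"]],
    perMaxDip = persis[["maxDip"]], perMass = persis[["mass"]],
    corPrev = dcor(dps[[2L]]$dip, dps[[1L]]$dip),
    corNext = dcor(dps[[2L]]$dip, dps[[3L]]$dip),
    meanInt = mean(stack$channels[, , 2L]),
    sdInt = sd(stack$channels[, , 2L])
  )
}

## Candidate proposals over the current B-scan with per-proposal
## features. Two proposal families share one feature map: (1) dip
## support runs -- maximal column runs where the dip profile exceeds
## each of several depths, the analogue of region proposals, and (2) a
## sparse lateral anchor grid guaranteeing coverage. Depth extents
## follow the estimated boundaries (baseline OPL/ONL junction minus a
## margin down to the outer band plus a margin). Boxes are emitted in
## native coordinates.
profileAnchorTable <- function(stack, params = list()) {
  widths <- params$widths %||% numeric(0)
  stride <- params$stride %||% 8
  mUp <- params$mUp %||% 16
  mDown <- params$mDown %||% 10
  runDepths <- params$runDepths %||% c(3, 5, 8, 12)
  sz <- stack$scale[["sz"]]
  sx <- stack$scale[["sx"]]
  H <- stack$nativeDim[1L]
  W <- stack$nativeDim[2L]
  dp2 <- stackDipProfile(stack, 2L)
  dpN <- stackDipProfile(stack, 1L)
  dpP <- stackDipProfile(stack, 3L)
  Wm <- length(dp2$dip) # model columns
  ## candidate lateral windows [x0m, x1m] in model columns
  wins <- NULL
  for (td in runDepths) {
    r <- rle(dp2$dip > td)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= max(3L, round(6 / sx)))) {
      wins <- rbind(wins, c(
        max(1L, starts[j] - round(2 / sx)),
        min(Wm, ends[j] + round(2 / sx))
      ))
    }
  }
  for (aw in widths) {
    awm <- max(4L, round(aw / sx))
    st <- max(1L, round(stride / sx) * 2L)
    x0s <- unique(pmin(
      seq(1L, max(1L, Wm - awm + 1L), by = st),
      max(1L, Wm - awm + 1L)
    ))
    wins <- rbind(wins, cbind(x0s, pmin(Wm, x0s + awm - 1L)))
  }
  featNames <- c(
    "meanDip", "maxDip", "centerDip", "flankDip", "contrast", "frac",
    "sLo", "sHi", "suppFrac", "nbDip", "nbMax", "onlRel", "outerRel", "logW"
  )
  if (is.null(wins)) {
    return(list(
      boxes = box2d(integer(0), numeric(0), numeric(0), numeric(0), numeric(0)),
      features = matrix(numeric(0), 0L, length(featNames),
        dimnames = list(NULL, featNames)
      )
    ))
  }
  wins <- unique(wins)
  nW <- nrow(wins)
  feats <- matrix(0, nW, length(featNames), dimnames = list(NULL, featNames))
  z0v <- numeric(nW)
  z1v <- numeric(nW)
  for (i in seq_len(nW)) {
    x0m <- wins[i, 1L]
    x1m <- wins[i, 2L]
    win <- x0m:x1m
    awm <- length(win)
    d <- dp2$dip[win]
    fl <- max(1L, x0m - awm %/% 2L):max(1L, x0m - 1L)
    fr <- min(Wm, x1m + 1L):min(Wm, x1m + awm %/% 2L)
    flank <- mean(c(dp2$dip[fl], dp2$dip[fr]))
    supp <- which(d > .dipTau)
    meanD <- sum(d) / awm
    feats[i, ] <- c(
      meanD, max(d), d[(awm + 1L) %/% 2L], flank, meanD - flank,
      length(supp) / awm,
      if (length(supp)) (supp[1L] - 1L) / awm else 0.5,
      if (length(supp)) supp[length(supp)] / awm else 0.5,
      length(supp) / awm,
      sum(dpN$dip[win] + dpP$dip[win]) / (2 * awm),
      min(max(dpN$dip[win]), max(dpP$dip[win])),
      sum(dp2$onlTop[win]) / (awm * H),
      sum(dp2$outerRow[win]) / (awm * H),
      log2(awm * sx)
    )
    z0v[i] <- max(0, min(dp2$baseline[win]) - mUp)
    z1v[i] <- min(H, max(dp2$outerRow[win]) + mDown)
    if (z1v[i] <= z0v[i]) {
      z1v[i] <- min(H, z0v[i] + 2)
    }
  }
  boxes <- data.frame(
    slice = rep.int(stack$sliceIndex, nW),
    x0 = (wins[, 1L] - 1L) * sx, x1 = wins[, 2L] * sx,
    z0 = z0v, z1 = z1v
  )
  list(boxes = boxes, features = feats)
}

## A plain pooled-intensity backbone: grid means/contrasts of the
## current channel and neighbour differences. Interface-identical to the
## profile backbone; used to demonstrate backbone pluggability.
poolCmFeatures <- function(stack) {
  g <- resizeMatrix(stack$channels[, , 2L], 6L, 6L)
  dn <- mean(abs(
    resizeMatrix(stack$channels[, , 2L], 6L, 6L) -
      resizeMatrix(stack$channels[, , 1L], 6L, 6L)
  ))
  c(as.numeric(g), nbDiff = dn, sdInt = sd(stack$channels[, , 2L]))
}

poolAnchorTable <- function(stack, params = list()) {
  out <- profileAnchorTable(stack, params)
  ## same anchor geometry, pooled-intensity features
  m <- stack$channels[, , 2L]
  sx <- stack$scale[["sx"]]
  feats <- t(vapply(seq_len(nrow(out$boxes)), function(i) {
    x0m <- max(1L, round(out$boxes$x0[i] / sx) + 1L)
    x1m <- min(ncol(m), round(out$boxes$x1[i] / sx))
    sub <- m[, x0m:x1m, drop = FALSE]
    p <- resizeMatrix(sub, 4L, 2L)
    c(as.numeric(p), sdInt = sd(sub))
  }, numeric(9L)))
  list(boxes = out$boxes, features = feats)
}

registerBackbone("profile", list(
  cmFeatures = profileCmFeatures,
  anchorTable = profileAnchorTable
))
registerBackbone("pool", list(
  cmFeatures = poolCmFeatures,
  anchorTable = poolAnchorTable
))
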