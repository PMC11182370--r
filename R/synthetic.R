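## Synthetic layered-retina OCT phantom: smooth boundary surfaces for
## {ILM, INL/OPL, OPL/ONL, ELM-proxy, RPE}, drusen-like RPE elevations,
## per-layer reflectivity with multiplicative gamma speckle, and
## parameterised OPL-subsidence events (raised-cosine dips of the
## INL/OPL and OPL/ONL boundaries) with exact A-scan ground truth.

## Nominal boundary depths as fractions of the axial size.
.layerFractions <- c(ilm = 0.16, inlopl = 0.38, oplonl = 0.44, elm = 0.72, rpe = 0.79)

#' Simulation configuration for synthetic OCT datasets
#'
#' Returns the configuration list controlling the phantom generator.
#' Defaults are the desk-scale study conditions: 49 B-scans of 160 x 256
#' px, one quarter of volumes carrying subsidence, raised-cosine dips of
#' amplitude 22-38 px with a 5 px visibility threshold, and gamma
#' speckle of shape 8 (multiplicative, mean 1).
#'
#' @param nVolumes number of volumes to generate.
#' @param nSlices B-scans per volume (native acquisition: 49).
#' @param depth,width B-scan size in px (rows x columns); 160 x 256 is
#'   the desk-scale default, 496 x 512 matches the native scans.
#' @param positiveFraction fraction of volumes with subsidence; the
#'   positive count is \code{round(nVolumes * positiveFraction)} exactly.
#' @param eventsPerVolume integer range \code{c(lo, hi)} of subsidence
#'   events per positive volume (uniform).
#' @param lateralRadius,sliceRadius,amplitude event parameter ranges
#'   (uniform): lateral half-width in columns, extent in slices, and dip
#'   depth in px.
#' @param tauVis visibility threshold in px: an A-scan is annotated when
#'   the injected dip exceeds this depth.
#' @param drusenCount,drusenRadius,drusenHeight ranges for drusen-like
#'   RPE elevations per volume.
#' @param speckleShape gamma shape of the multiplicative speckle
#'   (mean 1, variance 1/shape); \code{Inf} disables noise.
#' @param layerMeans named reflectivities of the six bands
#'   (vitreous, inner retina, OPL, ONL, outer band, choroid).
#' @param textureAmplitude relative amplitude of smooth per-layer
#'   lateral reflectivity modulation (0 disables).
#' @param surfaceAmplitude,surfaceJitter px amplitude of the shared
#'   smooth surface undulation and of per-surface jitter.
#' @param difficulty \code{"easy"} (well-separated contrast/noise) or
#'   \code{"hard"} (subtler dips, stronger speckle).
#' @param seed integer seed; every derived random stream is a pure
#'   function of it.
#' @return a \code{SimulationConfig} list.
#' @export
simulationConfig <- function(nVolumes = 20, nSlices = 49, depth = 160,
                             width = 256, positiveFraction = 0.25,
                             eventsPerVolume = c(1, 2),
                             lateralRadius = c(15, 30),
                             sliceRadius = c(2, 4),
                             amplitude = c(22, 38), tauVis = 5,
                             drusenCount = c(2, 6), drusenRadius = c(8, 20),
                             drusenHeight = c(4, 10), speckleShape = 8,
                             layerMeans = c(
                               vitreous = 0.04, inner = 0.22, opl = 0.32,
                               onl = 0.08, outer = 0.50, choroid = 0.16
                             ),
                             textureAmplitude = 0.05,
                             surfaceAmplitude = 2, surfaceJitter = 1,
                             difficulty = c("easy", "hard"), seed = 1L) {
  difficulty <- match.arg(difficulty)
  cfg <- list(
    nVolumes = nVolumes, nSlices = nSlices, depth = depth, width = width,
    positiveFraction = positiveFraction, eventsPerVolume = eventsPerVolume,
    lateralRadius = lateralRadius, sliceRadius = sliceRadius,
    amplitude = amplitude, tauVis = tauVis, drusenCount = drusenCount,
    drusenRadius = drusenRadius, drusenHeight = drusenHeight,
    speckleShape = speckleShape, layerMeans = layerMeans,
    textureAmplitude = textureAmplitude,
    surfaceAmplitude = surfaceAmplitude, surfaceJitter = surfaceJitter,
    difficulty = difficulty, seed = as.integer(seed)
  )
  if (difficulty == "hard") {
    cfg$amplitude <- c(8, 20)
    cfg$speckleShape <- 4
    cfg$layerMeans <- c(
      vitreous = 0.06, inner = 0.20, opl = 0.26,
      onl = 0.10, outer = 0.42, choroid = 0.16
    )
  }
  validateSimulationConfig(cfg)
  class(cfg) <- "SimulationConfig"
  cfg
}

validateSimulationConfig <- function(cfg) {
  stopifnot(
    cfg$nVolumes >= 0, cfg$nSlices >= 1, cfg$depth >= 1, cfg$width >= 1,
    cfg$positiveFraction >= 0, cfg$positiveFraction <= 1,
    all(cfg$eventsPerVolume >= 0), all(cfg$amplitude >= 0),
    cfg$tauVis >= 0, all(cfg$drusenCount >= 0), cfg$speckleShape > 0,
    all(cfg$layerMeans >= 0), all(cfg$layerMeans <= 1)
  )
  invisible(cfg)
}

## Evaluate an expression under a local RNG seed, restoring global state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## Derive an independent child seed (< 2^31) from a seed and a tag.
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 17) %% 2147483629)
}

## Smooth band-limited random field over an (nSlices x width) grid:
## coarse N(0,1) grid, clipped at +-2.5 sd, bilinearly upsampled.
smoothField <- function(nSlices, width, coarse = c(5, 9)) {
  cs <- max(2L, min(nSlices, coarse[1L]))
  cw <- max(2L, min(width, coarse[2L]))
  g <- matrix(pmin(pmax(rnorm(cs * cw), -2.5), 2.5), cs, cw)
  rows <- if (nSlices == 1L) {
    matrix(g[1L, ], 1L, cw)
  } else {
    apply(g, 2L, function(col) {
      approx(seq(0, 1, length.out = cs), col, xout = seq(0, 1, length.out = nSlices))$y
    })
  }
  if (nSlices == 1L) dim(rows) <- c(1L, cw)
  t(apply(rows, 1L, function(row) {
    approx(seq(0, 1, length.out = cw), row, xout = seq(0, 1, length.out = width))$y
  }))
}

#' Simulate smooth retinal layer surfaces
#'
#' Builds the five boundary height maps (ILM, INL/OPL, OPL/ONL, an
#' ELM proxy, RPE) over the (slice, column) grid: nominal depths plus a
#' shared smooth undulation, small per-surface jitter, and drusen-like
#' upward RPE elevations. Strict depth ordering of the surfaces is
#' enforced at every grid point.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param seed integer seed (defaults to \code{config$seed}).
#' @return a \code{LayerModel}: list with \code{surfaces} (named list of
#'   nSlices x width matrices, depths in px), \code{layerMeans},
#'   \code{textureAmplitude} and the grid dimensions.
#' @export
simulateLayers <- function(config, seed = config$seed) {
  validateSimulationConfig(config)
  d <- config$depth
  if (d < 40) {
    stop("axial size too small to fit ordered retinal layers (need >= 40 px)")
  }
  nS <- config$nSlices
  W <- config$width
  withSeed(deriveSeed(seed, "layers"), {
    base <- smoothField(nS, W) * config$surfaceAmplitude
    surf <- lapply(.layerFractions, function(f) {
      f * d + base + smoothField(nS, W) * config$surfaceJitter
    })
    ## drusen: smooth compact bumps lifting the RPE towards the retina
    nDrusen <- if (diff(range(config$drusenCount)) == 0) {
      config$drusenCount[1L]
    } else {
      sample(config$drusenCount[1L]:config$drusenCount[2L], 1L)
    }
    if (nDrusen > 0) {
      for (i in seq_len(nDrusen)) {
        cx <- runif(1, 0, W - 1)
        cs <- runif(1, 0, nS - 1)
        rx <- runif(1, config$drusenRadius[1L], config$drusenRadius[2L])
        rs <- max(1, rx * nS / W * 4)
        h <- runif(1, config$drusenHeight[1L], config$drusenHeight[2L])
        ux <- pmin(abs(seq_len(W) - 1 - cx) / rx, 1)
        us <- pmin(abs(seq_len(nS) - 1 - cs) / rs, 1)
        bump <- h * outer(0.5 * (1 + cos(pi * us)), 0.5 * (1 + cos(pi * ux)))
        ## the photoreceptor/RPE complex drapes over the druse: lift the
        ## outer band as a whole so its thickness is preserved
        surf$rpe <- pmax(surf$rpe - bump, surf$oplonl + 6)
        surf$elm <- pmax(surf$elm - bump, surf$oplonl + 2)
      }
    }
    ## enforce strict ordering and volume bounds
    surf$ilm <- pmin(pmax(surf$ilm, 2), d - 12)
    surf$inlopl <- pmin(pmax(surf$inlopl, surf$ilm + 2), d - 10)
    surf$oplonl <- pmin(pmax(surf$oplonl, surf$inlopl + 1), d - 8)
    surf$elm <- pmin(pmax(surf$elm, surf$oplonl + 1), d - 4)
    surf$rpe <- pmin(pmax(surf$rpe, surf$elm + 1), d - 2)
    structure(
      list(
        surfaces = surf, layerMeans = config$layerMeans,
        textureAmplitude = config$textureAmplitude,
        nSlices = nS, width = W, depth = d
      ),
      class = "LayerModel"
    )
  })
}

#' Define a subsidence event
#'
#' A localized downward displacement of the INL/OPL and OPL/ONL
#' boundaries with a separable raised-cosine profile
#' \eqn{A \, p(\Delta x / r_x) \, p(\Delta s / r_s)} where
#' \eqn{p(u) = (1 + \cos(\pi u))/2} for \eqn{|u| \le 1} and 0 outside.
#'
#' @param centerSlice,centerCol event center (0-based).
#' @param lateralRadius half-width in columns; \code{sliceRadius}
#'   half-extent in slices.
#' @param amplitude maximal dip depth in px (>= 0; 0 is a no-op).
#' @export
subsidenceEvent <- function(centerSlice, centerCol, lateralRadius,
                            sliceRadius, amplitude) {
  stopifnot(amplitude >= 0, lateralRadius > 0, sliceRadius > 0)
  list(
    centerSlice = centerSlice, centerCol = centerCol,
    lateralRadius = lateralRadius, sliceRadius = sliceRadius,
    amplitude = amplitude
  )
}

raisedCosine <- function(u) ifelse(abs(u) < 1, 0.5 * (1 + cos(pi * u)), 0)

## Dip depth of one event over the (slice, column) grid.
eventDip <- function(event, nSlices, width) {
  us <- (seq_len(nSlices) - 1 - event$centerSlice) / event$sliceRadius
  ux <- (seq_len(width) - 1 - event$centerCol) / event$lateralRadius
  event$amplitude * outer(raisedCosine(us), raisedCosine(ux))
}

#' Inject subsidence events into a layer model
#'
#' Deepens the INL/OPL and OPL/ONL surfaces by each event's
#' raised-cosine dip and returns the exact ground truth: an A-scan is
#' annotated for an event precisely where that event's dip exceeds the
#' visibility threshold \code{tauVis}. Surface ordering is preserved by
#' clipping the dip against the deeper boundaries (ELM proxy raised if
#' required, everything capped below the RPE).
#'
#' @param layers a \code{LayerModel} from \code{\link{simulateLayers}}.
#' @param events list of \code{\link{subsidenceEvent}}s.
#' @param tauVis visibility threshold in px (default 5).
#' @return list with the modified \code{layers} and the
#'   \linkS4class{SubsidenceAnnotation} (one lesion per event).
#' @export
injectSubsidence <- function(layers, events, tauVis = 5) {
  stopifnot(inherits(layers, "LayerModel"))
  nS <- layers$nSlices
  W <- layers$width
  surf <- layers$surfaces
  runs <- emptyRuns()
  for (i in seq_along(events)) {
    ev <- events[[i]]
    if (ev$centerSlice < 0 || ev$centerSlice > nS - 1 ||
      ev$centerCol < 0 || ev$centerCol > W - 1) {
      stop("subsidence event center outside volume bounds")
    }
    dip <- eventDip(ev, nS, W)
    if (ev$amplitude == 0) next
    ## apply dip with ordered clipping below
    oplonlRaw <- pmin(surf$oplonl + dip, surf$rpe - 2)
    surf$elm <- pmin(pmax(surf$elm, oplonlRaw + 1), surf$rpe - 1)
    surf$oplonl <- pmin(oplonlRaw, surf$elm - 1)
    surf$inlopl <- pmin(surf$inlopl + dip, surf$oplonl - 1)
    ## exact ground truth from the event's own dip profile
    vis <- dip > tauVis
    for (s in which(rowSums(vis) > 0)) {
      cols <- which(vis[s, ])
      ## unimodal profile => contiguous run
      runs <- rbind(runs, data.frame(
        lesionId = i, slice = s - 1L,
        x0 = min(cols) - 1L, x1 = max(cols)
      ))
    }
  }
  list(layers = layers_update(layers, surf), annotation = SubsidenceAnnotation(runs))
}

layers_update <- function(layers, surf) {
  layers$surfaces <- surf
  layers
}

#' Render a layer model into an OCT volume
#'
#' Piecewise-constant band reflectivities (vitreous, inner retina, OPL,
#' ONL, ELM-to-RPE outer band, choroid) modulated by a smooth per-layer
#' lateral texture field and multiplied voxel-wise by gamma speckle of
#' mean 1. Deterministic given the seed.
#'
#' @param layers a \code{LayerModel}.
#' @param config the \code{\link{simulationConfig}} (noise/texture
#'   parameters).
#' @param seed integer seed.
#' @return an \linkS4class{OCTVolume} with unit-interval float voxels.
#' @export
renderVolume <- function(layers, config, seed = config$seed) {
  stopifnot(inherits(layers, "LayerModel"))
  nS <- layers$nSlices
  H <- layers$depth
  W <- layers$width
  means <- layers$layerMeans
  surf <- layers$surfaces
  withSeed(deriveSeed(seed, "render"), {
    texAmp <- layers$textureAmplitude
    tex <- if (texAmp > 0) {
      lapply(seq_along(means), function(i) 1 + texAmp * smoothField(nS, W))
    } else {
      NULL
    }
    v <- array(0, c(nS, H, W))
    rowIdx <- matrix(0:(H - 1), H, W)
    for (s in seq_len(nS)) {
      band <- 1L +
        (rowIdx >= matrix(surf$ilm[s, ], H, W, byrow = TRUE)) +
        (rowIdx >= matrix(surf$inlopl[s, ], H, W, byrow = TRUE)) +
        (rowIdx >= matrix(surf$oplonl[s, ], H, W, byrow = TRUE)) +
        (rowIdx >= matrix(surf$elm[s, ], H, W, byrow = TRUE)) +
        (rowIdx >= matrix(surf$rpe[s, ], H, W, byrow = TRUE))
      img <- matrix(means[band], H, W)
      if (!is.null(tex)) {
        texs <- vapply(tex, function(tl) tl[s, ], numeric(W))
        ## texs: W x nLayers; pick per-voxel factor by band
        img <- img * matrix(texs[cbind(rep(seq_len(W), each = H), c(band))], H, W)
      }
      v[s, , ] <- img
    }
    if (is.finite(config$speckleShape)) {
      k <- config$speckleShape
      v <- v * array(rgamma(length(v), shape = k, rate = k), dim(v))
    }
    v <- pmin(v, 1)
    OCTVolume(v, bitDepth = NA_integer_)
  })
}

#' Generate a synthetic OCT dataset on disk
#'
#' Writes \code{round(nVolumes * positiveFraction)} positive and the
#' remaining negative volumes (8-bit multi-page TIFF + JSON metadata),
#' one annotation JSON per volume (empty for negatives), a dataset-level
#' \code{dataset.json} (ground-truth depth window, visibility threshold,
#' seed) and the dataset index CSV. Participants are synthesized with
#' two eyes each so participant-level stratification is exercisable.
#' Byte-identical output for identical config + seed.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param outDir output directory (created if needed).
#' @return the dataset index data.frame, invisibly; also written to
#'   \code{outDir/index.csv}.
#' @export
generateDataset <- function(config, outDir) {
  validateSimulationConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) {
    stop("cannot create output directory: ", outDir)
  }
  n <- config$nVolumes
  nPos <- round(n * config$positiveFraction)
  posIdx <- withSeed(
    deriveSeed(config$seed, "labels"),
    sample(seq_len(n), nPos)
  )
  index <- NULL
  for (i in seq_len(n)) {
    pid <- sprintf("P%03d", (i - 1) %/% 2 + 1)
    eye <- if (i %% 2 == 1) "left" else "right"
    vid <- "V0"
    vseed <- deriveSeed(config$seed, paste0("volume", i))
    layers <- simulateLayers(config, seed = vseed)
    annotation <- SubsidenceAnnotation()
    if (i %in% posIdx) {
      events <- withSeed(deriveSeed(vseed, "events"), {
        k <- sample(config$eventsPerVolume[1L]:config$eventsPerVolume[2L], 1L)
        ## rejection-sample laterally disjoint events (distinct lesions
        ## never share A-scans, matching how graders delineate them)
        evs <- list()
        tries <- 0L
        while (length(evs) < k && tries < 100L) {
          tries <- tries + 1L
          rx <- min(
            runif(1, config$lateralRadius[1L], config$lateralRadius[2L]),
            (config$width - 1) / 2
          )
          rs <- min(
            runif(1, config$sliceRadius[1L], config$sliceRadius[2L]),
            (config$nSlices - 1) / 2
          )
          cx <- runif(1, rx, config$width - 1 - rx)
          overlaps <- any(vapply(evs, function(e) {
            abs(e$centerCol - cx) < e$lateralRadius + rx + 8
          }, logical(1)))
          if (overlaps) next
          evs[[length(evs) + 1L]] <- subsidenceEvent(
            centerSlice = runif(1, rs, config$nSlices - 1 - rs),
            centerCol = cx, lateralRadius = rx, sliceRadius = rs,
            amplitude = runif(1, config$amplitude[1L], config$amplitude[2L])
          )
        }
        evs
      })
      inj <- injectSubsidence(layers, events, tauVis = config$tauVis)
      layers <- inj$layers
      annotation <- inj$annotation
    }
    vol <- renderVolume(layers, config, seed = vseed)
    vox <- round(voxels(vol) * 255)
    vol8 <- OCTVolume(vox,
      participantId = pid, eye = eye, visitId = vid, bitDepth = 8L
    )
    vpath <- file.path(outDir, sprintf("vol%03d.tiff", i))
    apath <- file.path(outDir, sprintf("vol%03d_annotation.json", i))
    saveVolume(vol8, vpath)
    writeAnnotation(annotation, apath)
    index <- rbind(index, data.frame(
      participantId = pid, eye = eye, visitId = vid,
      volumePath = vpath, annotationPath = apath,
      hasSubsidence = hasSubsidence(annotation)
    ))
  }
  if (!is.null(index)) {
    writeDatasetIndex(index, file.path(outDir, "index.csv"))
  }
  jsonlite::write_json(
    list(
      depth_window = defaultDepthWindow(config),
      tau_vis = config$tauVis, seed = config$seed,
      n_volumes = n, n_positive = nPos,
      depth = config$depth, width = config$width, n_slices = config$nSlices
    ),
    file.path(outDir, "dataset.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(index)
}

#' Ground-truth depth window for a synthetic dataset
#'
#' Subsidence lives between the INL/OPL boundary and the RPE; the
#' ground-truth box depth extent is the nominal INL/OPL depth minus a
#' margin down to the nominal RPE depth plus a margin (defaults 8 px
#' each).
#'
#' @param config a \code{\link{simulationConfig}} (or any list with
#'   \code{depth}).
#' @param mUp,mDown margins in px above the INL/OPL and below the RPE.
#' @return numeric \code{c(z0, z1)}.
#' @export
defaultDepthWindow <- function(config, mUp = 8, mDown = 8) {
  d <- config$depth
  c(
    max(0, round(.layerFractions[["inlopl"]] * d) - mUp),
    min(d, round(.layerFractions[["rpe"]] * d) + mDown)
  )
}

#' Read dataset-level metadata written by \code{\link{generateDataset}}
#'
#' @param dir dataset directory containing \code{dataset.json}.
#' @return list with \code{depth_window}, \code{tau_vis}, \code{seed},
#'   sizes.
#' @export
readDatasetMeta <- function(dir) {
  p <- file.path(dir, "dataset.json")
  if (!file.exists(p)) {
    stop("dataset metadata not found: ", p)
  }
  meta <- jsonlite::read_json(p, simplifyVector = TRUE)
  meta
}
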