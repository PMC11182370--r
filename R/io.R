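## Volume exchange formats: multi-page TIFF (integer grayscale) and NIfTI
## (integer or float), each with a JSON metadata sidecar named
## <stem>.json. Annotations, detections and metadata are JSON; the
## dataset index is CSV. Proprietary scanner formats are out of scope.

metadataPath <- function(path) {
  paste0(tools::file_path_sans_ext(path, compression = TRUE), ".json")
}

isTiffPath <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)
isNiftiPath <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)

#' Save an OCT volume to disk
#'
#' Writes the voxel stack plus a JSON metadata sidecar
#' (\code{<stem>.json}) holding identity and bit depth, so that
#' \code{\link{loadVolume}} reproduces the volume exactly. Multi-page
#' TIFF (\code{.tif/.tiff}) stores 8- or 16-bit integer volumes without
#' rescaling; NIfTI (\code{.nii/.nii.gz}) stores integer or float
#' volumes.
#'
#' @param volume an \linkS4class{OCTVolume}.
#' @param path output file; the extension selects the format.
#' @return \code{path}, invisibly.
#' @export
saveVolume <- function(volume, path) {
  stopifnot(is(volume, "OCTVolume"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  v <- voxels(volume)
  bd <- bitDepth(volume)
  if (isTiffPath(path)) {
    if (is.na(bd)) {
      stop("TIFF output requires an 8- or 16-bit integer volume; use NIfTI for float volumes")
    }
    pages <- lapply(seq_len(dim(v)[1L]), function(i) {
      m <- v[i, , , drop = TRUE]
      dim(m) <- dim(v)[2:3]
      m / (2^bd - 1)
    })
    tiff::writeTIFF(pages, path, bits.per.sample = bd)
  } else if (isNiftiPath(path)) {
    arr <- aperm(v, c(3L, 2L, 1L)) # (x, z, s) on disk
    dt <- if (is.na(bd)) "double" else if (bd == 8L) "uint8" else "uint16"
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = dt), path)
  } else {
    stop("unsupported volume format: ", path, " (use .tif/.tiff or .nii/.nii.gz)")
  }
  meta <- list(
    participant_id = participantId(volume), eye = eyeSide(volume),
    visit_id = visitId(volume), bit_depth = bd,
    n_slices = nSlices(volume), depth = axialSize(volume),
    width = lateralSize(volume)
  )
  jsonlite::write_json(meta, metadataPath(path),
    auto_unbox = TRUE, null = "null", na = "null"
  )
  invisible(path)
}

#' Load an OCT volume from disk
#'
#' Reads a multi-page TIFF or NIfTI stack written by
#' \code{\link{saveVolume}} (or any stack in those formats), together
#' with its JSON metadata sidecar when present. Slice order is
#' preserved. Distinct errors are raised for a missing file,
#' inconsistent slice shapes and an unreadable metadata sidecar.
#'
#' @param path volume file (.tif/.tiff or .nii/.nii.gz).
#' @return An \linkS4class{OCTVolume}.
#' @export
loadVolume <- function(path) {
  if (!file.exists(path)) {
    stop("volume file not found: ", path)
  }
  meta <- NULL
  mp <- metadataPath(path)
  if (file.exists(mp)) {
    meta <- tryCatch(jsonlite::read_json(mp), error = function(e) {
      stop("unreadable metadata sidecar ", mp, ": ", conditionMessage(e))
    })
  }
  if (isTiffPath(path)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
    if (ncol(dims) > 1L && any(dims != dims[, 1L])) {
      stop("inconsistent slice shapes in ", path)
    }
    v <- array(0, c(length(pages), dims[1L, 1L], dims[2L, 1L]))
    for (i in seq_along(pages)) v[i, , ] <- pages[[i]]
    bd <- if (!is.null(meta$bit_depth)) {
      as.integer(meta$bit_depth)
    } else if (max(v) > 255) 16L else 8L
  } else if (isNiftiPath(path)) {
    arr <- as.array(RNifti::readNifti(path))
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 3L) {
      stop("inconsistent slice shapes in ", path)
    }
    v <- aperm(arr, c(3L, 2L, 1L))
    bd <- if (!is.null(meta) && !is.null(meta$bit_depth)) {
      as.integer(meta$bit_depth)
    } else if (all(v == round(v)) && max(v) <= 65535 && max(v) > 1) {
      if (max(v) > 255) 16L else 8L
    } else {
      NA_integer_
    }
  } else {
    stop("unsupported volume format: ", path)
  }
  OCTVolume(
    v,
    participantId = meta$participant_id %||% "unknown",
    eye = meta$eye %||% "left",
    visitId = meta$visit_id %||% "V0",
    bitDepth = bd
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Read and write A-scan subsidence annotations (JSON)
#'
#' The on-disk schema mirrors what graders produce: per lesion, the list
#' of annotated column runs per B-scan,
#' \code{\{"lesions": [\{"lesion_id", "runs": [\{"slice","x0","x1"\}]\}]\}}
#' with 0-based half-open runs.
#'
#' @param annotation a \linkS4class{SubsidenceAnnotation}.
#' @param path JSON file path.
#' @return \code{readAnnotation} returns a
#'   \linkS4class{SubsidenceAnnotation}; \code{writeAnnotation} returns
#'   \code{path} invisibly.
#' @export
writeAnnotation <- function(annotation, path) {
  stopifnot(is(annotation, "SubsidenceAnnotation"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  r <- annotationRuns(annotation)
  lesions <- lapply(unique(r$lesionId), function(id) {
    g <- r[r$lesionId == id, , drop = FALSE]
    list(
      lesion_id = id,
      runs = lapply(seq_len(nrow(g)), function(i) {
        list(slice = g$slice[i], x0 = g$x0[i], x1 = g$x1[i])
      })
    )
  })
  jsonlite::write_json(list(lesions = lesions), path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname writeAnnotation
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path)
  }
  doc <- jsonlite::read_json(path)
  if (is.null(doc$lesions)) {
    stop("malformed annotation JSON (missing 'lesions'): ", path)
  }
  rows <- do.call(rbind, lapply(doc$lesions, function(l) {
    do.call(rbind, lapply(l$runs, function(rn) {
      data.frame(
        lesionId = as.integer(l$lesion_id), slice = as.integer(rn$slice),
        x0 = as.integer(rn$x0), x1 = as.integer(rn$x1)
      )
    }))
  }))
  SubsidenceAnnotation(if (is.null(rows)) emptyRuns() else rows)
}

#' Convert A-scan annotations to per-slice ground-truth boxes
#'
#' Graders mark only lateral columns; a depth extent must be supplied to
#' obtain training/evaluation boxes. Each maximal annotated column run
#' on each slice becomes one box whose lateral extent is the run and
#' whose depth extent is the depth window; boxes keep their
#' \code{lesionId}.
#'
#' @param annotation a \linkS4class{SubsidenceAnnotation}.
#' @param depthWindow either a numeric \code{c(z0, z1)} applied to every
#'   run, or a function \code{f(slice, x0, x1)} returning \code{c(z0, z1)}
#'   per run (used with synthetic volumes, where the window follows the
#'   known layer surfaces).
#' @param volumeDepth optional depth bound; runs whose window exceeds it
#'   raise an error.
#' @return data.frame of boxes with columns
#'   \code{lesionId, slice, x0, x1, z0, z1}.
#' @export
annotationToBoxes <- function(annotation, depthWindow, volumeDepth = NULL) {
  stopifnot(is(annotation, "SubsidenceAnnotation"))
  r <- annotationRuns(annotation)
  if (!nrow(r)) {
    return(cbind(lesionId = integer(0), box2d(integer(0), numeric(0), numeric(0), numeric(0), numeric(0))))
  }
  win <- if (is.function(depthWindow)) {
    t(mapply(depthWindow, r$slice, r$x0, r$x1))
  } else {
    matrix(rep(as.numeric(depthWindow), each = nrow(r)), ncol = 2L)
  }
  if (any(win[, 1L] >= win[, 2L]) || any(win[, 1L] < 0)) {
    stop("invalid depth window: need 0 <= z0 < z1")
  }
  if (!is.null(volumeDepth) && any(win[, 2L] > volumeDepth)) {
    stop("depth window outside volume bounds")
  }
  out <- box2d(r$slice, r$x0, r$x1, win[, 1L], win[, 2L])
  cbind(lesionId = r$lesionId, out)
}

#' Build ground-truth cuboids from an annotation
#'
#' One cuboid per lesion: the tight bounding extent (slice interval,
#' lateral and depth range) over the lesion's per-slice ground-truth
#' boxes. These are the units predictions are matched against.
#'
#' @inheritParams annotationToBoxes
#' @return data.frame with columns
#'   \code{lesionId, s0, s1, x0, x1, z0, z1}.
#' @export
annotationToCuboids <- function(annotation, depthWindow, volumeDepth = NULL) {
  bx <- annotationToBoxes(annotation, depthWindow, volumeDepth)
  if (!nrow(bx)) {
    return(cbind(lesionId = integer(0), emptyCuboids()[, 1:6]))
  }
  parts <- split(bx, bx$lesionId)
  out <- do.call(rbind, lapply(parts, function(g) {
    data.frame(
      lesionId = g$lesionId[1L],
      s0 = min(g$slice), s1 = max(g$slice) + 1L,
      x0 = min(g$x0), x1 = max(g$x1),
      z0 = min(g$z0), z1 = max(g$z1)
    )
  }))
  rownames(out) <- NULL
  out
}

#' Read and write detection cuboids (JSON)
#'
#' Schema: \code{\{"cuboids": [\{"s0","s1","x0","x1","z0","z1",
#' "confidence"\}]\}}. Confidences round-trip at full double precision.
#'
#' @param cuboids cuboid data.frame
#'   (\code{s0, s1, x0, x1, z0, z1, confidence}).
#' @param path JSON file path.
#' @export
writeDetections <- function(cuboids, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  recs <- lapply(seq_len(nrow(cuboids)), function(i) {
    as.list(cuboids[i, c("s0", "s1", "x0", "x1", "z0", "z1", "confidence")])
  })
  jsonlite::write_json(list(cuboids = recs), path,
    auto_unbox = TRUE, digits = I(17)
  )
  invisible(path)
}

#' @rdname writeDetections
#' @export
readDetections <- function(path) {
  if (!file.exists(path)) {
    stop("detections file not found: ", path)
  }
  doc <- tryCatch(jsonlite::read_json(path), error = function(e) {
    stop("malformed detections JSON ", path, ": ", conditionMessage(e))
  })
  if (is.null(doc$cuboids)) {
    stop("malformed detections JSON (missing 'cuboids'): ", path)
  }
  if (!length(doc$cuboids)) {
    return(emptyCuboids())
  }
  out <- do.call(rbind, lapply(doc$cuboids, function(cu) {
    data.frame(
      s0 = as.integer(cu$s0), s1 = as.integer(cu$s1),
      x0 = as.numeric(cu$x0), x1 = as.numeric(cu$x1),
      z0 = as.numeric(cu$z0), z1 = as.numeric(cu$z1),
      confidence = as.numeric(cu$confidence)
    )
  }))
  rownames(out) <- NULL
  out
}

#' Read and write the dataset index (CSV)
#'
#' The index lists one volume per row: identity
#' (\code{participantId, eye, visitId}), the volume and annotation file
#' paths, and the volume-level label \code{hasSubsidence}. The identity
#' triple must be unique.
#'
#' @param index data.frame with the columns above.
#' @param path CSV file path.
#' @export
writeDatasetIndex <- function(index, path) {
  checkDatasetIndex(index)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(index, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDatasetIndex
#' @export
readDatasetIndex <- function(path) {
  if (!file.exists(path)) {
    stop("index file not found: ", path)
  }
  idx <- read.csv(path, stringsAsFactors = FALSE)
  idx$hasSubsidence <- as.logical(idx$hasSubsidence)
  checkDatasetIndex(idx)
  idx
}

checkDatasetIndex <- function(index) {
  need <- c(
    "participantId", "eye", "visitId", "volumePath",
    "annotationPath", "hasSubsidence"
  )
  missing <- setdiff(need, names(index))
  if (length(missing)) {
    stop("dataset index missing columns: ", paste(missing, collapse = ", "))
  }
  key <- paste(index$participantId, index$eye, index$visitId)
  if (anyDuplicated(key)) {
    stop("dataset index has duplicate (participant, eye, visit) records")
  }
  invisible(index)
}
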