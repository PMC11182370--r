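#' @import methods
#' @importFrom stats rgamma rnorm runif median quantile sd runmed setNames
#' @importFrom utils head tail read.csv write.csv modifyList
NULL

## Coordinate convention used throughout the package:
## voxels are indexed (slice s, depth row z, lateral column x), all 0-based,
## and every interval (box edges, cuboid slice ranges, annotation runs) is
## half-open [lo, hi).

#' OCTVolume: a retinal OCT volume
#'
#' An OCT volume is a stack of B-scans (cross-sectional images). Voxels are
#' stored as a 3D array indexed \code{(slice, depth row, lateral column)}.
#' Intensities are either unsigned integers (8- or 16-bit grayscale,
#' \code{bitDepth} 8 or 16) or unit-interval floats (\code{bitDepth}
#' \code{NA}). Acquisition identity (participant, eye, visit) travels with
#' the volume so that evaluation can aggregate confidences hierarchically.
#'
#' @slot voxels 3D numeric array, dim \code{c(nSlices, depth, width)}.
#' @slot participantId,visitId character identifiers.
#' @slot eye \code{"left"} or \code{"right"}.
#' @slot bitDepth integer 8 or 16 for integer grayscale, \code{NA} for
#'   unit-interval float intensities.
#'
#' @examples
#' v <- OCTVolume(array(0, c(3, 8, 10)), participantId = "P01", eye = "left")
#' nSlices(v)
#' @export
setClass("OCTVolume",
  representation(
    voxels = "array",
    participantId = "character",
    eye = "character",
    visitId = "character",
    bitDepth = "integer"
  )
)

setValidity("OCTVolume", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L) {
    return("voxels must be a 3D array (slice, depth, width)")
  }
  if (dim(v)[1L] < 1L) {
    return("volume must contain at least one slice")
  }
  if (any(!is.finite(v))) {
    return("voxel intensities must be finite")
  }
  if (any(v < 0)) {
    return("voxel intensities must be non-negative")
  }
  bd <- object@bitDepth
  if (length(bd) != 1L || !(is.na(bd) || bd %in% c(8L, 16L))) {
    return("bitDepth must be 8, 16 or NA (unit-interval float)")
  }
  if (!is.na(bd)) {
    if (any(v != round(v)) || any(v > 2^bd - 1)) {
      return(sprintf("integer volume values must be whole numbers in [0, %d]", 2^bd - 1))
    }
  } else if (any(v > 1)) {
    return("float volumes must have intensities in [0, 1]")
  }
  if (!object@eye %in% c("left", "right")) {
    return("eye must be 'left' or 'right'")
  }
  TRUE
})

#' Construct an OCTVolume
#'
#' @param voxels 3D array indexed (slice, depth row, lateral column).
#' @param participantId,visitId identifiers (free-form strings).
#' @param eye \code{"left"} or \code{"right"}.
#' @param bitDepth 8 or 16 for integer grayscale volumes, \code{NA}
#'   (default) for unit-interval floats.
#' @return An \linkS4class{OCTVolume}.
#' @export
OCTVolume <- function(voxels, participantId = "unknown", eye = "left",
                      visitId = "V0", bitDepth = NA_integer_) {
  storage.mode(voxels) <- "double"
  new("OCTVolume",
    voxels = voxels, participantId = as.character(participantId),
    eye = as.character(eye), visitId = as.character(visitId),
    bitDepth = as.integer(bitDepth)
  )
}

#' @rdname OCTVolume-accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' Accessors for OCTVolume
#'
#' \code{voxels} returns the raw 3D array; \code{nSlices},
#' \code{axialSize} and \code{lateralSize} return the three dimensions;
#' \code{getSlice} extracts one B-scan as a depth x width matrix
#' (0-based slice index).
#'
#' @param object an \linkS4class{OCTVolume}.
#' @name OCTVolume-accessors
#' @export
setMethod("voxels", "OCTVolume", function(object) object@voxels)

#' @rdname OCTVolume-accessors
#' @export
setGeneric("nSlices", function(object) standardGeneric("nSlices"))
#' @rdname OCTVolume-accessors
setMethod("nSlices", "OCTVolume", function(object) dim(object@voxels)[1L])

#' @rdname OCTVolume-accessors
#' @export
setGeneric("axialSize", function(object) standardGeneric("axialSize"))
#' @rdname OCTVolume-accessors
setMethod("axialSize", "OCTVolume", function(object) dim(object@voxels)[2L])

#' @rdname OCTVolume-accessors
#' @export
setGeneric("lateralSize", function(object) standardGeneric("lateralSize"))
#' @rdname OCTVolume-accessors
setMethod("lateralSize", "OCTVolume", function(object) dim(object@voxels)[3L])

#' @rdname OCTVolume-accessors
#' @export
setGeneric("participantId", function(object) standardGeneric("participantId"))
#' @rdname OCTVolume-accessors
setMethod("participantId", "OCTVolume", function(object) object@participantId)

#' @rdname OCTVolume-accessors
#' @export
setGeneric("eyeSide", function(object) standardGeneric("eyeSide"))
#' @rdname OCTVolume-accessors
setMethod("eyeSide", "OCTVolume", function(object) object@eye)

#' @rdname OCTVolume-accessors
#' @export
setGeneric("visitId", function(object) standardGeneric("visitId"))
#' @rdname OCTVolume-accessors
setMethod("visitId", "OCTVolume", function(object) object@visitId)

#' @rdname OCTVolume-accessors
#' @export
setGeneric("bitDepth", function(object) standardGeneric("bitDepth"))
#' @rdname OCTVolume-accessors
setMethod("bitDepth", "OCTVolume", function(object) object@bitDepth)

#' @rdname OCTVolume-accessors
#' @param s 0-based slice index.
#' @export
getSlice <- function(object, s) {
  stopifnot(is(object, "OCTVolume"))
  if (s < 0 || s >= nSlices(object)) {
    stop("slice index out of range: ", s)
  }
  m <- object@voxels[s + 1L, , , drop = TRUE]
  dim(m) <- dim(object@voxels)[2:3]
  m
}

setMethod("show", "OCTVolume", function(object) {
  d <- dim(object@voxels)
  bd <- if (is.na(object@bitDepth)) "float" else paste0(object@bitDepth, "-bit")
  cat(sprintf(
    "OCTVolume: %d B-scans of %d x %d px (%s)\n  participant %s, %s eye, visit %s\n",
    d[1L], d[2L], d[3L], bd, object@participantId, object@eye, object@visitId
  ))
})

#' SubsidenceAnnotation: grader A-scan marks for OPL subsidence
#'
#' Graders mark subsidence by denoting the affected A-scans (lateral
#' columns) on each B-scan. The annotation is a table of column runs,
#' one row per maximal run: \code{lesionId} (integer), \code{slice}
#' (0-based B-scan index) and the half-open lateral extent
#' \code{[x0, x1)}. Runs of one lesion on one slice never overlap.
#'
#' @slot runs data.frame with integer columns
#'   \code{lesionId, slice, x0, x1}.
#' @export
setClass("SubsidenceAnnotation", representation(runs = "data.frame"))

setValidity("SubsidenceAnnotation", function(object) {
  r <- object@runs
  need <- c("lesionId", "slice", "x0", "x1")
  if (!all(need %in% names(r))) {
    return(paste("runs must have columns", paste(need, collapse = ", ")))
  }
  if (nrow(r) == 0L) {
    return(TRUE)
  }
  if (any(r$x0 < 0) || any(r$x0 >= r$x1) || any(r$slice < 0)) {
    return("runs must satisfy 0 <= x0 < x1 and slice >= 0")
  }
  ## runs of one lesion on one slice must not overlap
  key <- split(r, list(r$lesionId, r$slice), drop = TRUE)
  for (g in key) {
    if (nrow(g) > 1L) {
      g <- g[order(g$x0), ]
      if (any(g$x0[-1L] < g$x1[-nrow(g)])) {
        return("overlapping runs within one lesion on one slice")
      }
    }
  }
  TRUE
})

#' Construct a SubsidenceAnnotation
#'
#' @param runs data.frame with columns \code{lesionId, slice, x0, x1}
#'   (0-based, half-open lateral runs). An empty data.frame (the default)
#'   gives an empty annotation, i.e. a volume without subsidence.
#' @return A \linkS4class{SubsidenceAnnotation}.
#' @export
SubsidenceAnnotation <- function(runs = emptyRuns()) {
  if (nrow(runs)) {
    runs <- data.frame(
      lesionId = as.integer(runs$lesionId), slice = as.integer(runs$slice),
      x0 = as.integer(runs$x0), x1 = as.integer(runs$x1)
    )
    runs <- runs[order(runs$lesionId, runs$slice, runs$x0), , drop = FALSE]
    rownames(runs) <- NULL
  }
  new("SubsidenceAnnotation", runs = runs)
}

emptyRuns <- function() {
  data.frame(
    lesionId = integer(0), slice = integer(0),
    x0 = integer(0), x1 = integer(0)
  )
}

#' @rdname SubsidenceAnnotation-accessors
#' @export
setGeneric("annotationRuns", function(object) standardGeneric("annotationRuns"))
#' Accessors for SubsidenceAnnotation
#'
#' @param object a \linkS4class{SubsidenceAnnotation}.
#' @name SubsidenceAnnotation-accessors
#' @export
setMethod("annotationRuns", "SubsidenceAnnotation", function(object) object@runs)

#' @rdname SubsidenceAnnotation-accessors
#' @export
setGeneric("nLesions", function(object) standardGeneric("nLesions"))
#' @rdname SubsidenceAnnotation-accessors
setMethod("nLesions", "SubsidenceAnnotation", function(object) {
  length(unique(object@runs$lesionId))
})

#' @rdname SubsidenceAnnotation-accessors
#' @export
setGeneric("hasSubsidence", function(object) standardGeneric("hasSubsidence"))
#' @rdname SubsidenceAnnotation-accessors
setMethod("hasSubsidence", "SubsidenceAnnotation", function(object) {
  nrow(object@runs) > 0L
})

setMethod("show", "SubsidenceAnnotation", function(object) {
  cat(sprintf(
    "SubsidenceAnnotation: %d lesion(s), %d run(s) on %d slice(s)\n",
    nLesions(object), nrow(object@runs),
    length(unique(object@runs$slice))
  ))
})
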