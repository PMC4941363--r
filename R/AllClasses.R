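#' @useDynLib hcskit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats median mad sd quantile rnorm runif rpois rbinom kmeans
#'   dist hclust as.dendrogram order.dendrogram setNames pf cor coef resid
#' @importFrom utils write.csv read.csv packageVersion
NULL

#' FieldImage: one microscopy field
#'
#' A single imaged field: a named set of 2-D intensity channels (base
#' matrices, row/column pixel coordinates, 0-based in all reported
#' coordinates) together with its plate/well/field identity.
#'
#' @slot channels named list of numeric matrices, all with identical
#'   dimensions, intensities >= 0 (16-bit unsigned range by convention).
#' @slot plate plate identifier.
#' @slot well well identifier, e.g. "B03".
#' @slot field field index within the well (1-based).
#' @slot meta free-form list (simulation seed, clipping counts, ...).
#' @export
setClass("FieldImage",
  representation(channels = "list", plate = "character",
                 well = "character", field = "integer", meta = "list"),
  prototype(channels = list(), plate = "plate1", well = "A01",
            field = 1L, meta = list()))

setValidity("FieldImage", function(object) {
  ch <- object@channels
  if (length(ch) == 0) return("at least one channel required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))))
    return("channels must be named")
  if (anyDuplicated(names(ch))) return("duplicate channel names")
  dims <- vapply(ch, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all channels must share identical dimensions")
  for (m in ch) {
    if (!is.matrix(m) || !is.numeric(m)) return("channels must be numeric matrices")
    if (any(m < 0)) return("intensities must be >= 0")
  }
  TRUE
})

#' SegmentationResult: matched nuclear and cell label masks
#'
#' Nuclear and cell label masks share label IDs; for every label the nucleus
#' is contained in its cell mask and cell masks are pairwise disjoint (they
#' are label images, so disjointness is structural). Counts of discarded
#' small and edge objects and the parameters used are carried along.
#'
#' @slot nuclearMask integer label matrix (0 = background).
#' @slot cellMask integer label matrix, same dimensions and label set.
#' @slot discardedSmall number of objects dropped by the minimum-area filter.
#' @slot discardedEdge number of labels dropped because their cell mask
#'   touched the image border.
#' @slot parameters list of the parameters the chain ran with.
#' @export
setClass("SegmentationResult",
  representation(nuclearMask = "matrix", cellMask = "matrix",
                 discardedSmall = "integer", discardedEdge = "integer",
                 parameters = "list"))

setValidity("SegmentationResult", function(object) {
  nm <- object@nuclearMask; cm <- object@cellMask
  if (!all(dim(nm) == dim(cm))) return("mask dimensions differ")
  ln <- sort(unique(nm[nm > 0])); lc <- sort(unique(cm[cm > 0]))
  if (!identical(ln, lc)) return("label sets of nuclear and cell mask differ")
  if (any(nm > 0 & cm != nm)) return("nucleus pixels must lie in their own cell mask")
  TRUE
})

#' DoseResponseFit: four-parameter logistic fit
#'
#' Result of fitting the 4PL (Hill) model in log10-dose space. `ic50` is the
#' relative IC50: the dose at the halfway point between fitted top and
#' bottom. `flat = TRUE` means the flat (no-activity) model was preferred by
#' the extra-sum-of-squares F-test and the 4PL parameters should not be
#' interpreted.
#'
#' @slot top,bottom,hillSlope,ic50 fitted parameters (ic50 in the dose units
#'   of the input).
#' @slot rss residual sum of squares of the selected model.
#' @slot converged logical; FALSE when the fit failed or flat was selected.
#' @slot flat logical; TRUE when no dose activity was detected.
#' @slot ic50InRange logical; TRUE when the fitted ic50 lies within the
#'   tested dose range.
#' @slot direction "down" (inhibition) or "up".
#' @slot nPoints number of (dose, response) points used.
#' @export
setClass("DoseResponseFit",
  representation(top = "numeric", bottom = "numeric", hillSlope = "numeric",
                 ic50 = "numeric", rss = "numeric", converged = "logical",
                 flat = "logical", ic50InRange = "logical",
                 direction = "character", nPoints = "integer"))

setValidity("DoseResponseFit", function(object) {
  if (isTRUE(object@converged) && !isTRUE(object@flat) &&
      (is.na(object@ic50) || object@ic50 <= 0))
    return("converged fit requires ic50 > 0")
  TRUE
})

## ---- constructors -------------------------------------------------------

#' Create a FieldImage
#'
#' @param channels named list of numeric intensity matrices (equal dims).
#' @param plate,well plate and well identifiers.
#' @param field field index within the well.
#' @param meta optional metadata list.
#' @return A [FieldImage-class] object.
#' @export
FieldImage <- function(channels, plate = "plate1", well = "A01", field = 1L,
                       meta = list()) {
  new("FieldImage", channels = channels, plate = as.character(plate),
      well = as.character(well), field = as.integer(field), meta = meta)
}

## ---- accessors ----------------------------------------------------------

#' @describeIn FieldImage-class names of the intensity channels
#' @param x,object a `FieldImage`
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname FieldImage-class
#' @export
setMethod("channelNames", "FieldImage", function(x) names(x@channels))

#' @describeIn FieldImage-class extract one channel matrix by name
#' @param name channel name
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))
#' @rdname FieldImage-class
#' @export
setMethod("getChannel", "FieldImage", function(x, name) {
  if (!name %in% names(x@channels))
    stop("channel not present: ", name)
  x@channels[[name]]
})

#' @describeIn SegmentationResult-class the nuclear label mask
#' @param x,object a `SegmentationResult`
#' @export
setGeneric("nuclearMask", function(x) standardGeneric("nuclearMask"))
#' @rdname SegmentationResult-class
#' @export
setMethod("nuclearMask", "SegmentationResult", function(x) x@nuclearMask)

#' @describeIn SegmentationResult-class the cell label mask
#' @export
setGeneric("cellMask", function(x) standardGeneric("cellMask"))
#' @rdname SegmentationResult-class
#' @export
setMethod("cellMask", "SegmentationResult", function(x) x@cellMask)

#' @describeIn SegmentationResult-class number of segmented cells
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @rdname SegmentationResult-class
#' @export
setMethod("nCells", "SegmentationResult",
          function(x) length(unique(x@nuclearMask[x@nuclearMask > 0])))

setMethod("show", "FieldImage", function(object) {
  d <- dim(object@channels[[1]])
  cat("FieldImage", sprintf("%s/%s f%02d", object@plate, object@well,
                            object@field),
      sprintf("(%d x %d px)", d[1], d[2]), "\n")
  cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
})

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult:", nCells(object), "cells;",
      object@discardedSmall, "small and", object@discardedEdge,
      "edge objects discarded\n")
})

setMethod("show", "DoseResponseFit", function(object) {
  if (object@flat) {
    cat("DoseResponseFit: flat (no activity detected), n =",
        object@nPoints, "\n")
  } else {
    cat(sprintf(
      "DoseResponseFit (%s): top=%.4g bottom=%.4g slope=%.3g ic50=%.4g%s\n",
      object@direction, object@top, object@bottom, object@hillSlope,
      object@ic50, if (object@ic50InRange) "" else " (outside dose range)"))
  }
})
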