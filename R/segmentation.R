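## Nuclear/cell segmentation chain: rolling-ball background subtraction,
## locally adaptive mean threshold, minimum-area filter, distance-transform
## seeded watershed to split touching nuclei, contested circular dilation for
## approximate cell masks, and border-cell removal. 8-connectivity and exact
## Euclidean distances throughout; every stage is deterministic.

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale morphological opening of the
#' image with a flat disc structuring element of the given radius (the flat
#' disc stands in for the rolling ball; radius much larger than the nuclear
#' radius so nuclei are not flattened), then subtracts it, clipping at 0.
#'
#' @param image numeric intensity matrix.
#' @param radius structuring-element radius in pixels (>= 1).
#' @return background-subtracted matrix, same dimensions, >= 0.
#' @export
rollingBallSubtract <- function(image, radius = 50) {
  stopifnot(is.matrix(image), radius >= 1)
  if (radius > nrow(image) && radius > ncol(image))
    warning("rolling-ball radius exceeds both image dimensions; ",
            "background degenerates to the global minimum")
  bg <- cpp_disc_opening(image, as.integer(radius))
  pmax(image - bg, 0)
}

#' Locally adaptive mean threshold
#'
#' A pixel is foreground iff its intensity exceeds the mean over a
#' `window x window` neighborhood (symmetric border reflection) plus
#' `offset`.
#'
#' @param image numeric matrix.
#' @param window odd window edge length >= 3.
#' @param offset intensity offset added to the local mean; must exceed a few
#'   standard deviations of the background noise to keep speckle out.
#' @return logical foreground mask.
#' @export
adaptiveMeanThreshold <- function(image, window = 51, offset = 100) {
  stopifnot(is.matrix(image))
  if (window %% 2 == 0 || window < 3)
    stop("window must be odd and >= 3")
  lm <- cpp_local_mean(image, as.integer(window))
  image > lm + offset
}

#' Remove objects smaller than a minimum area
#'
#' Strict `<` semantics: objects with area `< minArea` pixels are discarded;
#' an object of exactly `minArea` pixels survives (default 20).
#'
#' @param mask logical mask or integer label matrix.
#' @param minArea minimum surviving area in pixels.
#' @return same kind as the input, with an attribute `discarded` giving the
#'   number of removed objects.
#' @export
filterSmallObjects <- function(mask, minArea = 20) {
  stopifnot(minArea >= 1)
  isLabel <- is.numeric(mask) || is.integer(mask)
  lab <- if (isLabel) {
    storage.mode(mask) <- "integer"
    mask
  } else cpp_label8(mask)
  labs <- lab[lab > 0]
  if (length(labs) == 0) {
    out <- if (isLabel) lab else mask
    attr(out, "discarded") <- 0L
    return(out)
  }
  areas <- tabulate(labs)
  drop <- which(areas > 0 & areas < minArea)
  keepMask <- lab > 0 & !(lab %in% drop)
  out <- if (isLabel) {
    l2 <- lab
    l2[!keepMask] <- 0L
    # renumber to a contiguous 1..N set
    u <- sort(unique(l2[l2 > 0]))
    if (length(u)) l2[] <- match(l2, u, nomatch = 1L) * (l2 > 0)
    storage.mode(l2) <- "integer"
    l2
  } else {
    keepMask
  }
  attr(out, "discarded") <- length(drop)
  out
}

#' Split touching nuclei by distance-transform seeded watershed
#'
#' Computes the exact Euclidean distance transform of the foreground, finds
#' seeds as the regional maxima of the distance map after h-maxima
#' suppression (depth `h`), and floods the negated distance map from those
#' seeds (Meyer flooding restricted to the foreground, deterministic
#' insertion-order tie-breaking). A dumbbell of two touching discs with two
#' distance maxima yields exactly two labels.
#'
#' @param mask logical foreground mask (small objects already removed).
#' @param h h-maxima suppression depth in pixels; maxima shallower than `h`
#'   above their saddle are merged (suppresses boundary-raggedness maxima).
#' @return integer label matrix, labels 1..N.
#' @export
splitTouchingNuclei <- function(mask, h = 1.2) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1, FALSE, TRUE)))
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (!any(mask)) {
    out <- matrix(0L, nrow(mask), ncol(mask))
    return(out)
  }
  dst <- sqrt(cpp_edt_sq(!mask))      # distance of fg pixels to background
  hmax <- cpp_reconstruct_dilation(dst - h, dst)
  seeds <- cpp_regional_maxima(hmax, mask)
  cpp_watershed(dst, mask, seeds)
}

#' Approximate cell masks by contested circular dilation
#'
#' Each nucleus is dilated by a disc of `dilationRadius` pixels. A pixel
#' reachable from more than one nucleus is assigned to the nucleus whose
#' nearest pixel is closest (exact Euclidean distance); exact ties go to the
#' lower label ID. Cell masks are therefore pairwise disjoint and each
#' nucleus is contained in its cell.
#'
#' @param nuclearMask integer nuclear label matrix.
#' @param dilationRadius dilation radius in pixels (>= 0).
#' @return integer cell label matrix with the same label set.
#' @export
makeCellMasks <- function(nuclearMask, dilationRadius = 10) {
  stopifnot(dilationRadius >= 0)
  storage.mode(nuclearMask) <- "integer"
  cpp_nearest_label_dilate(nuclearMask, dilationRadius)
}

#' Remove cells whose cell mask touches the image border
#'
#' The cell mask (not the nucleus) decides: any label whose cell mask
#' intersects the first/last row or column is removed from both masks.
#'
#' @param seg a [SegmentationResult-class].
#' @return a [SegmentationResult-class] with edge labels removed and
#'   `discardedEdge` updated; labels renumbered to 1..N.
#' @export
removeEdgeCells <- function(seg) {
  stopifnot(is(seg, "SegmentationResult"))
  cm <- seg@cellMask; nm <- seg@nuclearMask
  border <- c(cm[1, ], cm[nrow(cm), ], cm[, 1], cm[, ncol(cm)])
  bad <- unique(border[border > 0])
  if (length(bad)) {
    nm[nm %in% bad] <- 0L
    cm[cm %in% bad] <- 0L
  }
  u <- sort(unique(cm[cm > 0]))
  if (length(u)) {
    remap <- integer(max(u)); remap[u] <- seq_along(u)
    nm[nm > 0] <- remap[nm[nm > 0]]
    cm[cm > 0] <- remap[cm[cm > 0]]
  }
  storage.mode(nm) <- "integer"; storage.mode(cm) <- "integer"
  new("SegmentationResult", nuclearMask = nm, cellMask = cm,
      discardedSmall = seg@discardedSmall,
      discardedEdge = seg@discardedEdge + length(bad),
      parameters = seg@parameters)
}

#' Default segmentation parameters
#'
#' @param rollingBallRadius background structuring-element radius (px).
#' @param window,offset adaptive-mean-threshold window (odd, px) and
#'   intensity offset.
#' @param minArea minimum object area in pixels (strict `<` discards).
#' @param hMaxima watershed seed suppression depth (px).
#' @param dilationRadius cell-mask dilation radius (px).
#' @param dapiChannel name of the nuclear (DAPI) channel.
#' @return named list of parameters.
#' @export
segmentationParams <- function(rollingBallRadius = 50, window = 51,
                               offset = 100, minArea = 20, hMaxima = 1.2,
                               dilationRadius = 10, dapiChannel = "dapi") {
  list(rollingBallRadius = rollingBallRadius, window = window,
       offset = offset, minArea = minArea, hMaxima = hMaxima,
       dilationRadius = dilationRadius, dapiChannel = dapiChannel)
}

#' Segment one field from its DAPI channel
#'
#' Applies, in order: rolling-ball background subtraction, locally adaptive
#' mean threshold, minimum-area filter, distance-transform seeded watershed,
#' contested circular dilation, and border-cell removal. All parameters used
#' are recorded in the result.
#'
#' @param field a [FieldImage-class] containing the DAPI channel.
#' @param params a [segmentationParams()] list.
#' @return a [SegmentationResult-class].
#' @export
segmentField <- function(field, params = segmentationParams()) {
  stopifnot(is(field, "FieldImage"))
  if (!params$dapiChannel %in% channelNames(field))
    stop("DAPI channel '", params$dapiChannel, "' not present in field")
  img <- getChannel(field, params$dapiChannel)
  sub <- rollingBallSubtract(img, params$rollingBallRadius)
  fg <- adaptiveMeanThreshold(sub, params$window, params$offset)
  fg <- filterSmallObjects(fg, params$minArea)
  discardedSmall <- attr(fg, "discarded")
  nm <- splitTouchingNuclei(fg, params$hMaxima)
  # the watershed can carve sub-minArea fragments off ragged blobs
  nm <- filterSmallObjects(nm, params$minArea)
  discardedSmall <- discardedSmall + attr(nm, "discarded")
  cm <- makeCellMasks(nm, params$dilationRadius)
  seg <- new("SegmentationResult", nuclearMask = nm, cellMask = cm,
             discardedSmall = as.integer(discardedSmall),
             discardedEdge = 0L,
             parameters = c(params, list(plate = field@plate,
                                         well = field@well,
                                         field = field@field)))
  removeEdgeCells(seg)
}
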