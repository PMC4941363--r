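## Per-cell measurements: nuclear and cytoplasmic intensities, the
## nuclear/cytoplasmic translocation ratio, EdU S-phase classification,
## mitochondria morphometry and the JC-1 red/green ratio. The cytoplasmic
## compartment is the full cell-minus-nucleus region. Translocation uses the
## ratio of mean intensities, which is size-invariant.

#' Measure per-cell features on one field
#'
#' For every surviving label: nuclear area, per-channel nuclear mean and
#' integrated intensity, per-channel cytoplasmic mean (cell minus nucleus),
#' and the translocation ratio (nuclear mean / cytoplasmic mean) of the
#' designated marker channel. Cells with zero cytoplasm pixels are retained
#' with the ratio flagged undefined (`NA` + qc flag).
#'
#' @param seg a [SegmentationResult-class].
#' @param field the matching [FieldImage-class].
#' @param markerChannel channel whose N/C ratio is the translocation readout.
#' @return data.frame, one row per cell: `plate, well, field, label,
#'   nuc_area, <ch>_nuc_mean, <ch>_nuc_integrated, <ch>_cyto_mean, ...,
#'   ratio_<marker>, qc_flags`.
#' @export
measureCells <- function(seg, field, markerChannel = "marker") {
  stopifnot(is(seg, "SegmentationResult"), is(field, "FieldImage"))
  nm <- seg@nuclearMask; cm <- seg@cellMask
  d <- dim(getChannel(field, channelNames(field)[1]))
  if (!all(dim(nm) == d))
    stop("mask and channel dimensions differ")
  labs <- sort(unique(nm[nm > 0]))
  n <- length(labs)
  out <- data.frame(plate = rep(field@plate, n), well = rep(field@well, n),
                    field = rep(field@field, n), label = labs)
  if (n == 0) {
    out$nuc_area <- integer(0)
    return(out)
  }
  nucIdx <- nm > 0
  cytoIdx <- cm > 0 & nm == 0
  nucLab <- nm[nucIdx]
  cytoLab <- cm[cytoIdx]
  nucArea <- tabulate(nucLab, nbins = max(labs))[labs]
  cytoArea <- tabulate(cytoLab, nbins = max(labs))[labs]
  out$nuc_area <- nucArea
  for (ch in channelNames(field)) {
    img <- getChannel(field, ch)
    nsum <- rowsum(img[nucIdx], nucLab)[, 1]
    nmean <- nsum / nucArea
    csum <- if (any(cytoIdx)) rowsum(img[cytoIdx], cytoLab) else NULL
    cmean <- rep(NA_real_, n)
    if (!is.null(csum)) {
      hit <- match(labs, as.integer(rownames(csum)))
      cmean <- ifelse(is.na(hit), NA_real_, csum[hit, 1] / cytoArea)
    }
    out[[paste0(ch, "_nuc_mean")]] <- as.numeric(nmean)
    out[[paste0(ch, "_nuc_integrated")]] <- as.numeric(nsum)
    out[[paste0(ch, "_cyto_mean")]] <- as.numeric(cmean)
  }
  qc <- rep("", n)
  if (markerChannel %in% channelNames(field)) {
    nmean <- out[[paste0(markerChannel, "_nuc_mean")]]
    cmean <- out[[paste0(markerChannel, "_cyto_mean")]]
    ratio <- ifelse(is.na(cmean) | cmean == 0, NA_real_, nmean / cmean)
    qc[is.na(ratio)] <- "no_cytoplasm"
    out[[paste0("ratio_", markerChannel)]] <- ratio
  }
  out$qc_flags <- qc
  rownames(out) <- NULL
  out
}

#' Classify EdU-positive (S-phase) cells
#'
#' Default strategy: a two-class split of the log EdU nuclear means pooled
#' over the plate's vehicle wells (1-D 2-means), thresholding at the midpoint
#' (in log space) between the two class centers; the threshold is then frozen
#' and applied to the whole plate, so treatment cannot drift it. When
#' bimodality is not detected (class centers closer than `minSeparation`
#' log-units) or fewer than 50 vehicle cells are available, falls back to
#' `median + k * MAD` of the vehicle log intensities.
#'
#' @param records data.frame from [measureCells()] (rows from all wells of a
#'   plate), containing `<eduChannel>_nuc_mean`.
#' @param layout plate layout with columns `well`, `compound` (used to find
#'   vehicle wells).
#' @param eduChannel name of the EdU channel.
#' @param k MAD multiplier of the fallback strategy.
#' @param minSeparation minimal log10 separation of the two class centers to
#'   accept the bimodal split.
#' @return list with `records` (input plus logical `edu_positive`),
#'   `threshold` (on the intensity scale), `strategy` used, and `wellFractions`
#'   (data.frame `well, n, fraction_positive`).
#' @export
classifyEdu <- function(records, layout, eduChannel = "edu", k = 3,
                        minSeparation = 0.5) {
  col <- paste0(eduChannel, "_nuc_mean")
  if (!col %in% names(records)) stop("missing column: ", col)
  vehicleWells <- layout$well[layout$compound == "vehicle"]
  ref <- records[[col]][records$well %in% vehicleWells]
  ref <- ref[is.finite(ref) & ref > 0]
  x <- log10(ref)
  strategy <- "two-class"
  threshold <- NA_real_
  if (length(ref) >= 50) {
    init <- sort(quantile(x, c(0.25, 0.75)))
    km <- if (diff(init) > 0) {
      tryCatch(kmeans(x, centers = init, iter.max = 100,
                      algorithm = "Lloyd"),
               error = function(e) NULL)
    } else NULL
    if (!is.null(km)) {
      ctr <- sort(km$centers[, 1])
      if (diff(ctr) >= minSeparation) threshold <- 10^mean(ctr)
    }
  }
  if (is.na(threshold)) {
    if (length(ref) < 50)
      warning("fewer than 50 vehicle cells; falling back to median + k*MAD")
    strategy <- "median_mad"
    threshold <- 10^(median(x) + k * mad(x))
  }
  records$edu_positive <- records[[col]] > threshold
  agg <- split(records$edu_positive, records$well)
  wellFractions <- data.frame(
    well = names(agg),
    n = vapply(agg, length, integer(1)),
    fraction_positive = vapply(agg, function(v) mean(v, na.rm = TRUE),
                               numeric(1)),
    row.names = NULL)
  list(records = records, threshold = threshold, strategy = strategy,
       wellFractions = wellFractions)
}

#' Measure mitochondrial puncta on a single optical plane
#'
#' Puncta are segmented by rolling-ball background subtraction (small
#' radius), adaptive mean threshold, and a minimum-size filter; each punctum
#' is assigned to the cell containing its centroid (or left field-level when
#' the centroid falls outside all cell masks).
#'
#' @param mitoImage mitochondria-channel intensity matrix.
#' @param cellMask integer cell label matrix (same dimensions).
#' @param rollingBallRadius,window,offset puncta segmentation parameters
#'   (small structuring element: puncta are a few pixels wide).
#' @param minPunctaArea minimum punctum area in pixels.
#' @return data.frame, one row per punctum: `object, cell, area,
#'   mean_intensity, centroid_r, centroid_c` (0-based centroids).
#' @export
measureMitochondria <- function(mitoImage, cellMask,
                                rollingBallRadius = 5, window = 15,
                                offset = 100, minPunctaArea = 4) {
  stopifnot(all(dim(mitoImage) == dim(cellMask)))
  sub <- rollingBallSubtract(mitoImage, rollingBallRadius)
  fg <- adaptiveMeanThreshold(sub, window, offset)
  fg <- filterSmallObjects(fg, minPunctaArea)
  lab <- cpp_label8(fg)
  labs <- sort(unique(lab[lab > 0]))
  if (!length(labs))
    return(data.frame(object = integer(0), cell = integer(0),
                      area = integer(0), mean_intensity = numeric(0),
                      centroid_r = numeric(0), centroid_c = numeric(0)))
  idx <- which(lab > 0, arr.ind = TRUE)
  L <- lab[lab > 0]
  area <- tabulate(L)[labs]
  isum <- rowsum(mitoImage[lab > 0], L)[, 1]
  rbar <- rowsum(as.numeric(idx[, 1] - 1), L)[, 1] / area
  cbar <- rowsum(as.numeric(idx[, 2] - 1), L)[, 1] / area
  cellOf <- cellMask[cbind(pmin(pmax(round(rbar) + 1, 1), nrow(cellMask)),
                           pmin(pmax(round(cbar) + 1, 1), ncol(cellMask)))]
  data.frame(object = labs, cell = as.integer(cellOf), area = area,
             mean_intensity = as.numeric(isum / area),
             centroid_r = rbar, centroid_c = cbar)
}

#' JC-1 red/green ratio per cell
#'
#' Per cell, the ratio of mean red to mean green intensity over the cell
#' mask; the well summary is the median ratio. Cells with zero green mean are
#' flagged undefined.
#'
#' @param red,green intensity matrices of the two JC-1 channels.
#' @param cellMask integer cell label matrix.
#' @return list with `cells` (data.frame `label, red_mean, green_mean,
#'   ratio`) and `wellMedian` (median of the defined ratios).
#' @export
jc1Ratio <- function(red, green, cellMask) {
  stopifnot(all(dim(red) == dim(green)), all(dim(red) == dim(cellMask)))
  labs <- sort(unique(cellMask[cellMask > 0]))
  if (!length(labs))
    return(list(cells = data.frame(label = integer(0), red_mean = numeric(0),
                                   green_mean = numeric(0),
                                   ratio = numeric(0)),
                wellMedian = NA_real_))
  sel <- cellMask > 0
  L <- cellMask[sel]
  area <- tabulate(L)[labs]
  rmean <- rowsum(red[sel], L)[, 1] / area
  gmean <- rowsum(green[sel], L)[, 1] / area
  ratio <- ifelse(gmean == 0, NA_real_, rmean / gmean)
  cells <- data.frame(label = labs, red_mean = as.numeric(rmean),
                      green_mean = as.numeric(gmean),
                      ratio = as.numeric(ratio))
  list(cells = cells, wellMedian = median(ratio, na.rm = TRUE))
}

#' Match measured cells to simulator ground truth
#'
#' A truth row matches a segmented cell when the true center falls inside
#' that cell's recovered nucleus. Used by the recovery tests and the
#' acceptance checks.
#'
#' @param truth simulator truth rows for one field (0-based centers).
#' @param seg the field's [SegmentationResult-class].
#' @return integer vector, for each truth row the matched label (0 = none).
#' @export
matchTruthToLabels <- function(truth, seg) {
  nm <- seg@nuclearMask
  if (nrow(truth) == 0) return(integer(0))
  ri <- pmin(pmax(round(truth$center_r) + 1, 1), nrow(nm))
  ci <- pmin(pmax(round(truth$center_c) + 1, 1), ncol(nm))
  as.integer(nm[cbind(ri, ci)])
}
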