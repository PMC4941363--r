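## Well-level aggregation, plate-control normalization, 4PL dose-response
## fitting (relative IC50), treatment x cell-line profile assembly and
## hierarchical clustering, Biolog phenotype-array Z-scoring, and relative
## cell-number comparison.

#' Aggregate per-cell records to well summaries
#'
#' @param records data.frame from [measureCells()] (optionally after
#'   [classifyEdu()]), possibly spanning many wells.
#' @param layout plate layout (`well, compound, dose, unit, combo_agonist,
#'   replicate`, optional `cell_line`, `timepoint`). Wells present in the
#'   layout but without cells are kept with `n_cells = 0` and flagged.
#' @param markerChannel marker channel name used for the nuclear level and
#'   translocation columns.
#' @return data.frame, one row per layout well: `n_cells`, `median_nuc`,
#'   `mean_nuc`, `mad_nuc`, `median_ratio`, `pct_edu_positive` (when EdU
#'   calls are present), `flag`.
#' @export
aggregateWells <- function(records, layout, markerChannel = "marker") {
  nucCol <- paste0(markerChannel, "_nuc_mean")
  ratCol <- paste0("ratio_", markerChannel)
  out <- layout
  n <- nrow(layout)
  out$n_cells <- 0L
  out$median_nuc <- NA_real_
  out$mean_nuc <- NA_real_
  out$mad_nuc <- NA_real_
  out$median_ratio <- NA_real_
  hasEdu <- "edu_positive" %in% names(records)
  if (hasEdu) out$pct_edu_positive <- NA_real_
  out$flag <- ""
  for (i in seq_len(n)) {
    rec <- records[records$well == layout$well[i], , drop = FALSE]
    out$n_cells[i] <- nrow(rec)
    if (nrow(rec) == 0) {
      out$flag[i] <- "empty_well"
      next
    }
    if (nucCol %in% names(rec)) {
      out$median_nuc[i] <- median(rec[[nucCol]], na.rm = TRUE)
      out$mean_nuc[i] <- mean(rec[[nucCol]], na.rm = TRUE)
      out$mad_nuc[i] <- mad(rec[[nucCol]], na.rm = TRUE)
    }
    if (ratCol %in% names(rec))
      out$median_ratio[i] <- median(rec[[ratCol]], na.rm = TRUE)
    if (hasEdu)
      out$pct_edu_positive[i] <- 100 * mean(rec$edu_positive, na.rm = TRUE)
  }
  out
}

#' Normalize well summaries to plate controls
#'
#' Fold-change scale: `value / median(vehicle wells)`. Percent-of-agonist
#' scale: `100 * (value - vehicle) / (agonist - vehicle)`, where vehicle and
#' agonist are the medians of the respective control wells (agonist wells =
#' `compound == agonist` without combo flag).
#'
#' @param summaries data.frame from [aggregateWells()].
#' @param valueColumn which summary column to normalize.
#' @param scale `"fold"` or `"percent"`.
#' @param agonist compound name of the agonist control (e.g. `"DHT"`).
#' @return `summaries` with an added `norm_value` column; the scale and
#'   control medians are attached as attributes `scale`, `vehicleMedian`,
#'   `agonistMedian`.
#' @export
normalizePlate <- function(summaries, valueColumn = "median_nuc",
                           scale = c("fold", "percent"), agonist = "DHT") {
  scale <- match.arg(scale)
  v <- summaries[[valueColumn]]
  vehIdx <- summaries$compound == "vehicle"
  if (!any(vehIdx)) stop("no vehicle wells on this plate")
  vehMed <- median(v[vehIdx], na.rm = TRUE)
  agMed <- NA_real_
  if (scale == "fold") {
    summaries$norm_value <- v / vehMed
  } else {
    agIdx <- summaries$compound == agonist & !summaries$combo_agonist
    if (!any(agIdx))
      stop("percent-of-agonist scale requested but no '", agonist,
           "' wells present")
    agMed <- median(v[agIdx], na.rm = TRUE)
    summaries$norm_value <- 100 * (v - vehMed) / (agMed - vehMed)
  }
  attr(summaries, "scale") <- scale
  attr(summaries, "vehicleMedian") <- vehMed
  attr(summaries, "agonistMedian") <- agMed
  summaries
}

## ---- dose response ------------------------------------------------------

.fourPL <- function(x, top, bottom, slope, xmid, direction) {
  s <- if (direction == "down") 1 else -1
  bottom + (top - bottom) / (1 + 10^(s * slope * (x - xmid)))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Fits the 4PL in log10-dose space by bounded nonlinear least squares
#' (Levenberg-Marquardt) with multi-start initialization: top/bottom from
#' the response extrema, midpoint candidates from the doses bracketing
#' half-max, slope in \{0.5, 1, 2\}. The reported IC50 is the relative IC50:
#' the dose at the halfway point between fitted top and bottom. "No
#' activity" is declared when the flat (constant) model is not worse by an
#' extra-sum-of-squares F-test at `alpha`; the fit is then returned with
#' `flat = TRUE` and no IC50.
#'
#' Zero doses (explicit vehicle points) are excluded from the logistic fit;
#' negative doses are rejected.
#'
#' @param doses numeric doses (>= 0; zeros dropped as baseline anchors).
#' @param responses responses on a common normalized scale.
#' @param direction `"down"` for inhibition curves, `"up"` for activation.
#' @param alpha F-test level for flat-model selection.
#' @return a [DoseResponseFit-class].
#' @export
fitDoseResponse <- function(doses, responses, direction = c("down", "up"),
                            alpha = 0.05) {
  direction <- match.arg(direction)
  stopifnot(length(doses) == length(responses))
  if (any(doses < 0)) stop("negative doses rejected")
  keep <- doses > 0 & is.finite(responses)
  x <- log10(doses[keep]); y <- responses[keep]
  nd <- length(unique(x))
  if (nd < 4) stop("need >= 4 distinct positive doses")
  n <- length(y)
  flatRss <- sum((y - mean(y))^2)
  mkFit <- function(top, bottom, slope, xmid, rss, conv, flat) {
    ic50 <- if (flat || !conv) NA_real_ else 10^xmid
    new("DoseResponseFit", top = top, bottom = bottom, hillSlope = slope,
        ic50 = ic50, rss = rss, converged = conv && !flat, flat = flat,
        ic50InRange = isTRUE(!flat && conv && ic50 >= min(10^x) &&
                               ic50 <= max(10^x)),
        direction = direction, nPoints = as.integer(n))
  }
  scale2 <- max(flatRss, (mean(y))^2 * n, 1e-300)
  if (flatRss <= 1e-18 * scale2)  # responses numerically constant
    return(mkFit(mean(y), mean(y), NA_real_, NA_real_, flatRss, FALSE, TRUE))

  top0 <- max(y); bottom0 <- min(y)
  half <- (top0 + bottom0) / 2
  ord <- order(x)
  xo <- x[ord]; yo <- y[ord]
  # dose(s) bracketing half-max
  cross <- which(diff(sign(yo - half)) != 0)
  xmid0 <- if (length(cross)) (xo[cross[1]] + xo[cross[1] + 1]) / 2 else
    median(x)
  starts <- expand.grid(slope = c(0.5, 1, 2),
                        xmid = unique(c(xmid0, median(x))))
  lower <- c(top = -Inf, bottom = -Inf, slope = 0.05, xmid = min(x) - 3)
  upper <- c(top = Inf, bottom = Inf, slope = 20, xmid = max(x) + 3)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- list(top = top0, bottom = bottom0, slope = starts$slope[i],
               xmid = starts$xmid[i])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ .fourPL(x, top, bottom, slope, xmid, direction),
        start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, par = coef(fit))
  }
  if (is.null(best))
    return(mkFit(mean(y), mean(y), NA_real_, NA_real_, flatRss, FALSE, TRUE))
  # flat vs 4PL: extra-sum-of-squares F-test
  flat <- FALSE
  if (n > 4) {
    if (best$rss <= 1e-18 * scale2) {
      flat <- FALSE
    } else {
      Fstat <- ((flatRss - best$rss) / 3) / (best$rss / (n - 4))
      pval <- 1 - pf(Fstat, 3, n - 4)
      flat <- !is.finite(Fstat) || pval >= alpha
    }
  }
  p <- best$par
  if (flat)
    return(mkFit(mean(y), mean(y), NA_real_, NA_real_, flatRss, FALSE, TRUE))
  mkFit(unname(p["top"]), unname(p["bottom"]), unname(p["slope"]),
        unname(p["xmid"]), best$rss, TRUE, FALSE)
}

## ---- profiles and clustering --------------------------------------------

#' Assemble the treatment x cell-line profile matrix
#'
#' One row per condition (compound alone and compound+agonist as distinct
#' rows), one column per cell line; each value is the normalized well value
#' averaged over replicate wells. Missing combinations become `NA`.
#' Duplicate condition/cell-line pairs that are not replicate wells and
#' disagree are rejected.
#'
#' @param summaries data.frame with columns `compound`, `combo_agonist`,
#'   `cell_line`, `norm_value`, and (for replicate averaging) `well`;
#'   optionally `dose` (appended to the condition label when a compound
#'   appears at several doses).
#' @param agonistLabel suffix used for combo conditions.
#' @return numeric matrix (conditions x cell lines).
#' @export
buildProfileMatrix <- function(summaries, agonistLabel = "+DHT") {
  need <- c("compound", "combo_agonist", "cell_line", "norm_value")
  miss <- setdiff(need, names(summaries))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  s <- summaries
  lab <- s$compound
  if ("dose" %in% names(s)) {
    multi <- tapply(s$dose, s$compound, function(d) length(unique(d)) > 1)
    sel <- multi[s$compound]
    lab[sel] <- paste0(s$compound[sel], "@", signif(s$dose[sel], 3),
                       s$unit[sel])
  }
  lab[s$combo_agonist] <- paste0(lab[s$combo_agonist], agonistLabel)
  key <- paste(lab, s$cell_line, sep = "\r")
  if (!"well" %in% names(s)) {
    dup <- duplicated(key)
    if (any(dup)) {
      agree <- tapply(s$norm_value, key, function(v)
        max(v) - min(v) < 1e-12 * max(1, abs(mean(v))))
      if (!all(agree))
        stop("duplicate condition/cell-line pairs with conflicting values")
    }
  }
  val <- tapply(s$norm_value, list(lab, s$cell_line), mean)
  m <- matrix(val, nrow = nrow(val), dimnames = dimnames(val))
  m
}

#' Hierarchically cluster screening profiles
#'
#' Pairwise Euclidean distances and agglomerative clustering (default
#' average linkage / UPGMA). Rows (or columns) containing `NA` must be
#' handled explicitly: with `naAction = "drop"` they are removed (and
#' reported via an attribute), otherwise clustering refuses.
#'
#' @param mat profile matrix from [buildProfileMatrix()].
#' @param axis cluster the `"rows"` (conditions) or `"cols"` (cell lines).
#' @param linkage linkage method passed to [stats::hclust()].
#' @param naAction `"error"` or `"drop"`.
#' @return an [stats::hclust] tree (merge heights = dendrogram heights);
#'   attribute `dropped` lists any removed labels.
#' @export
clusterProfiles <- function(mat, axis = c("rows", "cols"),
                            linkage = "average",
                            naAction = c("error", "drop")) {
  axis <- match.arg(axis)
  naAction <- match.arg(naAction)
  if (axis == "cols") mat <- t(mat)
  dropped <- character(0)
  bad <- apply(mat, 1, function(r) any(!is.finite(r)))
  if (any(bad)) {
    if (naAction == "error")
      stop("masked/missing values on the clustered axis; impute or drop first")
    dropped <- rownames(mat)[bad]
    mat <- mat[!bad, , drop = FALSE]
  }
  if (nrow(mat) < 2) stop("need at least 2 profiles to cluster")
  hc <- hclust(dist(mat, method = "euclidean"), method = linkage)
  attr(hc, "dropped") <- dropped
  hc
}

#' Export a dendrogram as Newick
#'
#' @param hc an [stats::hclust] tree.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
dendrogramNewick <- function(hc, file = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Top-level split membership of a dendrogram
#'
#' Labels of the two clusters produced by cutting the tree into two groups;
#' convenient for checking that vehicle-like and agonist-like profiles
#' separate at the root.
#'
#' @param hc an [stats::hclust] tree.
#' @return list of two character vectors of labels.
#' @export
topLevelSplit <- function(hc) {
  ct <- stats::cutree(hc, k = 2)
  split(names(ct), ct)
}

## ---- Biolog -------------------------------------------------------------

#' Correct and Z-score Biolog phenotype plates
#'
#' Per plate, corrected value = raw - mean(negative-control wells of the
#' same plate). Z-scores are computed per carbon source across all corrected
#' replicate values (row mean 0, sd 1); zero-variance rows are set to 0 and
#' flagged.
#'
#' @param vehiclePlates,treatedPlates lists of plates as produced by
#'   [simulateBiolog()]: each `list(values, negativeWells, condition)`.
#' @return list with `corrected` (sources x replicates matrix, vehicle
#'   columns first), `zscore` (same shape), `zeroVarianceRows` (indices).
#' @export
biologAnalyze <- function(vehiclePlates, treatedPlates) {
  plates <- c(vehiclePlates, treatedPlates)
  if (!length(plates)) stop("no plates supplied")
  correct <- function(p) {
    stopifnot(length(p$negativeWells) >= 1)
    src <- setdiff(seq_along(p$values), p$negativeWells)
    p$values[src] - mean(p$values[p$negativeWells])
  }
  cols <- lapply(plates, correct)
  nsrc <- unique(vapply(cols, length, integer(1)))
  if (length(nsrc) != 1) stop("plates disagree on source-well count")
  corrected <- do.call(cbind, cols)
  colnames(corrected) <- c(
    paste0("vehicle_", seq_along(vehiclePlates)),
    paste0("treated_", seq_along(treatedPlates)))
  rownames(corrected) <- paste0("source_", seq_len(nrow(corrected)))
  mu <- rowMeans(corrected)
  sdv <- apply(corrected, 1, sd)
  zeroVar <- which(sdv == 0)
  sdv[sdv == 0] <- 1
  z <- (corrected - mu) / sdv
  z[zeroVar, ] <- 0
  list(corrected = corrected, zscore = z,
       zeroVarianceRows = as.integer(zeroVar))
}

## ---- cell counts --------------------------------------------------------

#' Relative cell numbers versus vehicle
#'
#' Per timepoint (when present), relative count = `n_cells / median(vehicle
#' n_cells)`. Zero-cell wells yield 0 with a flag.
#'
#' @param summaries data.frame with `well`, `compound`, `n_cells`, optional
#'   `timepoint`.
#' @return `summaries` with added `relative_count` and `count_flag` columns.
#' @export
compareCellCounts <- function(summaries) {
  tp <- if ("timepoint" %in% names(summaries)) summaries$timepoint else
    rep(1, nrow(summaries))
  summaries$relative_count <- NA_real_
  summaries$count_flag <- ""
  for (t in unique(tp)) {
    sel <- tp == t
    veh <- summaries$n_cells[sel & summaries$compound == "vehicle"]
    if (!length(veh)) stop("no vehicle wells for timepoint ", t)
    ref <- median(veh)
    summaries$relative_count[sel] <- summaries$n_cells[sel] / ref
  }
  summaries$count_flag[summaries$n_cells == 0] <- "zero_cells"
  summaries
}
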