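## End-to-end driver: fields -> segmentation -> per-cell features -> EdU
## calls -> well summaries -> control normalization -> dose-response fits ->
## (optionally) profile matrix + clustering. Deterministic given its inputs;
## every output CSV is accompanied by a resolved-configuration sidecar.

#' Run the full analysis pipeline
#'
#' @param input either the list returned by [simulatePlate()] or a directory
#'   written by [writePlate()] (TIFFs + `layout.csv`).
#' @param params segmentation parameters ([segmentationParams()]).
#' @param markerChannel receptor channel for level/translocation readouts.
#' @param eduChannel EdU channel name, or `NULL` to skip S-phase calls.
#' @param normScale `"fold"` or `"percent"` (see [normalizePlate()]).
#' @param agonist agonist compound name for the percent scale.
#' @param outDir optional output directory; when given, writes `cells.csv`,
#'   `wells.csv`, `fits.csv` (when any compound has a dose series),
#'   `profile.csv` + `dendrogram.nwk` (when the layout carries several cell
#'   lines), and `run_config.txt`.
#' @return list with `cells`, `wells`, `fits`, `profile`, `tree`,
#'   `eduThreshold`, `segmentation` (per-field object counts).
#' @export
runPipeline <- function(input, params = segmentationParams(),
                        markerChannel = "marker", eduChannel = "edu",
                        normScale = "fold", agonist = "DHT",
                        outDir = NULL) {
  if (is.character(input)) {
    fields <- readFields(input)
    layout <- readPlateLayout(file.path(input, "layout.csv"))
  } else {
    fields <- input$fields
    layout <- input$layout
  }
  if (!length(fields)) stop("no fields to analyze")

  cellList <- list()
  segStats <- list()
  for (f in fields) {
    seg <- segmentField(f, params)
    rec <- measureCells(seg, f, markerChannel = markerChannel)
    cellList[[length(cellList) + 1]] <- rec
    segStats[[length(segStats) + 1]] <- data.frame(
      well = f@well, field = f@field, n_cells = nCells(seg),
      discarded_small = seg@discardedSmall,
      discarded_edge = seg@discardedEdge)
  }
  cells <- do.call(rbind, cellList)
  segStats <- do.call(rbind, segStats)

  eduThreshold <- NA_real_
  if (!is.null(eduChannel) &&
      paste0(eduChannel, "_nuc_mean") %in% names(cells)) {
    ec <- classifyEdu(cells, layout, eduChannel = eduChannel)
    cells <- ec$records
    eduThreshold <- ec$threshold
  }

  wells <- aggregateWells(cells, layout, markerChannel = markerChannel)
  wells <- tryCatch(
    normalizePlate(wells, scale = normScale, agonist = agonist),
    error = function(e) {
      warning("normalization skipped: ", conditionMessage(e))
      wells
    })

  # dose-response fits for compounds with a dose series
  fits <- NULL
  if ("norm_value" %in% names(wells)) {
    grp <- unique(wells[wells$compound != "vehicle",
                        c("compound", "combo_agonist")])
    rows <- list()
    for (g in seq_len(nrow(grp))) {
      sel <- wells$compound == grp$compound[g] &
        wells$combo_agonist == grp$combo_agonist[g]
      d <- wells$dose[sel]; y <- wells$norm_value[sel]
      if (length(unique(d[d > 0])) < 4) next
      fit <- tryCatch(fitDoseResponse(d, y, direction = "down"),
                      error = function(e) NULL)
      if (is.null(fit)) next
      rows[[length(rows) + 1]] <- data.frame(
        compound = grp$compound[g], combo_agonist = grp$combo_agonist[g],
        top = fit@top, bottom = fit@bottom, hill_slope = fit@hillSlope,
        ic50 = fit@ic50, rss = fit@rss, converged = fit@converged,
        flat = fit@flat, ic50_in_range = fit@ic50InRange)
    }
    if (length(rows)) fits <- do.call(rbind, rows)
  }

  profile <- NULL; tree <- NULL
  if ("cell_line" %in% names(wells) &&
      length(unique(wells$cell_line)) > 1 && "norm_value" %in% names(wells)) {
    profile <- buildProfileMatrix(wells)
    if (nrow(profile) >= 2 && !anyNA(profile))
      tree <- clusterProfiles(profile)
  }

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    write.csv(cells, file.path(outDir, "cells.csv"), row.names = FALSE)
    write.csv(wells, file.path(outDir, "wells.csv"), row.names = FALSE)
    write.csv(segStats, file.path(outDir, "segmentation.csv"),
              row.names = FALSE)
    if (!is.null(fits))
      write.csv(fits, file.path(outDir, "fits.csv"), row.names = FALSE)
    if (!is.null(profile))
      write.csv(profile, file.path(outDir, "profile.csv"))
    if (!is.null(tree))
      dendrogramNewick(tree, file.path(outDir, "dendrogram.nwk"))
    writeConfigText(c(params, list(markerChannel = markerChannel,
                                   normScale = normScale)),
                    file.path(outDir, "run_config.txt"))
  }
  list(cells = cells, wells = wells, fits = fits, profile = profile,
       tree = tree, eduThreshold = eduThreshold, segmentation = segStats)
}
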