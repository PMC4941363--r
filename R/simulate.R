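## Synthetic plate simulator: renders multi-channel fields with per-cell
## ground truth so the whole measurement chain can be tested against known
## answers. Nuclei are discs and cytoplasm a concentric annulus; the pipeline
## only ever uses area and containment, so this geometry exercises every
## downstream measurement.

#' Four-parameter logistic (Hill) effect model
#'
#' @param top,bottom asymptotic response levels (response units).
#' @param ec50 midpoint concentration (> 0), in the dose units used
#'   throughout the scenario.
#' @param hillSlope Hill coefficient (> 0).
#' @param direction `"down"` (response falls from `top` at dose 0 towards
#'   `bottom`) or `"up"` (rises from `bottom` towards `top`).
#' @return An object of class `effectModel`.
#' @export
effectModel <- function(top, bottom, ec50, hillSlope = 1,
                        direction = c("down", "up")) {
  direction <- match.arg(direction)
  stopifnot(ec50 > 0, hillSlope > 0)
  structure(list(top = top, bottom = bottom, ec50 = ec50,
                 hillSlope = hillSlope, direction = direction),
            class = "effectModel")
}

#' Evaluate a 4PL effect model at given doses
#'
#' For `direction = "down"`:
#' `bottom + (top - bottom) / (1 + (dose/ec50)^hillSlope)`, so dose 0 gives
#' `top` and the midpoint sits at `ec50`. `"up"` is the mirrored curve
#' (dose 0 gives `bottom`).
#'
#' @param dose numeric vector of non-negative doses.
#' @param model an [effectModel()].
#' @return responses, same length as `dose`.
#' @export
hillResponse <- function(dose, model) {
  stopifnot(inherits(model, "effectModel"))
  if (any(dose < 0)) stop("doses must be >= 0")
  frac <- 1 / (1 + (dose / model$ec50)^model$hillSlope)
  if (model$direction == "down") {
    model$bottom + (model$top - model$bottom) * frac
  } else {
    model$top + (model$bottom - model$top) * frac
  }
}

#' Plate simulation configuration
#'
#' Collects plate geometry, rendering and noise parameters, and the condition
#' table. Each row of `conditions` is one treatment condition with its
#' generative truth: mean nuclear marker intensity (`nucMean`), true
#' nuclear/cytoplasmic ratio (`ratio`), S-phase fraction (`sPhaseFrac`),
#' relative cell density (`densityScale`), mitochondrial punctum intensity
#' (`mitoIntensity`) and JC-1 red/green ratio (`jc1Ratio`). Use
#' [doseResponseConditions()] to derive such rows from [effectModel()]s.
#'
#' The noise model is additive Gaussian read noise (sd `readNoiseSd`) plus an
#' intensity-proportional term with sd `shotScale * sqrt(signal)`; rendered
#' values are clipped to the 16-bit range `[0, 65535]` and clip events are
#' counted in the field metadata.
#'
#' @param conditions data.frame with columns `compound`, `dose`, `unit`,
#'   `comboAgonist`, `replicates`, `nucMean`, `ratio`, `sPhaseFrac`,
#'   `densityScale`, `mitoIntensity`, `jc1Ratio`. Must contain at least one
#'   `vehicle` row.
#' @param fieldSize field edge length in pixels.
#' @param cellsPerField expected cell count per field (Poisson mean before
#'   `densityScale`).
#' @param fieldsPerWell fields imaged per well.
#' @param touchingFraction fraction of cells placed as touching nuclear
#'   pairs (center distance drawn uniformly in
#'   `touchingRange * nuclearRadius`).
#' @param touchingRange range (in units of nuclear radius) for pair center
#'   distances; the default keeps two distance-transform maxima at least
#'   ~0.7 px above the saddle so the watershed split is well-posed.
#' @param nuclearRadius,cytoRadius nuclear and cytoplasmic disc radii (px),
#'   `cytoRadius > nuclearRadius`.
#' @param edgeMargin minimum distance from a cell center to the field border
#'   (px); the default keeps dilated cell masks off the border.
#' @param channels channels to render; subset of `dapi`, `marker`, `edu`,
#'   `mito`, `jc1red`, `jc1green`.
#' @param dapiIntensity DAPI foreground intensity.
#' @param eduNeg,eduPos EdU nuclear intensity for non-S and S-phase cells.
#' @param jc1Green JC-1 green-channel cell intensity.
#' @param mitoPerCell,mitoRadius mitochondrial puncta per cell and punctum
#'   radius (px).
#' @param cellCv,ratioCv lognormal cell-to-cell coefficients of variation of
#'   nuclear intensity and of the per-cell N/C ratio.
#' @param background,backgroundGradient flat background level and linear
#'   left-to-right gradient amplitude.
#' @param readNoiseSd,shotScale noise model parameters (see above).
#' @param seed integer seed; every well/field derives its own stream from it.
#' @return a list of class `plateSimConfig`.
#' @export
plateSimConfig <- function(conditions,
                           fieldSize = 448L,
                           cellsPerField = 50,
                           fieldsPerWell = 1L,
                           touchingFraction = 0.1,
                           touchingRange = c(1.3, 1.8),
                           nuclearRadius = 8,
                           cytoRadius = 19,
                           edgeMargin = nuclearRadius + 12,
                           channels = c("dapi", "marker", "edu"),
                           dapiIntensity = 3000,
                           eduNeg = 150, eduPos = 2500,
                           jc1Green = 800,
                           mitoPerCell = 6, mitoRadius = 2,
                           cellCv = 0.15, ratioCv = 0.2,
                           background = 100, backgroundGradient = 10,
                           readNoiseSd = 40, shotScale = 1,
                           seed = 1L) {
  stopifnot(is.data.frame(conditions), nrow(conditions) >= 1)
  need <- c("compound", "dose", "unit", "comboAgonist", "replicates",
            "nucMean", "ratio", "sPhaseFrac", "densityScale",
            "mitoIntensity", "jc1Ratio")
  miss <- setdiff(need, names(conditions))
  if (length(miss)) stop("conditions lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!any(conditions$compound == "vehicle"))
    stop("conditions must designate at least one 'vehicle' control row")
  stopifnot(fieldSize > 0, cellsPerField >= 0, fieldsPerWell >= 1,
            touchingFraction >= 0, touchingFraction <= 1,
            cytoRadius > nuclearRadius, nuclearRadius > 0,
            all(conditions$sPhaseFrac >= 0 & conditions$sPhaseFrac <= 1),
            all(conditions$dose >= 0), readNoiseSd >= 0, shotScale >= 0,
            background >= 0)
  cfg <- list(conditions = conditions, fieldSize = as.integer(fieldSize),
              cellsPerField = cellsPerField,
              fieldsPerWell = as.integer(fieldsPerWell),
              touchingFraction = touchingFraction,
              touchingRange = touchingRange,
              nuclearRadius = nuclearRadius, cytoRadius = cytoRadius,
              edgeMargin = edgeMargin, channels = channels,
              dapiIntensity = dapiIntensity, eduNeg = eduNeg,
              eduPos = eduPos, jc1Green = jc1Green,
              mitoPerCell = mitoPerCell, mitoRadius = mitoRadius,
              cellCv = cellCv, ratioCv = ratioCv,
              background = background,
              backgroundGradient = backgroundGradient,
              readNoiseSd = readNoiseSd, shotScale = shotScale,
              seed = as.integer(seed))
  class(cfg) <- "plateSimConfig"
  cfg
}

#' Build condition rows from effect models over a dose grid
#'
#' Evaluates 4PL effect models over a dose grid to produce the generative
#' per-condition truth used by [plateSimConfig()]. The default agonist grid
#' follows the six-point 10 pM - 100 nM convention; antagonist scenarios
#' typically span 1-40 uM.
#'
#' @param compound compound name.
#' @param doses dose grid (> 0).
#' @param unit dose unit label (e.g. `"M"` or `"uM"`).
#' @param nucModel [effectModel()] for the true mean nuclear marker level.
#' @param ratioModel optional effect model for the N/C ratio; a single number
#'   keeps the ratio constant across doses.
#' @param sPhaseModel optional effect model for the S-phase fraction; a
#'   single number keeps it constant.
#' @param densityModel optional effect model for relative cell density.
#' @param mitoModel optional effect model for mitochondrial punctum
#'   intensity; default constant 500.
#' @param jc1Model optional effect model for the JC-1 red/green ratio;
#'   default constant 2.
#' @param comboAgonist logical; TRUE when the compound is dosed on top of
#'   the agonist.
#' @param replicates wells per condition (quadruplicate by convention).
#' @return data.frame of condition rows.
#' @export
doseResponseConditions <- function(compound, doses, unit = "M", nucModel,
                                   ratioModel = 1.5, sPhaseModel = 0.27,
                                   densityModel = 1, mitoModel = 500,
                                   jc1Model = 2,
                                   comboAgonist = FALSE, replicates = 4L) {
  stopifnot(all(doses > 0))
  evalm <- function(m, d) {
    if (inherits(m, "effectModel")) hillResponse(d, m) else rep(m, length(d))
  }
  data.frame(compound = compound, dose = doses, unit = unit,
             comboAgonist = comboAgonist, replicates = as.integer(replicates),
             nucMean = hillResponse(doses, nucModel),
             ratio = evalm(ratioModel, doses),
             sPhaseFrac = evalm(sPhaseModel, doses),
             densityScale = evalm(densityModel, doses),
             mitoIntensity = evalm(mitoModel, doses),
             jc1Ratio = evalm(jc1Model, doses),
             stringsAsFactors = FALSE)
}

#' A single control condition row
#'
#' @param compound `"vehicle"`, agonist name, etc.
#' @param nucMean,ratio,sPhaseFrac,densityScale,mitoIntensity,jc1Ratio
#'   generative truth for the condition.
#' @param dose,unit,comboAgonist,replicates layout bookkeeping.
#' @return one-row data.frame compatible with [plateSimConfig()].
#' @export
controlCondition <- function(compound = "vehicle", nucMean = 800,
                             ratio = 1.5, sPhaseFrac = 0.27,
                             densityScale = 1, mitoIntensity = 500,
                             jc1Ratio = 2, dose = 0, unit = "M",
                             comboAgonist = FALSE, replicates = 4L) {
  data.frame(compound = compound, dose = dose, unit = unit,
             comboAgonist = comboAgonist, replicates = as.integer(replicates),
             nucMean = nucMean, ratio = ratio, sPhaseFrac = sPhaseFrac,
             densityScale = densityScale, mitoIntensity = mitoIntensity,
             jc1Ratio = jc1Ratio, stringsAsFactors = FALSE)
}

## ---- cell placement -----------------------------------------------------

#' Draw the cells of one field
#'
#' Places cells by rejection sampling so that non-pair cells keep disjoint
#' cytoplasmic discs, then adds touching nuclear pairs at center distance
#' `touchingRange * nuclearRadius`. True intensities are drawn lognormally
#' around the condition's generative means; S-phase flags are Bernoulli.
#'
#' @param config a [plateSimConfig()].
#' @param cond one condition row from `config$conditions`.
#' @return list with `cells` (one row per cell: center, radii, true
#'   intensities, ratio, S-phase flag, EdU and JC-1 levels) and `mito`
#'   (one row per mitochondrial punctum). Centers are 0-based (row, col).
#' @export
sampleFieldCells <- function(config, cond) {
  fs <- config$fieldSize
  nucR <- config$nuclearRadius
  cytoR <- config$cytoRadius
  margin <- config$edgeMargin
  lambda <- config$cellsPerField * cond$densityScale
  n <- if (lambda <= 0) 0L else rpois(1, lambda)
  empty <- list(cells = data.frame(), mito = data.frame())
  if (n == 0L) return(empty)

  nPairCells <- 2L * floor(config$touchingFraction * n / 2)
  nPairs <- nPairCells / 2L
  nSingles <- n - nPairCells

  lo <- margin; hi <- fs - 1 - margin
  if (hi <= lo) stop("edge margin leaves no room for cells in this field")
  minSep <- 2 * cytoR
  placed <- matrix(numeric(0), ncol = 2)   # anchor centers
  sepNeeded <- numeric(0)                  # per-anchor exclusion radius
  centers <- matrix(numeric(0), ncol = 2)  # actual cell centers
  pairId <- integer(0)
  maxTries <- 200 * n + 2000
  tries <- 0
  pid <- 0L
  placeAnchor <- function(isPair) {
    # returns anchor or NULL
    cand <- c(runif(1, lo, hi), runif(1, lo, hi))
    need <- if (isPair) minSep + nucR else minSep
    if (nrow(placed) > 0) {
      d <- sqrt((placed[, 1] - cand[1])^2 + (placed[, 2] - cand[2])^2)
      if (any(d < pmax(sepNeeded, need))) return(NULL)
    }
    cand
  }
  nPlacedPairs <- 0L; nPlacedSingles <- 0L
  while (nPlacedPairs < nPairs || nPlacedSingles < nSingles) {
    tries <- tries + 1
    if (tries > maxTries)
      stop("cell density infeasible for field size: could not place ", n,
           " cells in a ", fs, "px field")
    wantPair <- nPlacedPairs < nPairs
    a <- placeAnchor(wantPair)
    if (is.null(a)) next
    if (wantPair) {
      d <- runif(1, config$touchingRange[1], config$touchingRange[2]) * nucR
      th <- runif(1, 0, 2 * pi)
      off <- c(cos(th), sin(th)) * d / 2
      c1 <- a + off; c2 <- a - off
      if (any(c(c1, c2) < lo) || any(c(c1, c2) > hi)) next
      placed <- rbind(placed, a)
      sepNeeded <- c(sepNeeded, minSep + nucR)
      centers <- rbind(centers, c1, c2)
      pid <- pid + 1L
      pairId <- c(pairId, pid, pid)
      nPlacedPairs <- nPlacedPairs + 1L
    } else {
      placed <- rbind(placed, a)
      sepNeeded <- c(sepNeeded, minSep)
      centers <- rbind(centers, a)
      pairId <- c(pairId, 0L)
      nPlacedSingles <- nPlacedSingles + 1L
    }
  }
  n <- nrow(centers)
  lnorm <- function(mean, cv) {
    if (cv <= 0) return(rep(mean, n))
    sdl <- sqrt(log(1 + cv^2))
    mean * exp(rnorm(n, -sdl^2 / 2, sdl))
  }
  nucInt <- lnorm(cond$nucMean, config$cellCv)
  ratio <- lnorm(cond$ratio, config$ratioCv)
  cytoInt <- nucInt / ratio
  sPhase <- rbinom(n, 1, cond$sPhaseFrac) == 1
  eduInt <- ifelse(sPhase, config$eduPos, config$eduNeg) *
    exp(rnorm(n, 0, 0.05))
  jc1Green <- rep(config$jc1Green, n) * exp(rnorm(n, 0, 0.05))
  jc1Red <- jc1Green * cond$jc1Ratio * exp(rnorm(n, 0, 0.05))
  dapiInt <- rep(config$dapiIntensity, n) * exp(rnorm(n, 0, 0.05))
  cells <- data.frame(
    cell = seq_len(n),
    center_r = centers[, 1], center_c = centers[, 2],
    nuclear_radius = nucR, cyto_radius = cytoR,
    dapi_intensity = dapiInt,
    nuc_intensity = nucInt, cyto_intensity = cytoInt,
    true_ratio = nucInt / cytoInt,
    s_phase = sPhase, edu_intensity = eduInt,
    jc1_red = jc1Red, jc1_green = jc1Green,
    pair_id = pairId)
  mito <- empty$mito
  if ("mito" %in% config$channels && config$mitoPerCell > 0) {
    rows <- lapply(seq_len(n), function(i) {
      k <- config$mitoPerCell
      rr <- sqrt(runif(k)) * (cytoR - config$mitoRadius - 1)
      th <- runif(k, 0, 2 * pi)
      data.frame(cell = i,
                 center_r = centers[i, 1] + rr * cos(th),
                 center_c = centers[i, 2] + rr * sin(th),
                 radius = config$mitoRadius,
                 intensity = cond$mitoIntensity * exp(rnorm(k, 0, 0.1)))
    })
    mito <- do.call(rbind, rows)
  }
  list(cells = cells, mito = mito)
}

## ---- rendering ----------------------------------------------------------

# set disc pixels (0-based center) in matrix m to value; returns m
.paintDisc <- function(m, cr, cc, radius, value) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- max(0, floor(cr - radius)); r1 <- min(nr - 1, ceiling(cr + radius))
  c0 <- max(0, floor(cc - radius)); c1 <- min(nc - 1, ceiling(cc + radius))
  if (r1 < r0 || c1 < c0) return(m)
  ri <- r0:r1; ci <- c0:c1
  dr2 <- (ri - cr)^2
  dc2 <- (ci - cc)^2
  inside <- outer(dr2, dc2, "+") <= radius^2
  sub <- m[ri + 1, ci + 1, drop = FALSE]
  sub[inside] <- value
  m[ri + 1, ci + 1] <- sub
  m
}

#' Render one field to intensity channels
#'
#' Paints nuclei (discs), cytoplasm (annuli), EdU, mitochondrial puncta and
#' JC-1 channels from the drawn cell specs, then applies background, a linear
#' gradient, read and shot noise, and clips to the 16-bit range. With zero
#' noise the rendered pixels equal the generative values exactly, which is
#' what makes the measurement layer testable to machine precision.
#'
#' @param fieldCells output of [sampleFieldCells()].
#' @param config a [plateSimConfig()].
#' @param plate,well,field identity stamped on the [FieldImage-class].
#' @return a [FieldImage-class]; `meta$clipped` counts clipped pixels.
#' @export
renderField <- function(fieldCells, config, plate = "plate1", well = "A01",
                        field = 1L) {
  fs <- config$fieldSize
  cells <- fieldCells$cells
  blank <- matrix(0, fs, fs)
  chans <- list()
  wants <- function(ch) ch %in% config$channels
  dapi <- blank; marker <- blank; edu <- blank
  mito <- blank; jred <- blank; jgreen <- blank
  n <- if (is.null(cells) || nrow(cells) == 0) 0L else nrow(cells)
  if (n > 0) {
    # cytoplasmic pass first, nuclei overwrite
    for (i in seq_len(n)) {
      cr <- cells$center_r[i]; cc <- cells$center_c[i]
      if (wants("marker"))
        marker <- .paintDisc(marker, cr, cc, cells$cyto_radius[i],
                             cells$cyto_intensity[i])
      if (wants("jc1red"))
        jred <- .paintDisc(jred, cr, cc, cells$cyto_radius[i],
                           cells$jc1_red[i])
      if (wants("jc1green"))
        jgreen <- .paintDisc(jgreen, cr, cc, cells$cyto_radius[i],
                             cells$jc1_green[i])
    }
    for (i in seq_len(n)) {
      cr <- cells$center_r[i]; cc <- cells$center_c[i]; rad <- cells$nuclear_radius[i]
      if (wants("dapi"))
        dapi <- .paintDisc(dapi, cr, cc, rad, cells$dapi_intensity[i])
      if (wants("marker"))
        marker <- .paintDisc(marker, cr, cc, rad, cells$nuc_intensity[i])
      if (wants("edu"))
        edu <- .paintDisc(edu, cr, cc, rad, cells$edu_intensity[i])
    }
    if (wants("mito") && nrow(fieldCells$mito) > 0) {
      mt <- fieldCells$mito
      for (k in seq_len(nrow(mt)))
        mito <- .paintDisc(mito, mt$center_r[k], mt$center_c[k],
                           mt$radius[k], mt$intensity[k])
    }
  }
  if (wants("dapi")) chans$dapi <- dapi
  if (wants("marker")) chans$marker <- marker
  if (wants("edu")) chans$edu <- edu
  if (wants("mito")) chans$mito <- mito
  if (wants("jc1red")) chans$jc1red <- jred
  if (wants("jc1green")) chans$jc1green <- jgreen

  grad <- if (config$backgroundGradient != 0 && fs > 1) {
    matrix(rep(config$backgroundGradient * (0:(fs - 1)) / (fs - 1),
               each = fs), fs, fs)
  } else 0
  clipped <- 0L
  for (nm in names(chans)) {
    v <- chans[[nm]] + config$background + grad
    if (config$readNoiseSd > 0)
      v <- v + rnorm(length(v), 0, config$readNoiseSd)
    if (config$shotScale > 0)
      v <- v + rnorm(length(v), 0, config$shotScale * sqrt(pmax(v, 0)))
    nclip <- sum(v < 0 | v > 65535)
    clipped <- clipped + nclip
    v <- pmin(pmax(v, 0), 65535)
    chans[[nm]] <- v
  }
  FieldImage(chans, plate = plate, well = well, field = field,
             meta = list(seed = config$seed, clipped = clipped))
}

## ---- plate assembly -----------------------------------------------------

.wellName <- function(i, ncol = 24) {
  r <- (i - 1) %/% ncol + 1
  c <- (i - 1) %% ncol + 1
  sprintf("%s%02d", LETTERS[r], c)
}

#' Simulate a full plate with layout and ground truth
#'
#' Assigns each condition to its replicate wells (quadruplicate by default,
#' vehicle controls always present), renders every field, and returns the
#' per-cell ground-truth table. Deterministic under the config seed: each
#' well/field derives its own RNG stream, so partial re-rendering reproduces
#' the same cells.
#'
#' @param config a [plateSimConfig()].
#' @return list with `fields` (list of [FieldImage-class]), `layout`
#'   (data.frame `well,compound,dose,unit,combo_agonist,replicate`), `truth`
#'   (one row per rendered cell) and the `config`.
#' @export
simulatePlate <- function(config) {
  stopifnot(inherits(config, "plateSimConfig"))
  conds <- config$conditions
  layout <- do.call(rbind, lapply(seq_len(nrow(conds)), function(ci) {
    data.frame(condIdx = ci, replicate = seq_len(conds$replicates[ci]))
  }))
  layout$well <- .wellName(seq_len(nrow(layout)))
  layout <- data.frame(well = layout$well,
                       compound = conds$compound[layout$condIdx],
                       dose = conds$dose[layout$condIdx],
                       unit = conds$unit[layout$condIdx],
                       combo_agonist = conds$comboAgonist[layout$condIdx],
                       replicate = layout$replicate,
                       condIdx = layout$condIdx,
                       stringsAsFactors = FALSE)
  fields <- list()
  truths <- list()
  for (w in seq_len(nrow(layout))) {
    cond <- conds[layout$condIdx[w], ]
    for (f in seq_len(config$fieldsPerWell)) {
      seed_wf <- (config$seed + 7919 * w + 104729 * f) %% 2147483647L
      set.seed(seed_wf)
      fc <- sampleFieldCells(config, cond)
      img <- renderField(fc, config, plate = "plate1",
                         well = layout$well[w], field = f)
      fields[[length(fields) + 1]] <- img
      if (nrow(fc$cells) > 0) {
        tr <- fc$cells
        tr$well <- layout$well[w]
        tr$field <- f
        tr$compound <- cond$compound
        tr$dose <- cond$dose
        tr$unit <- cond$unit
        tr$combo_agonist <- cond$comboAgonist
        truths[[length(truths) + 1]] <- tr
      }
    }
  }
  truth <- if (length(truths)) do.call(rbind, truths) else data.frame()
  rownames(truth) <- NULL
  layout$condIdx <- NULL
  list(fields = fields, layout = layout, truth = truth, config = config)
}

## ---- Biolog phenotype arrays --------------------------------------------

#' Simulate paired Biolog phenotype plates
#'
#' Emulates 96-well carbon-source utilization plates read by tetrazolium dye
#' reduction: ~90 source wells plus negative-control (empty) wells. Vehicle
#' source wells sit at `baseline + activity`; treated wells at
#' `baseline + multiplier * activity`, so after negative-control correction
#' the treated/vehicle ratio per source equals the multiplier (exactly at
#' zero noise).
#'
#' @param multipliers per-source treated-effect multipliers (length
#'   `nSources`, recycled if scalar).
#' @param nSources number of carbon-source wells (default 90).
#' @param negativeWells indices of the negative-control wells (default the
#'   remaining wells up to 96).
#' @param baseline negative-control (no-substrate) signal level.
#' @param activityMean,activityCv lognormal parameters of per-source
#'   utilization signal, drawn once and shared across replicates.
#' @param noiseSd additive Gaussian well noise.
#' @param nReplicates biological replicate plates per arm.
#' @param seed RNG seed.
#' @return list with `vehicle` and `treated` (each a list of plates; a plate
#'   is `list(values, negativeWells, condition)`), plus `activities` and
#'   `multipliers` (the generative truth).
#' @export
simulateBiolog <- function(multipliers = 1, nSources = 90,
                           negativeWells = (nSources + 1):96,
                           baseline = 80, activityMean = 150,
                           activityCv = 0.4, noiseSd = 5,
                           nReplicates = 3, seed = 1L) {
  stopifnot(nSources >= 1, length(negativeWells) >= 1,
            nSources + length(negativeWells) <= 96)
  multipliers <- rep_len(multipliers, nSources)
  set.seed(seed %% 2147483647L)
  sdl <- sqrt(log(1 + activityCv^2))
  activities <- activityMean * exp(rnorm(nSources, -sdl^2 / 2, sdl))
  nWells <- nSources + length(negativeWells)
  mkplate <- function(mult, condition) {
    values <- numeric(nWells)
    values[seq_len(nSources)] <- baseline + mult * activities
    values[negativeWells] <- baseline
    if (noiseSd > 0) values <- values + rnorm(nWells, 0, noiseSd)
    list(values = values, negativeWells = negativeWells,
         condition = condition)
  }
  vehicle <- lapply(seq_len(nReplicates), function(i)
    mkplate(rep(1, nSources), "vehicle"))
  treated <- lapply(seq_len(nReplicates), function(i)
    mkplate(multipliers, "treated"))
  list(vehicle = vehicle, treated = treated, activities = activities,
       multipliers = multipliers)
}
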