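## File formats: one 16-bit grayscale TIFF per channel per field, named
## r{row:02d}c{col:02d}f{field:02d}_{channel}.tif; plate layout, ground
## truth and all tabular outputs as CSV; run configuration as a flat
## key/value text file. Lowest-common-denominator formats any stack reads.

.wellToRC <- function(well) {
  r <- match(substr(well, 1, 1), LETTERS)
  c <- as.integer(substr(well, 2, nchar(well)))
  c(r, c)
}

.fieldFileName <- function(well, field, channel) {
  rc <- .wellToRC(well)
  sprintf("r%02dc%02df%02d_%s.tif", rc[1], rc[2], field, channel)
}

#' Write one field as per-channel 16-bit TIFFs
#'
#' @param field a [FieldImage-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeFieldTiff <- function(field, dir) {
  stopifnot(is(field, "FieldImage"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (ch in channelNames(field)) {
    m <- getChannel(field, ch)
    p <- file.path(dir, .fieldFileName(field@well, field@field, ch))
    tiff::writeTIFF(pmin(pmax(m, 0), 65535) / 65535, p,
                    bits.per.sample = 16, compression = "none")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a simulated plate to disk
#'
#' Writes per-field TIFFs, `layout.csv`, `truth.csv` and the resolved
#' configuration as `config.txt` (key/value text).
#'
#' @param plate the list returned by [simulatePlate()].
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
writePlate <- function(plate, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (f in plate$fields) writeFieldTiff(f, dir)
  write.csv(plate$layout, file.path(dir, "layout.csv"), row.names = FALSE)
  write.csv(plate$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  writeConfigText(plate$config, file.path(dir, "config.txt"))
  invisible(dir)
}

#' Write a configuration as flat key/value text
#'
#' Nested fields are dot-separated; the condition table is written as its
#' own CSV block. Every simulation/analysis run stores its resolved
#' configuration next to its outputs.
#'
#' @param config a list (e.g. [plateSimConfig()] or [segmentationParams()]).
#' @param file output path.
#' @export
writeConfigText <- function(config, file) {
  lines <- c(paste0("package.version: ", as.character(packageVersion("hcskit"))))
  for (nm in names(config)) {
    v <- config[[nm]]
    if (is.data.frame(v)) {
      lines <- c(lines, paste0(nm, ":"))
      tc <- textConnection("buf", "w", local = TRUE)
      write.csv(v, tc, row.names = FALSE)
      close(tc)
      lines <- c(lines, paste0("  ", buf))
    } else if (is.atomic(v)) {
      lines <- c(lines, paste0(nm, ": ", paste(format(v), collapse = ", ")))
    }
  }
  writeLines(lines, file)
}

#' Read plate layout CSV
#'
#' Expects columns `well, compound, dose, unit, combo_agonist, replicate`
#' (extra columns such as `cell_line` or `timepoint` pass through). Controls
#' must be identifiable: at least one `vehicle` row.
#'
#' @param path CSV path.
#' @return the layout data.frame.
#' @export
readPlateLayout <- function(path) {
  layout <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "compound", "dose", "unit", "combo_agonist", "replicate")
  miss <- setdiff(need, names(layout))
  if (length(miss)) stop("layout lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(layout$well)) stop("duplicate well IDs in layout")
  if (any(layout$dose < 0)) stop("negative doses in layout")
  if (!any(layout$compound == "vehicle"))
    stop("layout has no vehicle control wells")
  layout
}

#' Read fields from a directory of per-channel TIFFs
#'
#' Files must follow `r{row:02d}c{col:02d}f{field:02d}_{channel}.tif`, or be
#' listed in a manifest CSV (`file,well,field,channel`). Channels are
#' grouped per (well, field); a field whose channels disagree in dimension,
#' or that lacks a channel present in the other fields, is skipped with a
#' message.
#'
#' @param root directory containing the TIFFs.
#' @param manifest optional manifest CSV path overriding filename parsing.
#' @return list of [FieldImage-class] objects.
#' @export
readFields <- function(root, manifest = NULL) {
  if (!is.null(manifest)) {
    mf <- read.csv(manifest, stringsAsFactors = FALSE)
    need <- c("file", "well", "field", "channel")
    miss <- setdiff(need, names(mf))
    if (length(miss)) stop("manifest lacks columns: ",
                           paste(miss, collapse = ", "))
    mf$path <- ifelse(file.exists(mf$file), mf$file,
                      file.path(root, mf$file))
  } else {
    files <- list.files(root, pattern = "^r\\d+c\\d+f\\d+_.+\\.tif$")
    if (!length(files)) return(list())
    m <- regmatches(files,
                    regexec("^r(\\d+)c(\\d+)f(\\d+)_(.+)\\.tif$", files))
    mf <- data.frame(
      path = file.path(root, files),
      well = vapply(m, function(x)
        sprintf("%s%02d", LETTERS[as.integer(x[2])], as.integer(x[3])),
        character(1)),
      field = vapply(m, function(x) as.integer(x[4]), integer(1)),
      channel = vapply(m, function(x) x[5], character(1)),
      stringsAsFactors = FALSE)
  }
  keys <- unique(mf[c("well", "field")])
  keys <- keys[order(keys$well, keys$field), , drop = FALSE]
  allChans <- sort(unique(mf$channel))
  fields <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- mf[mf$well == keys$well[i] & mf$field == keys$field[i], ,
              drop = FALSE]
    if (!setequal(sel$channel, allChans)) {
      message("skipping field ", keys$well[i], "/f", keys$field[i],
              ": missing channel(s) ",
              paste(setdiff(allChans, sel$channel), collapse = ", "))
      next
    }
    chans <- list()
    ok <- TRUE
    for (j in seq_len(nrow(sel))) {
      img <- tryCatch(tiff::readTIFF(sel$path[j]), error = function(e) NULL)
      if (is.null(img) || length(dim(img)) != 2) {
        message("skipping field ", keys$well[i], "/f", keys$field[i],
                ": unreadable ", sel$path[j])
        ok <- FALSE
        break
      }
      chans[[sel$channel[j]]] <- img * 65535
    }
    if (!ok) next
    dims <- vapply(chans, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      message("skipping field ", keys$well[i], "/f", keys$field[i],
              ": channel dimension mismatch")
      next
    }
    fields[[length(fields) + 1]] <-
      FieldImage(chans, well = keys$well[i], field = keys$field[i])
  }
  fields
}
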