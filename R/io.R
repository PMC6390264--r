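## Reading and writing label rasters with their metadata sidecar, report
## tables and false-colour overlays. Label images are single-channel 8-bit
## indexed rasters (PNG or TIFF); all interpretation lives in the sidecar
## (YAML or JSON), never in image colours.

.imgFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext))
}

.metaFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) return("yaml")
  if (ext == "json") return("json")
  stop(sprintf("unsupported metadata format '.%s' (use YAML or JSON)", ext))
}

.requireMeta <- function(meta, field) {
  if (is.null(meta[[field]]))
    stop(sprintf("configuration error: metadata field '%s' is missing", field))
  meta[[field]]
}

.paletteFromMeta <- function(pl) {
  data.frame(tissue = vapply(pl, `[[`, "", "tissue"),
             value = vapply(pl, function(x) as.integer(x$value), 1L),
             colour = vapply(pl, `[[`, "", "colour"),
             stringsAsFactors = FALSE)
}

.paletteToMeta <- function(pal) {
  lapply(seq_len(nrow(pal)), function(i)
    list(tissue = pal$tissue[i], value = as.integer(pal$value[i]),
         colour = pal$colour[i]))
}

#' Read a labelled section from an image and its metadata sidecar
#'
#' Reads a single-channel indexed raster (PNG or TIFF, 8-bit) plus a YAML or
#' JSON sidecar supplying `resolution` (px/mm), `axis`, `gap_centre`
#' (`[row, col]`), `anterior_side`, `animal_id`, `group` and the label
#' `palette`. A missing metadata field raises a configuration error naming
#' the field; label values outside the palette raise a validation error
#' listing the offending values — never a silent coercion.
#'
#' @param imagePath path to the label image.
#' @param metaPath path to the metadata sidecar.
#' @return A validated [LabeledSection-class].
#' @seealso [writeSection()]
#' @export
readSection <- function(imagePath, metaPath) {
  img <- switch(.imgFormat(imagePath),
                png = png::readPNG(imagePath),
                tiff = tiff::readTIFF(imagePath))
  if (length(dim(img)) != 2L)
    stop("label image must be single-channel (indexed), got ",
         paste(dim(img), collapse = "x"))
  labs <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  meta <- switch(.metaFormat(metaPath),
                 yaml = yaml::read_yaml(metaPath),
                 json = jsonlite::read_json(metaPath, simplifyVector = FALSE))
  pal <- .paletteFromMeta(.requireMeta(meta, "palette"))
  pv <- .checkPalette(pal)
  if (!is.null(pv)) stop("configuration error: ", pv)
  bad <- setdiff(unique(as.vector(labs)), pal$value)
  if (length(bad))
    stop(sprintf("validation error: label values outside the palette: %s",
                 paste(sort(bad), collapse = ", ")))
  LabeledSection(
    labs,
    resolution = as.numeric(.requireMeta(meta, "resolution")),
    axis = as.character(.requireMeta(meta, "axis")),
    gapCentre = as.numeric(unlist(.requireMeta(meta, "gap_centre"))),
    anteriorSide = as.character(.requireMeta(meta, "anterior_side")),
    animalId = as.character(.requireMeta(meta, "animal_id")),
    group = as.character(.requireMeta(meta, "group")),
    palette = pal)
}

#' Write a labelled section and its metadata sidecar
#'
#' Lossless counterpart of [readSection()]: the label matrix is written as
#' an 8-bit single-channel raster and every metadata field (including the
#' palette) goes to the sidecar, so that write-then-read is the identity.
#'
#' @param section a [LabeledSection-class].
#' @param imagePath output image path (`.png`, `.tif`/`.tiff`).
#' @param metaPath output sidecar path (`.yaml`/`.yml`/`.json`).
#' @return Invisibly, the two paths.
#' @export
writeSection <- function(section, imagePath, metaPath) {
  stopifnot(is(section, "LabeledSection"))
  labs <- section@labels
  if (length(labs) == 0L) stop("refusing to write an empty (0-pixel) grid")
  if (any(labs < 0 | labs > 255))
    stop("label values must fit an 8-bit raster")
  img <- labs / 255
  switch(.imgFormat(imagePath),
         png = png::writePNG(img, imagePath),
         tiff = tiff::writeTIFF(img, imagePath, bits.per.sample = 8L))
  meta <- list(
    resolution = section@resolution,
    axis = section@axis,
    gap_centre = as.numeric(section@gapCentre),
    anterior_side = section@anteriorSide,
    animal_id = section@animalId,
    group = section@group,
    palette = .paletteToMeta(section@palette))
  switch(.metaFormat(metaPath),
         yaml = yaml::write_yaml(meta, metaPath),
         json = jsonlite::write_json(meta, metaPath, auto_unbox = TRUE,
                                     digits = NA))
  invisible(c(imagePath, metaPath))
}

.hexToRGB <- function(cols) grDevices::col2rgb(cols) / 255

#' Render a section to an RGB array
#'
#' Tissue palette rendering; if a [DensityResult-class] is supplied, ROI
#' pixels are false-coloured by density class (low red, medium turquoise,
#' high light blue) on top of the tissue rendering.
#'
#' @param section a [LabeledSection-class].
#' @param density optional [DensityResult-class] on the same grid.
#' @return A `nrow x ncol x 3` numeric array in `[0, 1]`.
#' @export
renderSection <- function(section, density = NULL) {
  labs <- section@labels
  pal <- section@palette
  idx <- match(as.vector(labs), pal$value)
  rgb <- .hexToRGB(pal$colour)
  out <- array(0, c(nrow(labs), ncol(labs), 3))
  for (k in 1:3) out[, , k] <- matrix(rgb[k, idx], nrow(labs), ncol(labs))
  if (!is.null(density)) {
    stopifnot(is(density, "DensityResult"))
    cm <- classMap(density)
    if (!identical(dim(cm), dim(labs)))
      stop("validation error: section and density map shapes disagree")
    dcol <- .hexToRGB(densityClassColours())
    sel <- !is.na(cm)
    for (k in 1:3) {
      plane <- out[, , k]
      plane[sel] <- dcol[k, cm[sel]]
      out[, , k] <- plane
    }
  }
  out
}

#' Write a false-colour density overlay
#'
#' Writes an RGB PNG in which callus-ROI pixels are coloured by their
#' low/medium/high density class and all other pixels show the tissue
#' palette. Pixel counts per class colour equal the class pixel counts of
#' the [DensityResult-class] exactly.
#'
#' @inheritParams renderSection
#' @param path output PNG path.
#' @return Invisibly, `path`.
#' @export
writeOverlay <- function(section, density, path) {
  png::writePNG(renderSection(section, density), path)
  invisible(path)
}

#' Write the morphometry report CSV
#'
#' One data row per (animal, region) followed by one summary block per
#' (group, region): rows for mean, SD, median, min and max of each measurand
#' column, the shape of the study's report tables. Groups of a single animal
#' report SD 0 and carry a note. Column names are the field's symbols
#' (`Cl.Ar`, `nB.Ar`, `Cg.Ar`, `nBV/TV`, `CgV/TV`).
#'
#' @param records per-animal records from [measureSection()] (rows bound
#'   over animals); at least one row.
#' @param path output CSV path.
#' @return Invisibly, the full report `data.frame` that was written.
#' @export
writeReport <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("validation error: at least one record is required")
  meas <- intersect(.MEASURANDS, names(records))
  dataRows <- data.frame(row_type = "animal", stat = "value",
                         animal_id = records$animal_id,
                         group = records$group, region = records$region,
                         check.names = FALSE, stringsAsFactors = FALSE)
  for (mcol in meas) dataRows[[mcol]] <- records[[mcol]]
  dataRows$notes <- if ("flagged" %in% names(records))
    ifelse(records$flagged, "empty region", "") else ""

  summ <- summarizeGroups(records, measurands = meas)
  sumRows <- list()
  grid <- unique(summ[, c("group", "region")])
  for (i in seq_len(nrow(grid))) {
    sg <- summ[summ$group == grid$group[i] & summ$region == grid$region[i], ]
    for (stat in c("mean", "SD", "median", "min", "max")) {
      row <- data.frame(row_type = "summary", stat = stat,
                        animal_id = "", group = grid$group[i],
                        region = grid$region[i],
                        check.names = FALSE, stringsAsFactors = FALSE)
      for (mcol in meas)
        row[[mcol]] <- if (mcol %in% sg$measurand)
          sg[[stat]][sg$measurand == mcol] else NA_real_
      row$notes <- paste(unique(sg$notes[nzchar(sg$notes)]), collapse = "; ")
      sumRows[[length(sumRows) + 1L]] <- row
    }
  }
  out <- rbind(dataRows, do.call(rbind, sumRows))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Write the density-class report CSV
#'
#' Per-animal density-class areas and percentages (long format) followed by
#' group summary rows (mean, SD, median, min, max of the class percentage
#' per group, region and class).
#'
#' @param classRows `data.frame` with columns `animal_id`, `group`,
#'   `region`, `class`, `px`, `area`, `percent` (rows bound over animals).
#' @param path output CSV path.
#' @return Invisibly, the full report `data.frame` that was written.
#' @export
writeDensityReport <- function(classRows, path) {
  if (!is.data.frame(classRows) || nrow(classRows) == 0L)
    stop("validation error: at least one density record is required")
  dataRows <- cbind(data.frame(row_type = "animal", stat = "value",
                               stringsAsFactors = FALSE),
                    classRows)
  grid <- unique(classRows[, c("group", "region", "class")])
  sumRows <- list()
  for (i in seq_len(nrow(grid))) {
    sel <- classRows$group == grid$group[i] &
      classRows$region == grid$region[i] & classRows$class == grid$class[i]
    v <- classRows$percent[sel]
    v <- v[!is.na(v)]
    if (!length(v)) next
    stats5 <- c(mean = mean(v), SD = if (length(v) == 1L) 0 else stats::sd(v),
                median = stats::median(v), min = min(v), max = max(v))
    for (stat in names(stats5)) {
      row <- data.frame(row_type = "summary", stat = stat, animal_id = "",
                        group = grid$group[i], region = grid$region[i],
                        class = grid$class[i], px = NA_real_, area = NA_real_,
                        percent = stats5[[stat]], stringsAsFactors = FALSE)
      sumRows[[length(sumRows) + 1L]] <- row
    }
  }
  out <- rbind(dataRows, do.call(rbind, sumRows))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
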