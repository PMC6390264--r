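## Area and fraction measurands per region. All logic is in integer pixel
## counts; division by resolution^2 happens once, at reporting, so that
## anterior + posterior = total holds exactly.

.MEASURANDS <- c("Cl.Ar", "nB.Ar", "Cg.Ar", "nBV/TV", "CgV/TV")

.regionRecord <- function(section, mask, region) {
  labs <- section@labels
  tl <- tissueLabels()
  clPx <- sum(mask)
  nbPx <- sum(mask & labs == tl[["NEW_BONE"]])
  cgPx <- sum(mask & labs == tl[["CARTILAGE"]])
  a <- section@resolution^2
  rec <- data.frame(
    animal_id = section@animalId, group = section@group, region = region,
    Cl.px = clPx, nB.px = nbPx, Cg.px = cgPx,
    check.names = FALSE, stringsAsFactors = FALSE)
  rec[["Cl.Ar"]] <- clPx / a
  rec[["nB.Ar"]] <- nbPx / a
  rec[["Cg.Ar"]] <- cgPx / a
  rec[["nBV/TV"]] <- if (clPx > 0) 100 * nbPx / clPx else NA_real_
  rec[["CgV/TV"]] <- if (clPx > 0) 100 * cgPx / clPx else NA_real_
  rec$flagged <- clPx == 0
  rec
}

#' Measure callus, new-bone and cartilage areas per region
#'
#' Computes the classical measurands within the callus ROI and its anterior
#' and posterior halves: total callus area Cl.Ar (every ROI pixel), new-bone
#' area nB.Ar (NEW_BONE pixels in the ROI), cartilage area Cg.Ar (CARTILAGE
#' pixels), all in mm² (`pixels / resolution²`), plus the area fractions
#' nBV/TV and CgV/TV in percent of Cl.Ar. An empty region yields zero areas
#' and `NA` fractions with `flagged = TRUE`.
#'
#' @param section a [LabeledSection-class].
#' @param roi a [CallusROI-class]; partitioned automatically if it is not.
#' @return A `data.frame` with one row per region (`anterior`, `posterior`,
#'   `total`) and columns `animal_id`, `group`, `region`, integer pixel
#'   counts `Cl.px`, `nB.px`, `Cg.px`, areas `Cl.Ar`, `nB.Ar`, `Cg.Ar` (mm²),
#'   fractions `nBV/TV`, `CgV/TV` (%), and `flagged`.
#' @examples
#' g <- generateSection(sectionConfig(seed = 1))
#' roi <- splitAnteriorPosterior(buildROI(g$section), g$section)
#' measureSection(g$section, roi)
#' @export
measureSection <- function(section, roi) {
  stopifnot(is(section, "LabeledSection"), is(roi, "CallusROI"))
  if (!identical(dim(roi@roiMask), dim(section@labels)))
    stop("ROI and section dimensions disagree")
  if (!roi@partitioned)
    roi <- splitAnteriorPosterior(roi, section)
  rbind(.regionRecord(section, roi@anteriorMask, "anterior"),
        .regionRecord(section, roi@posteriorMask, "posterior"),
        .regionRecord(section, roi@roiMask, "total"))
}

#' Combine anterior and posterior records into totals
#'
#' Sums the anterior and posterior rows of each animal into a `total` row:
#' areas (and pixel counts, when present) add; the fractions are recomputed
#' from the summed areas. This is the aggregation contract that the reported
#' group means inherit — the printed total new-bone or cartilage area of a
#' group is the sum of its anterior and posterior means.
#'
#' @param records a `data.frame` of per-region records with at least
#'   `animal_id`, `group`, `region`, `Cl.Ar`, `nB.Ar`, `Cg.Ar`, and regions
#'   `anterior` and `posterior` for every animal.
#' @return A `data.frame` of `total` rows, one per animal.
#' @examples
#' g <- generateSection(sectionConfig(seed = 1))
#' roi <- splitAnteriorPosterior(buildROI(g$section), g$section)
#' m <- measureSection(g$section, roi)
#' combineRegions(m[m$region != "total", ])
#' @export
combineRegions <- function(records) {
  stopifnot(is.data.frame(records), all(c("animal_id", "region") %in% names(records)))
  recs <- records[records$region %in% c("anterior", "posterior"), , drop = FALSE]
  out <- lapply(split(recs, recs$animal_id), function(df) {
    if (!setequal(df$region, c("anterior", "posterior")))
      stop("every animal needs exactly an anterior and a posterior record")
    tot <- df[1, , drop = FALSE]
    tot$region <- "total"
    for (col in intersect(c("Cl.px", "nB.px", "Cg.px",
                            "Cl.Ar", "nB.Ar", "Cg.Ar"), names(df)))
      tot[[col]] <- sum(df[[col]])
    if (all(c("Cl.Ar", "nB.Ar", "nBV/TV") %in% names(df)))
      tot[["nBV/TV"]] <- if (tot[["Cl.Ar"]] > 0)
        100 * tot[["nB.Ar"]] / tot[["Cl.Ar"]] else NA_real_
    if (all(c("Cl.Ar", "Cg.Ar", "CgV/TV") %in% names(df)))
      tot[["CgV/TV"]] <- if (tot[["Cl.Ar"]] > 0)
        100 * tot[["Cg.Ar"]] / tot[["Cl.Ar"]] else NA_real_
    if ("flagged" %in% names(df)) tot$flagged <- all(df$flagged)
    tot
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise measurands per treatment group and region
#'
#' One summary row per (group, region, measurand) with mean, SD, median,
#' minimum and maximum, the shape of the study's report tables. The SD uses
#' the sample (n - 1) convention; a group of a single animal reports SD 0
#' and is flagged in the `notes` column.
#'
#' @param records per-animal records as returned by [measureSection()] (rows
#'   from several animals bound together).
#' @param measurands which measurand columns to summarise.
#' @return A `data.frame` with columns `group`, `region`, `measurand`, `n`,
#'   `mean`, `SD`, `median`, `min`, `max`, `notes`.
#' @examples
#' recs <- data.frame(animal_id = c("a", "b"), group = "g", region = "total",
#'                    check.names = FALSE)
#' recs[["nB.Ar"]] <- c(40, 60)
#' summarizeGroups(recs, measurands = "nB.Ar")
#' @export
summarizeGroups <- function(records, measurands = intersect(.MEASURANDS,
                                                            names(records))) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  if (!all(c("group", "region") %in% names(records)))
    stop("records need 'group' and 'region' columns")
  if (!length(measurands)) stop("no measurand columns found")
  grid <- unique(records[, c("group", "region")])
  out <- list()
  for (i in seq_len(nrow(grid))) {
    sel <- records$group == grid$group[i] & records$region == grid$region[i]
    for (m in measurands) {
      v <- records[[m]][sel]
      v <- v[!is.na(v)]
      if (!length(v)) next
      n1 <- length(v) == 1L
      out[[length(out) + 1L]] <- data.frame(
        group = grid$group[i], region = grid$region[i], measurand = m,
        n = length(v), mean = mean(v), SD = if (n1) 0 else stats::sd(v),
        median = stats::median(v), min = min(v), max = max(v),
        notes = if (n1) "n=1: SD reported as 0" else "",
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
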