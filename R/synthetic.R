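## Synthetic labelled sections and whole studies with known ground truth.
## The section generator emulates a longitudinal mid-diaphyseal osteotomy
## section: two cortices flanking a marrow canal, a transverse gap (3 mm by
## default), periosteal callus bulges on both sides, endosteal and
## intercortical callus near the gap. Callus texture is Bernoulli per pixel
## at a compartment-specific target bone fill fraction, so the expected
## local density of every compartment is known analytically.

.COMPARTMENTS <- c(none = 0L, periosteal_anterior = 1L,
                   periosteal_posterior = 2L, endosteal = 3L,
                   intercortical = 4L)

#' Configuration for a synthetic labelled section
#'
#' Geometry and composition of one synthetic section. All lengths are in mm;
#' the proximal–distal axis runs along rows. The `profile` presets encode the
#' two section archetypes the emulated study contrasts: `"treatment"`
#' (axially stimulated: larger callus, compact bone adjacent to the
#' periosteal and endosteal surfaces, medium-density intercortical bridge)
#' and `"control"` (rigidly fixed: smaller callus, composition shifted
#' towards medium density). Explicit arguments override the preset.
#'
#' @param seed integer random seed; mandatory — the same seed reproduces the
#'   section bit-identically.
#' @param resolution pixels per mm (default 15; coarser than the reference
#'   imaging setup's 229 px/mm so that routine runs stay light).
#' @param lengthMm,widthMm section extent along / across the bone axis.
#' @param cortexThicknessMm,marrowWidthMm cortical wall thickness and marrow
#'   canal width.
#' @param gapSizeMm osteotomy gap (default 3 mm).
#' @param periostealExtentAnteriorMm,periostealExtentPosteriorMm lateral
#'   extent of the periosteal callus on the anterior/posterior side (the
#'   anterior callus is larger, as in vivo).
#' @param periostealHalfLengthMm,endostealHalfLengthMm half-length of the
#'   periosteal / endosteal callus along the bone axis, from the gap centre.
#' @param fillPeriosteal,fillEndosteal,fillIntercortical target local bone
#'   fill fraction per compartment, in `[0, 1]`.
#' @param cartilageProb probability that a non-bone callus pixel in the
#'   periosteal gap zone becomes cartilage (cartilage occurs mainly in the
#'   periosteal gap; the control archetype has nearly none).
#' @param marginMm background margin around the specimen.
#' @param profile `"treatment"` or `"control"` preset (see above).
#' @param animalId,group metadata carried into the section.
#' @return A list of class `sectionConfig`.
#' @seealso [generateSection()]
#' @export
sectionConfig <- function(seed, resolution = 15, lengthMm = 40, widthMm = 24,
                          cortexThicknessMm = 3, marrowWidthMm = 8,
                          gapSizeMm = 3,
                          periostealExtentAnteriorMm = NULL,
                          periostealExtentPosteriorMm = NULL,
                          periostealHalfLengthMm = NULL,
                          endostealHalfLengthMm = 5,
                          fillPeriosteal = NULL, fillEndosteal = NULL,
                          fillIntercortical = NULL, cartilageProb = NULL,
                          marginMm = 1, profile = c("treatment", "control"),
                          animalId = "synthetic", group = profile[1]) {
  profile <- match.arg(profile)
  ## Preset fills/extents encode the archetypes' class compositions: the
  ## compact periosteal collar is high-density (> 0.66), the endosteal fill
  ## medium (0.33-0.66) and the young intercortical bridge low (< 0.33), so
  ## with these compartment area shares a treatment-like section carries
  ## roughly 60% high / 30% medium / 10% low density and a control-like
  ## section a smaller callus shifted towards medium.
  preset <- if (profile == "treatment")
    list(pa = 5, pp = 3, phl = 10, fp = 0.80, fe = 0.50, fi = 0.25,
         cp = 0.75)
  else
    list(pa = 4, pp = 2.5, phl = 8, fp = 0.70, fe = 0.45, fi = 0.20,
         cp = 0.05)
  cfg <- list(
    seed = seed, resolution = resolution, lengthMm = lengthMm,
    widthMm = widthMm, cortexThicknessMm = cortexThicknessMm,
    marrowWidthMm = marrowWidthMm, gapSizeMm = gapSizeMm,
    periostealExtentAnteriorMm = periostealExtentAnteriorMm %||% preset$pa,
    periostealExtentPosteriorMm = periostealExtentPosteriorMm %||% preset$pp,
    periostealHalfLengthMm = periostealHalfLengthMm %||% preset$phl,
    endostealHalfLengthMm = endostealHalfLengthMm,
    fillPeriosteal = fillPeriosteal %||% preset$fp,
    fillEndosteal = fillEndosteal %||% preset$fe,
    fillIntercortical = fillIntercortical %||% preset$fi,
    cartilageProb = cartilageProb %||% preset$cp, marginMm = marginMm,
    profile = profile, animalId = animalId, group = group)
  .validateSectionConfig(cfg)
  class(cfg) <- "sectionConfig"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.validateSectionConfig <- function(cfg) {
  if (is.null(cfg$seed) || !is.finite(cfg$seed))
    stop("a finite random seed is mandatory in a sectionConfig")
  lens <- c("resolution", "lengthMm", "widthMm", "cortexThicknessMm",
            "marrowWidthMm", "gapSizeMm", "periostealExtentAnteriorMm",
            "periostealExtentPosteriorMm", "periostealHalfLengthMm",
            "endostealHalfLengthMm")
  for (f in lens)
    if (cfg[[f]] <= 0) stop(sprintf("%s must be positive", f))
  fills <- c("fillPeriosteal", "fillEndosteal", "fillIntercortical",
             "cartilageProb")
  for (f in fills)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("%s must lie in [0, 1]", f))
  boneWidth <- 2 * cfg$marginMm + cfg$periostealExtentAnteriorMm +
    cfg$periostealExtentPosteriorMm + 2 * cfg$cortexThicknessMm +
    cfg$marrowWidthMm
  if (boneWidth > cfg$widthMm)
    stop(sprintf(
      "geometrically impossible: margins + callus + cortices + marrow (%.3g mm) exceed widthMm (%.3g mm)",
      boneWidth, cfg$widthMm))
  if (cfg$gapSizeMm >= cfg$lengthMm)
    stop("gapSizeMm must be smaller than lengthMm")
  if (2 * cfg$periostealHalfLengthMm > cfg$lengthMm ||
      2 * cfg$endostealHalfLengthMm > cfg$lengthMm)
    stop("callus half-lengths must fit inside the section")
  invisible(cfg)
}

#' Generate a synthetic labelled section with ground truth
#'
#' Renders the geometry of [sectionConfig()] into a tissue-label raster and
#' draws the callus texture: each compartment pixel becomes NEW_BONE with its
#' compartment's target fill fraction (independent Bernoulli draws), FIBROUS
#' otherwise; non-bone pixels in the periosteal gap zone may become
#' CARTILAGE. Deterministic under the config seed.
#'
#' @param config a [sectionConfig()].
#' @return A list with elements
#'   \describe{
#'     \item{`section`}{the [LabeledSection-class];}
#'     \item{`truth`}{ground truth: `fill` (per-pixel target bone fill
#'       fraction, `NA` outside the callus), `compartment` (integer matrix,
#'       see `truth$compartmentCodes`), `callusMask` (logical: the geometric
#'       callus envelope), and `roi` (a partitioned [CallusROI-class] over
#'       the envelope, usable to score downstream stages independently of
#'       ROI reconstruction).}
#'   }
#' @examples
#' g <- generateSection(sectionConfig(seed = 42))
#' g$section
#' @export
generateSection <- function(config) {
  stopifnot(inherits(config, "sectionConfig"))
  .validateSectionConfig(config)
  set.seed(config$seed)
  res <- config$resolution
  nr <- round(config$lengthMm * res)
  nc <- round(config$widthMm * res)
  tl <- tissueLabels()

  ## column bands (mm -> px), anterior on the left
  px <- function(mm) round(mm * res)
  m  <- px(config$marginMm)
  pa <- px(config$periostealExtentAnteriorMm)
  ct <- px(config$cortexThicknessMm)
  mw <- px(config$marrowWidthMm)
  pp <- px(config$periostealExtentPosteriorMm)
  colPerioA <- (m + 1):(m + pa)
  colCortA  <- (m + pa + 1):(m + pa + ct)
  colMarrow <- (m + pa + ct + 1):(m + pa + ct + mw)
  colCortP  <- (m + pa + ct + mw + 1):(m + pa + ct + mw + ct)
  colPerioP <- (m + pa + ct + mw + ct + 1):(m + pa + ct + mw + ct + pp)

  ctrRow <- (nr + 1) / 2
  rowIdx <- row(matrix(0L, nr, nc))
  gapRows <- abs(rowIdx - ctrRow) <= px(config$gapSizeMm) / 2
  perioRows <- abs(rowIdx - ctrRow) <= px(config$periostealHalfLengthMm)
  endoRows <- abs(rowIdx - ctrRow) <= px(config$endostealHalfLengthMm)
  inCols <- function(cols) {
    z <- matrix(FALSE, nr, nc); z[, cols] <- TRUE; z
  }

  labs <- matrix(tl[["BACKGROUND"]], nr, nc)
  labs[inCols(colMarrow)] <- tl[["MARROW"]]
  cortex <- (inCols(colCortA) | inCols(colCortP)) & !gapRows
  labs[cortex] <- tl[["CORTICAL_BONE"]]

  comp <- matrix(.COMPARTMENTS[["none"]], nr, nc)
  comp[inCols(colPerioA) & perioRows] <- .COMPARTMENTS[["periosteal_anterior"]]
  comp[inCols(colPerioP) & perioRows] <- .COMPARTMENTS[["periosteal_posterior"]]
  comp[inCols(colMarrow) & endoRows]  <- .COMPARTMENTS[["endosteal"]]
  comp[(inCols(colCortA) | inCols(colCortP)) & gapRows] <-
    .COMPARTMENTS[["intercortical"]]

  fillOf <- c(NA, config$fillPeriosteal, config$fillPeriosteal,
              config$fillEndosteal, config$fillIntercortical)
  fill <- matrix(fillOf[comp + 1L], nr, nc)

  callus <- comp != .COMPARTMENTS[["none"]]
  u <- matrix(stats::runif(nr * nc), nr, nc)
  bone <- callus & u < fill
  labs[callus] <- tl[["FIBROUS"]]
  labs[bone] <- tl[["NEW_BONE"]]

  ## cartilage occurs mainly in the periosteal gap zone: periosteal columns
  ## within one gap length of the gap centre
  cartRows <- abs(rowIdx - ctrRow) <= px(config$gapSizeMm)
  perioGap <- (inCols(colPerioA) | inCols(colPerioP)) & perioRows & cartRows
  cartCand <- perioGap & !bone
  v <- matrix(stats::runif(nr * nc), nr, nc)
  labs[cartCand & v < config$cartilageProb] <- tl[["CARTILAGE"]]

  gapCol <- (min(colMarrow) + max(colMarrow)) / 2
  section <- LabeledSection(labs, resolution = res,
                            gapCentre = c(ctrRow, gapCol),
                            axis = "row", anteriorSide = "left",
                            animalId = config$animalId, group = config$group)
  blank <- matrix(FALSE, nr, nc)
  roi <- new("CallusROI", roiMask = callus, anteriorMask = blank,
             posteriorMask = blank, splitLine = gapCol,
             windowHalfwidthMm = config$lengthMm / 2, partitioned = FALSE,
             empty = !any(callus))
  roi <- splitAnteriorPosterior(roi, section)
  list(section = section,
       truth = list(fill = fill, compartment = comp,
                    compartmentCodes = .COMPARTMENTS,
                    callusMask = callus, roi = roi))
}

#' Generate a banded test section with stepped fill fractions
#'
#' A rectangular callus made of horizontal bands stacked along the
#' proximal–distal axis, the i-th band filled with new bone at `fills[i]`
#' (Bernoulli per pixel, FIBROUS otherwise), surrounded by background. The
#' returned ROI covers exactly the banded rectangle, so the local density of
#' a band-interior pixel concentrates tightly around the band's fill
#' fraction — a controlled fixture for classification recovery.
#'
#' @param seed integer random seed.
#' @param fills per-band target fill fractions.
#' @param bandHeightMm,widthMm band geometry in mm.
#' @param resolution pixels per mm.
#' @param marginMm background margin.
#' @return A list with `section`, `roi` (partitioned [CallusROI-class]) and
#'   `truth` (`band` index matrix, 0 outside; `fills`).
#' @export
generateBandedSection <- function(seed, fills = c(0.2, 0.5, 0.8),
                                  bandHeightMm = 8, widthMm = 12,
                                  resolution = 20, marginMm = 1) {
  stopifnot(is.finite(seed), length(fills) >= 1, all(fills >= 0 & fills <= 1))
  set.seed(seed)
  tl <- tissueLabels()
  mg <- round(marginMm * resolution)
  bh <- round(bandHeightMm * resolution)
  bw <- round(widthMm * resolution)
  nr <- 2 * mg + bh * length(fills)
  nc <- 2 * mg + bw
  labs <- matrix(tl[["BACKGROUND"]], nr, nc)
  band <- matrix(0L, nr, nc)
  for (i in seq_along(fills)) {
    rows <- (mg + (i - 1L) * bh + 1L):(mg + i * bh)
    cols <- (mg + 1L):(mg + bw)
    band[rows, cols] <- i
    u <- matrix(stats::runif(length(rows) * length(cols)),
                length(rows), length(cols))
    sub <- ifelse(u < fills[i], tl[["NEW_BONE"]], tl[["FIBROUS"]])
    labs[rows, cols] <- sub
  }
  mask <- band > 0L
  section <- LabeledSection(labs, resolution = resolution,
                            gapCentre = c((nr + 1) / 2, (nc + 1) / 2),
                            animalId = "banded", group = "fixture")
  blank <- matrix(FALSE, nr, nc)
  roi <- new("CallusROI", roiMask = mask, anteriorMask = blank,
             posteriorMask = blank, splitLine = (nc + 1) / 2,
             windowHalfwidthMm = nr / resolution / 2, partitioned = FALSE,
             empty = !any(mask))
  roi <- splitAnteriorPosterior(roi, section)
  list(section = section, roi = roi,
       truth = list(band = band, fills = fills))
}

#' Configuration for a synthetic study
#'
#' The statistical structure a per-animal regional measurement inherits in
#' the emulated design: five groups with the evaluated sample sizes
#' 6/6/7/8/4, a group mean per measurand, a fixed anterior–posterior
#' location effect, a Gaussian random intercept per animal, and Gaussian
#' residual noise. Default group means and effect magnitudes follow the
#' scale of posterior new-bone areas in the emulated study (mm²).
#'
#' @param seed integer random seed (mandatory).
#' @param groupSizes named integer vector of animals per group.
#' @param groupMeans named numeric vector (same names): posterior-side group
#'   mean of the measurand.
#' @param locationEffect additive effect of the anterior location (default
#'   40 mm²: anterior new-bone area runs well above posterior).
#' @param interceptSD between-animal random-intercept SD.
#' @param residualSD residual SD.
#' @param measurand name of the measurand the values represent.
#' @return A list of class `studyConfig`.
#' @export
studyConfig <- function(seed,
                        groupSizes = c("0.0mm" = 6L, "0.2mm" = 6L,
                                       "0.4mm" = 7L, "0.8mm" = 8L,
                                       control = 4L),
                        groupMeans = c("0.0mm" = 48.8, "0.2mm" = 63.1,
                                       "0.4mm" = 58.8, "0.8mm" = 56.8,
                                       control = 34.4),
                        locationEffect = 40, interceptSD = 20,
                        residualSD = 15, measurand = "nB.Ar") {
  if (missing(seed) || !is.finite(seed))
    stop("a finite random seed is mandatory in a studyConfig")
  if (any(groupSizes < 1)) stop("all group sizes must be >= 1")
  if (interceptSD < 0 || residualSD < 0) stop("SDs must be non-negative")
  if (!setequal(names(groupSizes), names(groupMeans)))
    stop("groupSizes and groupMeans must carry the same group names")
  cfg <- list(seed = seed, groupSizes = groupSizes,
              groupMeans = groupMeans[names(groupSizes)],
              locationEffect = locationEffect, interceptSD = interceptSD,
              residualSD = residualSD, measurand = measurand)
  class(cfg) <- "studyConfig"
  cfg
}

#' Generate a synthetic study table
#'
#' Draws one value per (animal, region) as
#' `group mean + location effect (anterior) + animal intercept + residual`,
#' truncated at zero, giving the long per-animal table the mixed models
#' consume. Deterministic under the config seed.
#'
#' @param config a [studyConfig()].
#' @return A `data.frame` (StudyTable) with columns `animal_id`, `group`,
#'   `region`, `measurand`, `value`.
#' @examples
#' head(generateStudy(studyConfig(seed = 7)))
#' @export
generateStudy <- function(config) {
  stopifnot(inherits(config, "studyConfig"))
  set.seed(config$seed)
  rows <- list()
  aIdx <- 0L
  for (g in names(config$groupSizes)) {
    for (i in seq_len(config$groupSizes[[g]])) {
      aIdx <- aIdx + 1L
      id <- sprintf("A%02d", aIdx)
      b <- stats::rnorm(1, 0, config$interceptSD)
      for (region in c("anterior", "posterior")) {
        mu <- config$groupMeans[[g]] +
          if (region == "anterior") config$locationEffect else 0
        val <- max(0, mu + b + stats::rnorm(1, 0, config$residualSD))
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = id, group = g, region = region,
          measurand = config$measurand, value = val,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
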