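#' @import methods
NULL

#' LabeledSection: a tissue-label raster with physical and anatomical metadata
#'
#' The pipeline's input object: a 2D single-channel integer raster in which
#' every pixel carries one of the six tissue codes of [tissueLabels()],
#' together with the metadata needed to measure it — the pixel resolution in
#' px/mm, which grid axis runs proximal–distal, the pixel coordinate of the
#' osteotomy-gap centre, which side of the longitudinal split line is
#' anterior, and the animal/treatment-group identifiers.
#'
#' Grid convention: matrices are indexed `[row, col]`, 1-based, row-major in
#' presentation; the row axis is proximal–distal unless `axis = "col"`.
#'
#' @slot labels integer matrix of tissue codes.
#' @slot resolution numeric, pixels per millimetre (> 0).
#' @slot axis `"row"` or `"col"`: the proximal–distal grid axis.
#' @slot gapCentre numeric length-2 `(row, col)` pixel coordinate of the
#'   osteotomy-gap centre; must lie inside the grid.
#' @slot anteriorSide `"left"` (lower cross-axis index) or `"right"`.
#' @slot animalId character scalar, opaque animal identifier.
#' @slot group character scalar, treatment-group label.
#' @slot palette `data.frame` mapping tissue names to values and colours.
#'
#' @seealso [LabeledSection()], [readSection()], [buildROI()]
#' @export
setClass("LabeledSection",
  representation(
    labels       = "matrix",
    resolution   = "numeric",
    axis         = "character",
    gapCentre    = "numeric",
    anteriorSide = "character",
    animalId     = "character",
    group        = "character",
    palette      = "data.frame"
  )
)

setValidity("LabeledSection", function(object) {
  msgs <- character(0)
  lab <- object@labels
  if (length(lab) == 0L)
    msgs <- c(msgs, "labels must be a non-empty matrix")
  if (!is.numeric(lab) && !is.integer(lab))
    msgs <- c(msgs, "labels must be numeric/integer")
  pv <- .checkPalette(object@palette)
  if (!is.null(pv)) msgs <- c(msgs, pv)
  if (is.null(pv) && length(lab) > 0L) {
    bad <- setdiff(unique(as.vector(lab)), object@palette$value)
    if (length(bad))
      msgs <- c(msgs, sprintf("label values outside the palette: %s",
                              paste(sort(bad), collapse = ", ")))
  }
  if (length(object@resolution) != 1L || !is.finite(object@resolution) ||
      object@resolution <= 0)
    msgs <- c(msgs, "resolution must be a single positive number (px/mm)")
  if (!object@axis %in% c("row", "col"))
    msgs <- c(msgs, "axis must be 'row' or 'col'")
  if (length(object@gapCentre) != 2L || any(!is.finite(object@gapCentre)))
    msgs <- c(msgs, "gapCentre must be a finite (row, col) pair")
  else if (length(lab) > 0L &&
           (object@gapCentre[1] < 1 || object@gapCentre[1] > nrow(lab) ||
            object@gapCentre[2] < 1 || object@gapCentre[2] > ncol(lab)))
    msgs <- c(msgs, "gapCentre must lie inside the grid")
  if (!object@anteriorSide %in% c("left", "right"))
    msgs <- c(msgs, "anteriorSide must be 'left' or 'right'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a LabeledSection
#'
#' @param labels integer matrix of tissue codes (see [tissueLabels()]).
#' @param resolution pixels per millimetre; the reference imaging setup
#'   acquires at 229 px/mm, which is the default.
#' @param gapCentre `(row, col)` pixel coordinate of the osteotomy-gap centre.
#'   Defaults to the grid centre.
#' @param axis which grid axis is proximal–distal: `"row"` (default) or
#'   `"col"`.
#' @param anteriorSide `"left"` or `"right"`: which side of the longitudinal
#'   split line is the anterior half.
#' @param animalId,group identifier metadata carried through to reports.
#' @param palette label palette; see [defaultPalette()].
#'
#' @return A validated [LabeledSection-class] object.
#' @examples
#' labs <- matrix(tissueLabels()[["BACKGROUND"]], 10, 10)
#' sec <- LabeledSection(labs, resolution = 10)
#' sec
#' @export
LabeledSection <- function(labels, resolution = 229,
                           gapCentre = c((nrow(labels) + 1) / 2,
                                         (ncol(labels) + 1) / 2),
                           axis = "row", anteriorSide = "left",
                           animalId = "unknown", group = "unknown",
                           palette = defaultPalette()) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  storage.mode(labels) <- "integer"
  new("LabeledSection", labels = labels, resolution = as.numeric(resolution),
      axis = axis, gapCentre = as.numeric(gapCentre),
      anteriorSide = anteriorSide, animalId = as.character(animalId),
      group = as.character(group), palette = palette)
}

#' CallusROI: the callus measurement domain and its anterior/posterior halves
#'
#' Boolean masks on the section grid: the callus region of interest (all
#' newly formed tissue within the proximal–distal window around the gap
#' centre, excluding cortical bone, background, and marrow open to the
#' medullary canal), and — once partitioned — its anterior and posterior
#' halves on either side of the longitudinal split line.
#'
#' @slot roiMask logical matrix: the callus ROI.
#' @slot anteriorMask,posteriorMask logical matrices partitioning `roiMask`
#'   (all-`FALSE` until [splitAnteriorPosterior()] is applied).
#' @slot splitLine numeric: cross-axis pixel index of the longitudinal split.
#' @slot windowHalfwidthMm numeric: half-width of the proximal–distal window
#'   in mm (15 mm by default, i.e. 1.5 cm to either side of the gap centre).
#' @slot partitioned logical: whether the anterior/posterior split is filled.
#' @slot empty logical: flag set when no callus tissue was found in the
#'   window (an empty ROI is a warning condition, not an error).
#' @seealso [buildROI()], [splitAnteriorPosterior()]
#' @export
setClass("CallusROI",
  representation(
    roiMask           = "matrix",
    anteriorMask      = "matrix",
    posteriorMask     = "matrix",
    splitLine         = "numeric",
    windowHalfwidthMm = "numeric",
    partitioned       = "logical",
    empty             = "logical"
  )
)

setValidity("CallusROI", function(object) {
  msgs <- character(0)
  r <- object@roiMask; a <- object@anteriorMask; p <- object@posteriorMask
  if (!is.logical(r) || !is.logical(a) || !is.logical(p))
    msgs <- c(msgs, "masks must be logical matrices")
  if (!identical(dim(r), dim(a)) || !identical(dim(r), dim(p)))
    msgs <- c(msgs, "mask dimensions must agree")
  else if (is.logical(r) && is.logical(a) && is.logical(p)) {
    if (any(a & p)) msgs <- c(msgs, "anterior and posterior masks overlap")
    if (any((a | p) & !r))
      msgs <- c(msgs, "anterior/posterior masks must be subsets of the ROI")
    if (isTRUE(object@partitioned) && any(r & !(a | p)))
      msgs <- c(msgs, "partitioned ROI: anterior ∪ posterior must equal the ROI")
  }
  if (object@windowHalfwidthMm <= 0)
    msgs <- c(msgs, "windowHalfwidthMm must be positive")
  if (length(msgs)) msgs else TRUE
})

#' DensityResult: local new-bone density map, class map and class areas
#'
#' Output of the nB.Dn method: for every callus-ROI pixel, the fraction of
#' new bone among ROI pixels within a fixed-radius disk around it, the
#' three-way low/medium/high classification of that fraction, and the mm²
#' area of each class per region.
#'
#' @slot densityMap numeric matrix in \[0, 1\], `NA` outside the ROI.
#' @slot classMap integer matrix (1 = low, 2 = medium, 3 = high), `NA`
#'   outside the ROI.
#' @slot classAreas `data.frame` with one row per (region, class).
#' @slot radiusMm disk radius in mm (default 0.8).
#' @slot thresholds numeric pair `(t_low, t_high)`, default `c(0.33, 0.66)`.
#' @slot resolution pixels per mm used for the area conversion.
#' @seealso [localDensityMap()], [classifyDensity()], [densityAnalysis()]
#' @export
setClass("DensityResult",
  representation(
    densityMap = "matrix",
    classMap   = "matrix",
    classAreas = "data.frame",
    radiusMm   = "numeric",
    thresholds = "numeric",
    resolution = "numeric"
  )
)

setValidity("DensityResult", function(object) {
  msgs <- character(0)
  d <- object@densityMap
  if (!identical(dim(d), dim(object@classMap)))
    msgs <- c(msgs, "densityMap and classMap dimensions must agree")
  v <- d[!is.na(d)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    msgs <- c(msgs, "density values must lie in [0, 1]")
  th <- object@thresholds
  if (length(th) != 2L || !(th[1] < th[2]) || th[1] <= 0 || th[2] >= 1)
    msgs <- c(msgs, "thresholds must be strictly increasing within (0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' LMMResult: a fitted linear mixed model for regional measurements
#'
#' Holds the fixed-effect estimates, variance components and term-level
#' F-tests of a mixed model with a random intercept per animal (and, for
#' density-class compositions, an additional animal-by-class random level).
#' F-tests use Satterthwaite denominator degrees of freedom; the tag in
#' `methodTag` records the estimator and approximation used.
#'
#' @slot fixedEffects `data.frame` with `term`, `estimate`, `se`.
#' @slot varianceComponents named numeric vector of variance components
#'   (SD scale), including `residual`.
#' @slot tests `data.frame` with `term`, `F`, `numDF`, `denDF`, `p`.
#' @slot methodTag character, e.g. `"REML + Satterthwaite F"`.
#' @slot converged logical.
#' @slot flags character vector of warnings (singular fit, degenerate data).
#' @slot measurand character: the dependent variable modelled.
#' @slot fit the underlying fit object (or `NULL` for degenerate input).
#' @seealso [fitAreaModel()], [fitDensityModel()]
#' @export
setClass("LMMResult",
  representation(
    fixedEffects       = "data.frame",
    varianceComponents = "numeric",
    tests              = "data.frame",
    methodTag          = "character",
    converged          = "logical",
    flags              = "character",
    measurand          = "character",
    fit                = "ANY"
  )
)

setValidity("LMMResult", function(object) {
  msgs <- character(0)
  if (any(object@varianceComponents < 0, na.rm = TRUE))
    msgs <- c(msgs, "variance components must be non-negative")
  p <- object@tests$p
  if (!is.null(p) && any(p < 0 | p > 1, na.rm = TRUE))
    msgs <- c(msgs, "p-values must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})
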