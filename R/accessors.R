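#' @name accessors
#' @title Accessors for callusHisto classes
#'
#' @description Small accessor generics so that user code never touches
#' slots directly: `labelMatrix()`, `pixelResolution()`, `gapCentre()`,
#' `anteriorSide()`, `animalId()`, `groupLabel()`, `sectionPalette()`,
#' `roiMask()`, `anteriorMask()`, `posteriorMask()`, `densityMap()`,
#' `classMap()`, `classAreaTable()`, `fixedEffects()`, `varianceComponents()`,
#' `modelTests()`.
#'
#' @param x a [LabeledSection-class], [CallusROI-class],
#'   [DensityResult-class] or [LMMResult-class] object, as appropriate.
#' @return The corresponding slot value.
#' @examples
#' sec <- LabeledSection(matrix(0L, 4, 4), resolution = 10)
#' pixelResolution(sec)
NULL

#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))
#' @rdname accessors
#' @export
setMethod("labelMatrix", "LabeledSection", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("pixelResolution", function(x) standardGeneric("pixelResolution"))
#' @rdname accessors
#' @export
setMethod("pixelResolution", "LabeledSection", function(x) x@resolution)
#' @rdname accessors
#' @export
setMethod("pixelResolution", "DensityResult", function(x) x@resolution)

#' @rdname accessors
#' @export
setGeneric("gapCentre", function(x) standardGeneric("gapCentre"))
#' @rdname accessors
#' @export
setMethod("gapCentre", "LabeledSection", function(x) x@gapCentre)

#' @rdname accessors
#' @export
setGeneric("anteriorSide", function(x) standardGeneric("anteriorSide"))
#' @rdname accessors
#' @export
setMethod("anteriorSide", "LabeledSection", function(x) x@anteriorSide)

#' @rdname accessors
#' @export
setGeneric("animalId", function(x) standardGeneric("animalId"))
#' @rdname accessors
#' @export
setMethod("animalId", "LabeledSection", function(x) x@animalId)

#' @rdname accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))
#' @rdname accessors
#' @export
setMethod("groupLabel", "LabeledSection", function(x) x@group)

#' @rdname accessors
#' @export
setGeneric("sectionPalette", function(x) standardGeneric("sectionPalette"))
#' @rdname accessors
#' @export
setMethod("sectionPalette", "LabeledSection", function(x) x@palette)

#' @rdname accessors
#' @export
setGeneric("roiMask", function(x) standardGeneric("roiMask"))
#' @rdname accessors
#' @export
setMethod("roiMask", "CallusROI", function(x) x@roiMask)

#' @rdname accessors
#' @export
setGeneric("anteriorMask", function(x) standardGeneric("anteriorMask"))
#' @rdname accessors
#' @export
setMethod("anteriorMask", "CallusROI", function(x) x@anteriorMask)

#' @rdname accessors
#' @export
setGeneric("posteriorMask", function(x) standardGeneric("posteriorMask"))
#' @rdname accessors
#' @export
setMethod("posteriorMask", "CallusROI", function(x) x@posteriorMask)

#' @rdname accessors
#' @export
setGeneric("isEmptyROI", function(x) standardGeneric("isEmptyROI"))
#' @rdname accessors
#' @export
setMethod("isEmptyROI", "CallusROI", function(x) x@empty)

#' @rdname accessors
#' @export
setGeneric("densityMap", function(x) standardGeneric("densityMap"))
#' @rdname accessors
#' @export
setMethod("densityMap", "DensityResult", function(x) x@densityMap)

#' @rdname accessors
#' @export
setGeneric("classMap", function(x) standardGeneric("classMap"))
#' @rdname accessors
#' @export
setMethod("classMap", "DensityResult", function(x) x@classMap)

#' @rdname accessors
#' @export
setGeneric("classAreaTable", function(x) standardGeneric("classAreaTable"))
#' @rdname accessors
#' @export
setMethod("classAreaTable", "DensityResult", function(x) x@classAreas)

#' @rdname accessors
#' @export
setGeneric("fixedEffects", function(x) standardGeneric("fixedEffects"))
#' @rdname accessors
#' @export
setMethod("fixedEffects", "LMMResult", function(x) x@fixedEffects)

#' @rdname accessors
#' @export
setGeneric("varianceComponents",
           function(x) standardGeneric("varianceComponents"))
#' @rdname accessors
#' @export
setMethod("varianceComponents", "LMMResult", function(x) x@varianceComponents)

#' @rdname accessors
#' @export
setGeneric("modelTests", function(x) standardGeneric("modelTests"))
#' @rdname accessors
#' @export
setMethod("modelTests", "LMMResult", function(x) x@tests)

setMethod("show", "LabeledSection", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabeledSection: %d x %d px at %.4g px/mm (%.3g x %.3g mm)\n",
              d[1], d[2], object@resolution,
              d[1] / object@resolution, d[2] / object@resolution))
  cat(sprintf("  animal '%s', group '%s'\n", object@animalId, object@group))
  cat(sprintf("  proximal-distal axis: %s; gap centre at (%.1f, %.1f); anterior: %s\n",
              object@axis, object@gapCentre[1], object@gapCentre[2],
              object@anteriorSide))
  tab <- table(factor(object@labels, levels = object@palette$value,
                      labels = object@palette$tissue))
  cat("  pixels per class:\n")
  print(tab)
  invisible(NULL)
})

setMethod("show", "CallusROI", function(object) {
  cat(sprintf("CallusROI: %d ROI px (window half-width %.3g mm)%s\n",
              sum(object@roiMask), object@windowHalfwidthMm,
              if (object@empty) " [EMPTY]" else ""))
  if (object@partitioned)
    cat(sprintf("  anterior %d px | posterior %d px (split line at %.1f)\n",
                sum(object@anteriorMask), sum(object@posteriorMask),
                object@splitLine))
  else cat("  not yet partitioned; see splitAnteriorPosterior()\n")
  invisible(NULL)
})

setMethod("show", "DensityResult", function(object) {
  v <- object@densityMap[!is.na(object@densityMap)]
  cat(sprintf("DensityResult: nB.Dn on %d ROI px (radius %.3g mm, thresholds %.2f/%.2f)\n",
              length(v), object@radiusMm, object@thresholds[1],
              object@thresholds[2]))
  if (length(v))
    cat(sprintf("  mean local density %.3f; class split low/medium/high = %s px\n",
                mean(v), paste(tabulate(object@classMap[!is.na(object@classMap)],
                                        nbins = 3L), collapse = "/")))
  invisible(NULL)
})

setMethod("show", "LMMResult", function(object) {
  cat(sprintf("LMMResult (%s): %s%s\n", object@measurand, object@methodTag,
              if (!object@converged) " [NOT CONVERGED]" else ""))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
  cat("  variance components (SD):\n")
  print(round(object@varianceComponents, 4))
  cat("  F-tests:\n")
  print(object@tests, row.names = FALSE)
  invisible(NULL)
})
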