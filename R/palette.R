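#' Tissue label codes
#'
#' Integer codes used in tissue-label rasters. Every pixel of a
#' [LabeledSection] carries exactly one of these six values: background
#' (outside the specimen), original cortical bone of the proximal and distal
#' fragments, newly formed (woven) bone, cartilage, soft/fibrous tissue, and
#' marrow.
#'
#' @return Named integer vector of the six tissue codes.
#' @examples
#' tissueLabels()
#' @export
tissueLabels <- function() {
  c(BACKGROUND    = 0L,
    CORTICAL_BONE = 1L,
    NEW_BONE      = 2L,
    CARTILAGE     = 3L,
    FIBROUS       = 4L,
    MARROW        = 5L)
}

#' Default label palette
#'
#' The palette maps each tissue-class name to its integer raster value and a
#' display colour. It is a bijection on the six class names and travels with
#' the section in the metadata sidecar, so label images are never interpreted
#' by colour.
#'
#' @return A `data.frame` with columns `tissue`, `value`, `colour`.
#' @examples
#' defaultPalette()
#' @export
defaultPalette <- function() {
  labs <- tissueLabels()
  data.frame(
    tissue = names(labs),
    value  = unname(labs),
    colour = c("#000000",  # background
               "#D9C6A5",  # cortical bone
               "#F2E3C0",  # new (woven) bone
               "#7A9BD4",  # cartilage
               "#C97FA4",  # fibrous tissue
               "#6B4F3A"), # marrow
    stringsAsFactors = FALSE
  )
}

#' Density-class display colours
#'
#' False-colour convention for the three local bone-density classes:
#' low density in red, medium in turquoise, high in light blue.
#'
#' @return Named character vector of hex colours for `low`, `medium`, `high`.
#' @export
densityClassColours <- function() {
  c(low = "#FF0000", medium = "#40E0D0", high = "#ADD8E6")
}

.checkPalette <- function(palette) {
  need <- c("tissue", "value", "colour")
  if (!is.data.frame(palette) || !all(need %in% names(palette)))
    return("palette must be a data.frame with columns tissue, value, colour")
  labs <- tissueLabels()
  if (!setequal(palette$tissue, names(labs)))
    return(sprintf("palette must cover exactly the classes: %s",
                   paste(names(labs), collapse = ", ")))
  if (anyDuplicated(palette$tissue) || anyDuplicated(palette$value))
    return("palette must be a bijection: duplicated tissue names or values")
  NULL
}
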