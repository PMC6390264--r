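## ROI construction: callus tissue within a proximal-distal window around the
## osteotomy gap centre; marrow/fibrous regions open to the surrounding marrow
## space or the image exterior are excluded, enclosed pockets are kept.

.shiftLogical <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  okr <- rs >= 1L & rs <= nr; okc <- cs >= 1L & cs <= nc
  out[okr, okc] <- m[rs[okr], cs[okc]]
  out
}

## multi-source BFS on a logical mask; returns all mask pixels reachable from
## seeds through mask pixels under 4- or 8-connectivity
.floodReachable <- function(mask, seeds, connectivity = 4L) {
  stopifnot(connectivity %in% c(4L, 8L))
  visited <- mask & seeds
  frontier <- visited
  offs <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  if (connectivity == 8L)
    offs <- c(offs, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
  while (any(frontier)) {
    nb <- Reduce(`|`, lapply(offs, function(o)
      .shiftLogical(frontier, o[1], o[2])))
    frontier <- nb & mask & !visited
    visited <- visited | frontier
  }
  visited
}

## proximal-distal ("pd") and cross-axis index matrices for a section
.axisIndex <- function(section) {
  d <- dim(section@labels)
  if (section@axis == "row")
    list(pd = row(matrix(0L, d[1], d[2])), cross = col(matrix(0L, d[1], d[2])),
         pdCentre = section@gapCentre[1], crossCentre = section@gapCentre[2])
  else
    list(pd = col(matrix(0L, d[1], d[2])), cross = row(matrix(0L, d[1], d[2])),
         pdCentre = section@gapCentre[2], crossCentre = section@gapCentre[1])
}

.roundHalfUp <- function(x) floor(x + 0.5)

#' Construct the callus region of interest
#'
#' Builds the boolean callus ROI on a labelled section: all newly formed
#' tissue within a proximal–distal window of `windowHalfwidthMm` (default
#' 15 mm, i.e. 1.5 cm to either side) around the osteotomy-gap centre.
#' New bone and cartilage pixels inside the window always belong to the ROI.
#' Soft/fibrous and marrow pixels belong to it only when they are enclosed
#' within the callus: any marrow/fibrous/background region 4-connected (see
#' `connectivity`) to the image border or to tissue outside the window is
#' treated as the surrounding marrow space / exterior and excluded, while
#' pockets fully encapsulated by callus or cortex are included as fibrous
#' tissue encapsulated within the callus. Cortical bone and background are
#' never part of the ROI. The lateral extent is not restricted: it is bounded
#' only by the extension of the callus itself.
#'
#' @param section a [LabeledSection-class].
#' @param windowHalfwidthMm half-width of the proximal–distal window in mm
#'   (converted to whole pixels by rounding half-up).
#' @param connectivity pixel connectivity for the reachability rule, 4
#'   (default) or 8.
#' @return A [CallusROI-class]; when the window contains no callus tissue the
#'   ROI is empty and flagged (a warning is emitted, not an error).
#' @seealso [splitAnteriorPosterior()], [measureSection()]
#' @examples
#' labs <- matrix(0L, 40, 40)
#' labs[15:25, 15:25] <- tissueLabels()[["NEW_BONE"]]
#' sec <- LabeledSection(labs, resolution = 1, gapCentre = c(20, 20))
#' roi <- buildROI(sec)
#' sum(roiMask(roi))  # the 11 x 11 blob
#' @export
buildROI <- function(section, windowHalfwidthMm = 15, connectivity = 4L) {
  stopifnot(is(section, "LabeledSection"))
  if (windowHalfwidthMm <= 0) stop("windowHalfwidthMm must be positive")
  labs <- section@labels
  tl <- tissueLabels()
  ax <- .axisIndex(section)
  halfPx <- .roundHalfUp(windowHalfwidthMm * section@resolution)
  window <- abs(ax$pd - .roundHalfUp(ax$pdCentre)) <= halfPx

  conduit <- matrix(labs %in% tl[c("MARROW", "FIBROUS", "BACKGROUND")],
                    nrow(labs), ncol(labs))
  border <- matrix(FALSE, nrow(labs), ncol(labs))
  border[1, ] <- TRUE; border[nrow(labs), ] <- TRUE
  border[, 1] <- TRUE; border[, ncol(labs)] <- TRUE
  open <- .floodReachable(conduit, conduit & (border | !window),
                          as.integer(connectivity))

  hard <- matrix(labs %in% tl[c("NEW_BONE", "CARTILAGE")],
                 nrow(labs), ncol(labs))
  soft <- matrix(labs %in% tl[c("MARROW", "FIBROUS")], nrow(labs), ncol(labs))
  roi <- window & (hard | (soft & !open))

  empty <- !any(roi)
  if (empty)
    warning("no callus tissue found within the proximal-distal window; ",
            "returning an empty ROI")
  blank <- matrix(FALSE, nrow(labs), ncol(labs))
  new("CallusROI", roiMask = roi, anteriorMask = blank, posteriorMask = blank,
      splitLine = ax$crossCentre, windowHalfwidthMm = windowHalfwidthMm,
      partitioned = FALSE, empty = empty)
}

#' Partition the callus ROI into anterior and posterior halves
#'
#' Divides the ROI longitudinally along the split line — the line through the
#' gap-centre coordinate parallel to the proximal–distal axis (overridable
#' via `splitLine`). The section's `anteriorSide` metadata decides which half
#' is anterior; pixels lying exactly on the split line are assigned to the
#' anterior half (deterministic tie-break).
#'
#' @param roi a [CallusROI-class] from [buildROI()].
#' @param section the [LabeledSection-class] the ROI was built from.
#' @param splitLine optional cross-axis pixel index overriding the default
#'   split through the gap centre.
#' @return The [CallusROI-class] with `anteriorMask`/`posteriorMask` filled;
#'   they partition `roiMask` exactly.
#' @examples
#' labs <- matrix(0L, 40, 40)
#' labs[15:25, 15:25] <- tissueLabels()[["NEW_BONE"]]
#' sec <- LabeledSection(labs, resolution = 1, gapCentre = c(20, 20))
#' roi <- splitAnteriorPosterior(buildROI(sec), sec)
#' sum(anteriorMask(roi)) + sum(posteriorMask(roi)) == sum(roiMask(roi))
#' @export
splitAnteriorPosterior <- function(roi, section, splitLine = NULL) {
  stopifnot(is(roi, "CallusROI"), is(section, "LabeledSection"))
  if (!identical(dim(roi@roiMask), dim(section@labels)))
    stop("ROI and section dimensions disagree")
  ax <- .axisIndex(section)
  split <- if (is.null(splitLine)) roi@splitLine else as.numeric(splitLine)
  ant <- if (section@anteriorSide == "left") ax$cross <= split
         else ax$cross >= split
  roi@anteriorMask <- roi@roiMask & ant
  roi@posteriorMask <- roi@roiMask & !ant
  roi@splitLine <- split
  roi@partitioned <- TRUE
  validObject(roi)
  roi
}

#' Build a CallusROI from an explicit mask
#'
#' Wraps a user-supplied (or ground-truth) boolean mask into a partitioned
#' [CallusROI-class], bypassing [buildROI()]'s reconstruction. Useful for
#' scoring against a generator's ground truth or for externally traced ROIs.
#'
#' @param mask logical matrix on the section grid.
#' @param section the matching [LabeledSection-class].
#' @param windowHalfwidthMm recorded window half-width (defaults to half the
#'   proximal–distal grid extent, i.e. unrestricted).
#' @return A partitioned [CallusROI-class].
#' @export
callusROIFromMask <- function(mask, section, windowHalfwidthMm = NULL) {
  stopifnot(is(section, "LabeledSection"), is.logical(mask),
            identical(dim(mask), dim(section@labels)))
  ax <- .axisIndex(section)
  if (is.null(windowHalfwidthMm)) {
    pdLen <- if (section@axis == "row") nrow(mask) else ncol(mask)
    windowHalfwidthMm <- pdLen / section@resolution / 2
  }
  blank <- matrix(FALSE, nrow(mask), ncol(mask))
  roi <- new("CallusROI", roiMask = mask, anteriorMask = blank,
             posteriorMask = blank, splitLine = ax$crossCentre,
             windowHalfwidthMm = windowHalfwidthMm, partitioned = FALSE,
             empty = !any(mask))
  splitAnteriorPosterior(roi, section)
}
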