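tl <- tissueLabels()

test_that("a single bone blob inside the window is exactly the ROI", {
  labs <- matrix(tl[["BACKGROUND"]], 40, 40)
  labs[11:20, 11:20] <- tl[["NEW_BONE"]]  # 100 px
  sec <- LabeledSection(labs, resolution = 1, gapCentre = c(15, 15))
  roi <- buildROI(sec)
  expect_equal(sum(roiMask(roi)), 100)
  expect_identical(roiMask(roi), labs == tl[["NEW_BONE"]])
  expect_false(isEmptyROI(roi))
})

test_that("a bone blob entirely outside the window yields an empty flagged ROI", {
  labs <- matrix(tl[["BACKGROUND"]], 80, 40)
  labs[70:75, 11:20] <- tl[["NEW_BONE"]]
  sec <- LabeledSection(labs, resolution = 1, gapCentre = c(10, 15))
  expect_warning(roi <- buildROI(sec, windowHalfwidthMm = 15), "empty ROI")
  expect_true(isEmptyROI(roi))
  expect_equal(sum(roiMask(roi)), 0)
})

test_that("enclosed fibrous pockets are kept, bands open to the marrow are excluded", {
  labs <- matrix(tl[["BACKGROUND"]], 40, 40)
  labs[10:30, 10:30] <- tl[["NEW_BONE"]]
  labs[15:18, 15:18] <- tl[["FIBROUS"]]   # pocket fully surrounded by bone
  labs[25, 20:40] <- tl[["MARROW"]]       # channel from inside to the border
  labs[24, 22:26] <- tl[["FIBROUS"]]      # band touching that open channel
  labs[24:26, 21] <- tl[["FIBROUS"]]
  sec <- LabeledSection(labs, resolution = 1, gapCentre = c(20, 20))
  roi <- buildROI(sec)
  m <- roiMask(roi)
  expect_true(all(m[15:18, 15:18]))            # pocket included
  expect_false(any(m[25, 20:40]))              # open channel excluded
  expect_false(m[24, 23])                      # band connected to it excluded
  expect_identical(m, oracleROI(sec))          # full rule vs scalar flood fill
})

test_that("buildROI matches the flood-fill oracle on random sections", {
  for (seed in 1:8) {
    sec <- randomSection(seed, nr = 40, nc = 36, resolution = 1)
    got <- suppressWarnings(roiMask(buildROI(sec, windowHalfwidthMm = 12)))
    expect_identical(got, oracleROI(sec, windowHalfwidthMm = 12),
                     label = sprintf("seed %d", seed))
  }
})

test_that("the ROI never contains cortical bone, background, or out-of-window pixels", {
  for (seed in 11:14) {
    sec <- randomSection(seed, resolution = 1)
    roi <- suppressWarnings(buildROI(sec, windowHalfwidthMm = 10))
    m <- roiMask(roi)
    labs <- labelMatrix(sec)
    expect_false(any(m & labs == tl[["CORTICAL_BONE"]]))
    expect_false(any(m & labs == tl[["BACKGROUND"]]))
    dist <- abs(row(labs) - floor(gapCentre(sec)[1] + 0.5))
    expect_true(all(dist[m] <= floor(10 * pixelResolution(sec) + 0.5)))
  }
})

test_that("enlarging the window never shrinks the ROI", {
  for (seed in 21:24) {
    sec <- randomSection(seed, resolution = 1)
    small <- suppressWarnings(roiMask(buildROI(sec, windowHalfwidthMm = 6)))
    big <- suppressWarnings(roiMask(buildROI(sec, windowHalfwidthMm = 14)))
    expect_false(any(small & !big), label = sprintf("seed %d", seed))
  }
})

test_that("anterior and posterior masks partition the ROI pixel-for-pixel", {
  for (seed in 31:36) {
    sec <- randomSection(seed, resolution = 1)
    roi <- suppressWarnings(buildROI(sec, windowHalfwidthMm = 12))
    roi <- splitAnteriorPosterior(roi, sec)
    expect_identical(anteriorMask(roi) | posteriorMask(roi), roiMask(roi))
    expect_false(any(anteriorMask(roi) & posteriorMask(roi)))
  }
})

test_that("a symmetric ROI splits into equal halves; on-line pixels go anterior", {
  labs <- matrix(tl[["BACKGROUND"]], 30, 31)
  labs[10:20, 6:26] <- tl[["NEW_BONE"]]   # symmetric about column 16
  sec <- LabeledSection(labs, resolution = 1, gapCentre = c(15, 16))
  roi <- splitAnteriorPosterior(buildROI(sec), sec)
  # 21 columns, on-line column 16 counts as anterior: 11 x 11 vs 11 x 10
  expect_equal(sum(anteriorMask(roi)), 11 * 11)
  expect_equal(sum(posteriorMask(roi)), 11 * 10)
})

test_that("callus lying entirely on the anterior side leaves posterior empty", {
  labs <- matrix(tl[["BACKGROUND"]], 30, 30)
  labs[10:20, 2:10] <- tl[["NEW_BONE"]]
  sec <- LabeledSection(labs, resolution = 1, gapCentre = c(15, 20))
  roi <- splitAnteriorPosterior(buildROI(sec), sec)
  expect_equal(sum(posteriorMask(roi)), 0)
  expect_equal(sum(anteriorMask(roi)), sum(roiMask(roi)))
})

test_that("anteriorSide = 'right' mirrors the partition", {
  labs <- matrix(tl[["BACKGROUND"]], 30, 30)
  labs[10:20, 5:25] <- tl[["NEW_BONE"]]
  secL <- LabeledSection(labs, resolution = 1, gapCentre = c(15, 15),
                         anteriorSide = "left")
  secR <- LabeledSection(labs, resolution = 1, gapCentre = c(15, 15),
                         anteriorSide = "right")
  roiL <- splitAnteriorPosterior(buildROI(secL), secL)
  roiR <- splitAnteriorPosterior(buildROI(secR), secR)
  # both conventions assign the on-line column to anterior
  expect_equal(sum(anteriorMask(roiL)), sum(anteriorMask(roiR)))
  expect_false(any(anteriorMask(roiL) & anteriorMask(roiR) &
                     col(labs) != 15))
})
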