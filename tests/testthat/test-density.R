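tl <- tissueLabels()

test_that("disk sums match the per-pixel brute-force oracle exactly", {
  set.seed(101)
  for (r in c(2, 3.5, 5)) {
    x <- matrix(rpois(30 * 24, 2), 30, 24)
    expect_identical(diskNeighborhoodSum(x, r), oracleDiskSum(x, r),
                     label = sprintf("radius %g", r))
  }
})

test_that("an all-bone ROI has density 1 everywhere, including edge pixels", {
  sec <- rectSection(20, 20)
  mask <- matrix(FALSE, 20, 20); mask[3:18, 3:18] <- TRUE
  d <- localDensityMap(sec, callusROIFromMask(mask, sec), radiusMm = 2)
  expect_true(all(d[mask] == 1))
  expect_true(all(is.na(d[!mask])))
})

test_that("an ROI without new bone has density 0 everywhere", {
  sec <- rectSection(20, 20, "FIBROUS")
  mask <- matrix(TRUE, 20, 20)
  d <- localDensityMap(sec, callusROIFromMask(mask, sec), radiusMm = 2)
  expect_true(all(d == 0))
})

test_that("a 1-px checkerboard gives interior densities near 0.5, exactly as brute force", {
  labs <- matrix(tl[["FIBROUS"]], 40, 40)
  labs[(row(labs) + col(labs)) %% 2 == 0] <- tl[["NEW_BONE"]]
  sec <- LabeledSection(labs, resolution = 2)   # radius 4 mm -> 8 px
  mask <- matrix(TRUE, 40, 40)
  roi <- callusROIFromMask(mask, sec)
  d <- localDensityMap(sec, roi, radiusMm = 4)
  bone <- (labs == tl[["NEW_BONE"]]) + 0
  num <- oracleDiskSum(bone, 8); den <- oracleDiskSum(mask + 0, 8)
  expect_identical(d, num / den)
  # closed form for an interior pixel on the bone parity: the density is the
  # share of disk offsets with even di + dj, a pure parity count of the disk
  offs <- expand.grid(di = -8:8, dj = -8:8)
  offs <- offs[offs$di^2 + offs$dj^2 <= 64, ]
  nEven <- sum((offs$di + offs$dj) %% 2 == 0)
  expect_equal(d[20, 20], nEven / nrow(offs))
  expect_lt(abs(d[20, 20] - 0.5), 0.02)  # parity imbalance stays small
})

test_that("the fast density map equals naive disk counting on random sections", {
  for (seed in 1:6) {
    sec <- randomSection(seed, nr = 32, nc = 28, resolution = 2)
    roi <- randomMaskROI(seed + 100, sec)
    d <- localDensityMap(sec, roi, radiusMm = 2.5)   # 5 px
    bone <- ((labelMatrix(sec) == tl[["NEW_BONE"]]) & roiMask(roi)) + 0
    num <- oracleDiskSum(bone, 5)
    den <- oracleDiskSum(roiMask(roi) + 0, 5)
    expl <- matrix(NA_real_, 32, 28)
    expl[roiMask(roi)] <- num[roiMask(roi)] / den[roiMask(roi)]
    expect_identical(d, expl, label = sprintf("seed %d", seed))
  }
})

test_that("a sub-pixel radius is a configuration error", {
  sec <- rectSection(10, 10)
  roi <- callusROIFromMask(matrix(TRUE, 10, 10), sec)  # resolution 2 px/mm
  expect_error(localDensityMap(sec, roi, radiusMm = 0.3), "below one pixel")
})

test_that("classification brackets are <0.33 low, [0.33, 0.66] medium, >0.66 high", {
  d <- matrix(c(0.20, 0.50, 0.80, 0.33, 0.66, NA), 2, 3)
  cl <- classifyDensity(d)
  expect_equal(as.vector(cl), c(1L, 2L, 3L, 2L, 2L, NA))
  expect_error(classifyDensity(d, thresholds = c(0.7, 0.3)),
               "strictly increasing")
  expect_error(classifyDensity(d, thresholds = c(0, 0.5)),
               "strictly increasing")
})

test_that("class pixel counts always sum to the ROI pixel count", {
  for (seed in 41:44) {
    sec <- randomSection(seed, resolution = 2)
    roi <- randomMaskROI(seed, sec)
    cl <- classifyDensity(localDensityMap(sec, roi, radiusMm = 2))
    expect_equal(sum(!is.na(cl)), sum(roiMask(roi)))
    expect_equal(sum(tabulate(cl[!is.na(cl)], 3)), sum(roiMask(roi)))
  }
})

test_that("class areas partition Cl.Ar per region", {
  g <- generateSection(sectionConfig(seed = 17, resolution = 4))
  roi <- splitAnteriorPosterior(buildROI(g$section), g$section)
  dres <- densityAnalysis(g$section, roi)
  rec <- measureSection(g$section, roi)
  ca <- classAreaTable(dres)
  for (rg in c("anterior", "posterior", "total")) {
    expect_equal(sum(ca$px[ca$region == rg]), rec$Cl.px[rec$region == rg])
    expect_equal(sum(ca$area[ca$region == rg]),
                 rec[["Cl.Ar"]][rec$region == rg])
    expect_equal(sum(ca$percent[ca$region == rg]), 100)
  }
})

test_that("an all-high map reports the full callus area as high", {
  sec <- rectSection(20, 20, resolution = 10)      # 0.01 mm2 per px
  mask <- matrix(FALSE, 20, 20); mask[1:20, 1:10] <- TRUE  # 200 px = 2.0 mm2
  roi <- callusROIFromMask(mask, sec)
  dres <- densityAnalysis(sec, roi, radiusMm = 0.5)
  ca <- classAreaTable(dres)
  expect_equal(ca$area[ca$region == "total" & ca$class == "high"], 2.0)
  expect_equal(ca$area[ca$region == "total" & ca$class == "medium"], 0)
  expect_equal(ca$area[ca$region == "total" & ca$class == "low"], 0)
})

test_that("mean density equals the ROI bone fraction exactly on a torus", {
  for (seed in 51:53) {
    sec <- randomSection(seed, nr = 30, nc = 30, resolution = 2)
    roi <- callusROIFromMask(matrix(TRUE, 30, 30), sec)
    d <- localDensityMap(sec, roi, radiusMm = 3, wrap = TRUE)
    boneFrac <- mean(labelMatrix(sec) == tl[["NEW_BONE"]])
    expect_equal(mean(d), boneFrac, tolerance = 1e-12)
    expect_equal(densityEdgeBound(roi, 3, 2, wrap = TRUE), 0,
                 tolerance = 1e-12)
  }
})

test_that("off-torus, the mean density deviates by at most the computed edge bound", {
  for (seed in 61:63) {
    g <- generateSection(sectionConfig(seed = seed, resolution = 4))
    roi <- g$truth$roi
    d <- localDensityMap(g$section, roi, radiusMm = 0.8)
    rec <- measureSection(g$section, roi)
    tot <- rec[rec$region == "total", ]
    bound <- densityEdgeBound(roi, 0.8, pixelResolution(g$section))
    expect_lte(abs(mean(d, na.rm = TRUE) - tot$nB.px / tot$Cl.px), bound)
  }
})

test_that("adding new-bone pixels never decreases any local density", {
  set.seed(77)
  labs <- matrix(tl[["FIBROUS"]], 30, 30)
  labs[runif(900) < 0.3] <- tl[["NEW_BONE"]]
  sec1 <- LabeledSection(labs, resolution = 2)
  labs2 <- labs
  flips <- sample(which(labs == tl[["FIBROUS"]]), 40)
  labs2[flips] <- tl[["NEW_BONE"]]
  sec2 <- LabeledSection(labs2, resolution = 2)
  mask <- matrix(TRUE, 30, 30)
  d1 <- localDensityMap(sec1, callusROIFromMask(mask, sec1), radiusMm = 2.5)
  d2 <- localDensityMap(sec2, callusROIFromMask(mask, sec2), radiusMm = 2.5)
  expect_true(all(d2 >= d1))
})

test_that("banded sections recover their band's class in the interior", {
  b <- generateBandedSection(seed = 5, fills = c(0.2, 0.5, 0.8),
                             bandHeightMm = 6, widthMm = 8, resolution = 10)
  dres <- densityAnalysis(b$section, b$roi, radiusMm = 0.8)
  cl <- classMap(dres)
  rPx <- ceiling(0.8 * 10)
  for (i in 1:3) {
    bandPx <- which(b$truth$band == i, arr.ind = TRUE)
    interior <- bandPx[
      bandPx[, 1] >= min(bandPx[, 1]) + rPx & bandPx[, 1] <= max(bandPx[, 1]) - rPx &
      bandPx[, 2] >= min(bandPx[, 2]) + rPx & bandPx[, 2] <= max(bandPx[, 2]) - rPx, ]
    cls <- cl[interior]
    expect_equal(as.integer(names(which.max(table(cls)))), i,
                 label = sprintf("band %d majority class", i))
  }
})
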