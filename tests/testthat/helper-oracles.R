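# Independent oracles used across the suite. Each deliberately reimplements
# the quantity it checks with the dumbest correct algorithm.

# per-pixel double-loop disk sum (exact; use only on small grids)
oracleDiskSum <- function(x, rPx) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  R <- floor(rPx); r2 <- rPx^2
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (di in -R:R) for (dj in -R:R) {
      if (di * di + dj * dj <= r2) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) s <- s + x[ii, jj]
      }
    }
    out[i, j] <- s
  }
  out
}

# offset-accumulation disk sum: independent of the cumulative-sum fast path,
# still exact, fast enough for ~128 x 128 grids
shiftDiskSum <- function(x, rPx) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  R <- floor(rPx); r2 <- rPx^2
  for (di in -R:R) for (dj in -R:R) {
    if (di * di + dj * dj > r2) next
    ri <- max(1, 1 - di):min(nr, nr - di)
    ci <- max(1, 1 - dj):min(nc, nc - dj)
    out[ri, ci] <- out[ri, ci] + x[ri + di, ci + dj]
  }
  out
}

# scalar queue-based flood fill (reachability oracle)
oracleFlood <- function(mask, seeds, connectivity = 4) {
  nr <- nrow(mask); nc <- ncol(mask)
  visited <- mask & seeds
  queue <- which(visited)
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8)
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    i <- (p - 1) %% nr + 1; j <- (p - 1) %/% nr + 1
    for (o in offs) {
      ii <- i + o[1]; jj <- j + o[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
        q <- (jj - 1) * nr + ii
        if (mask[q] && !visited[q]) {
          visited[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
  }
  visited
}

# full ROI-rule recomputation on top of the scalar flood fill
oracleROI <- function(section, windowHalfwidthMm = 15, connectivity = 4) {
  labs <- labelMatrix(section)
  tl <- tissueLabels()
  nr <- nrow(labs); nc <- ncol(labs)
  res <- pixelResolution(section)
  gc <- gapCentre(section)
  halfPx <- floor(windowHalfwidthMm * res + 0.5)
  pd <- row(labs)  # sections in these tests all use axis = "row"
  window <- abs(pd - floor(gc[1] + 0.5)) <= halfPx
  conduit <- matrix(labs %in% tl[c("MARROW", "FIBROUS", "BACKGROUND")], nr, nc)
  border <- matrix(FALSE, nr, nc)
  border[c(1, nr), ] <- TRUE; border[, c(1, nc)] <- TRUE
  open <- oracleFlood(conduit, conduit & (border | !window), connectivity)
  hard <- matrix(labs %in% tl[c("NEW_BONE", "CARTILAGE")], nr, nc)
  soft <- matrix(labs %in% tl[c("MARROW", "FIBROUS")], nr, nc)
  window & (hard | (soft & !open))
}

# random labelled section for property tests
randomSection <- function(seed, nr = 48, nc = 48, resolution = 2,
                          probs = c(0.25, 0.05, 0.3, 0.05, 0.2, 0.15)) {
  set.seed(seed)
  tl <- tissueLabels()
  labs <- matrix(sample(unname(tl), nr * nc, replace = TRUE, prob = probs),
                 nr, nc)
  LabeledSection(labs, resolution = resolution,
                 gapCentre = c(sample(nr, 1), sample(nc, 1)),
                 animalId = sprintf("R%d", seed), group = "random")
}

# random ROI mask wrapped into a CallusROI on an arbitrary section
randomMaskROI <- function(seed, section, p = 0.5) {
  set.seed(seed)
  d <- dim(labelMatrix(section))
  mask <- matrix(runif(prod(d)) < p, d[1], d[2])
  callusROIFromMask(mask, section)
}

# small fully-bone section with an explicit rectangular ROI
rectSection <- function(nr, nc, label = "NEW_BONE", resolution = 2) {
  tl <- tissueLabels()
  LabeledSection(matrix(tl[[label]], nr, nc), resolution = resolution)
}
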