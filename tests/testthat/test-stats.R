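makeDensityTable <- function(seed, n = 10, shiftHigh = 0, noise = 5,
                             base = c(low = 20, medium = 40, high = 40)) {
  # two groups, two regions, three classes per animal/region, rows sum to 100
  set.seed(seed)
  rows <- list()
  for (grp in c("ctrl", "trt")) {
    mu <- base
    if (grp == "trt")
      mu <- base + c(-shiftHigh / 2, -shiftHigh / 2, shiftHigh)
    for (i in seq_len(n)) {
      id <- sprintf("%s%02d", grp, i)
      for (rg in c("anterior", "posterior")) {
        x <- mu + rnorm(3, 0, noise)
        x <- pmax(x, 1)
        x <- 100 * x / sum(x)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = id, group = grp, region = rg,
          class = c("low", "medium", "high"), percent = x,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

test_that("identical groups with zero spread give zero effects and p = 1", {
  tab <- data.frame(
    animal_id = rep(sprintf("A%d", 1:6), each = 2),
    group = rep(c("g1", "g2"), each = 6),
    region = rep(c("anterior", "posterior"), 6),
    measurand = "nB.Ar", value = 50, stringsAsFactors = FALSE)
  fit <- fitAreaModel(tab)
  expect_true(fit@converged)
  expect_match(paste(fit@flags, collapse = " "), "degenerate")
  expect_true(all(modelTests(fit)$p == 1))
  fe <- fixedEffects(fit)
  expect_equal(fe$estimate[fe$term == "(Intercept)"], 50)
})

test_that("with no between-animal variance the fixed effects match OLS", {
  tab <- generateStudy(studyConfig(seed = 11, interceptSD = 0,
                                   residualSD = 10))
  fit <- fitAreaModel(tab)
  d <- tab
  d$group <- factor(d$group)
  d$region <- factor(d$region, levels = c("posterior", "anterior"))
  ols <- lm(value ~ group * region, data = d)
  fe <- fixedEffects(fit)
  expect_equal(fe$estimate, unname(coef(ols)[fe$term]), tolerance = 1e-4)
  expect_match(paste(fit@flags, collapse = " "), "singular|boundary",
               ignore.case = TRUE)
})

test_that("estimates are invariant to row order and animal relabeling", {
  tab <- generateStudy(studyConfig(seed = 12))
  fit1 <- fitAreaModel(tab)
  set.seed(1)
  tab2 <- tab[sample(nrow(tab)), ]
  map <- setNames(sprintf("Z%02d", sample(31)), unique(tab$animal_id))
  tab2$animal_id <- unname(map[tab2$animal_id])
  fit2 <- fitAreaModel(tab2)
  expect_equal(fixedEffects(fit1)$estimate, fixedEffects(fit2)$estimate,
               tolerance = 1e-6)
  expect_equal(modelTests(fit1)$F, modelTests(fit2)$F, tolerance = 1e-6)
})

test_that("degenerate designs are rejected with informative errors", {
  tab <- generateStudy(studyConfig(seed = 13))
  oneGroup <- tab[tab$group == "0.0mm", ]
  expect_error(fitAreaModel(oneGroup), "two treatment groups")
  oneRegion <- tab[tab$region == "anterior", ]
  expect_error(fitAreaModel(oneRegion), "anterior and posterior")
  dup <- rbind(tab, tab[1, ])
  expect_error(fitAreaModel(dup), "at most once")
  expect_error(fitAreaModel(tab, measurand = "Cg.Ar"), "no rows")
})

test_that("likelihood-ratio route reports chi-square tests and agrees on strong effects", {
  tab <- generateStudy(studyConfig(seed = 14))
  sat <- fitAreaModel(tab)
  lrt <- fitAreaModel(tab, method = "lrt")
  expect_match(lrt@methodTag, "likelihood-ratio")
  expect_true(all(is.na(modelTests(lrt)$denDF)))
  # the strong location effect is detected by both routes
  pSat <- modelTests(sat)$p[modelTests(sat)$term == "region"]
  pLrt <- modelTests(lrt)$p[modelTests(lrt)$term == "region"]
  expect_lt(pSat, 0.01)
  expect_lt(pLrt, 0.01)
})

test_that("variance components are recovered on a large simulated study", {
  cfg <- studyConfig(seed = 15,
                     groupSizes = c(g1 = 60, g2 = 60),
                     groupMeans = c(g1 = 100, g2 = 120),
                     locationEffect = 40, interceptSD = 20, residualSD = 10)
  fit <- fitAreaModel(generateStudy(cfg))
  vc <- varianceComponents(fit)
  expect_lt(abs(vc[["animal_id"]] - 20) / 20, 0.25)
  expect_lt(abs(vc[["residual"]] - 10) / 10, 0.25)
})

test_that("identical density compositions give zero group effect and p = 1", {
  tab <- makeDensityTable(seed = 1, n = 6, shiftHigh = 0, noise = 0)
  fit <- fitDensityModel(tab)
  expect_match(paste(fit@flags, collapse = " "), "degenerate")
  expect_true(all(modelTests(fit)$p == 1))
})

test_that("near-uniform compositions repeated on every row give p ~ 1", {
  rows <- expand.grid(animal_id = sprintf("A%d", 1:8),
                      region = c("anterior", "posterior"),
                      class = c("low", "medium", "high"),
                      stringsAsFactors = FALSE)
  rows$group <- ifelse(as.integer(sub("A", "", rows$animal_id)) <= 4,
                       "g1", "g2")
  rows$percent <- c(low = 33.3, medium = 33.3, high = 33.4)[rows$class]
  fit <- fitDensityModel(rows)
  p <- modelTests(fit)$p
  expect_true(all(p[modelTests(fit)$term != "class"] > 0.99))
})

test_that("percentages that do not sum to 100 are rejected", {
  tab <- makeDensityTable(seed = 2, n = 4)
  tab$percent[1] <- tab$percent[1] + 5
  expect_error(fitDensityModel(tab), "sum to 100")
})

test_that("a shift in the high-density class is recovered with the right sign", {
  nrep <- 60
  hits <- 0L
  for (i in seq_len(nrep)) {
    tab <- makeDensityTable(seed = 300 + i, n = 50, shiftHigh = 15)
    fit <- fitDensityModel(tab)
    fe <- fixedEffects(fit)
    est <- fe$estimate[fe$term == "classhigh:grouptrt"]
    hits <- hits + (length(est) == 1 && est > 0)
  }
  expect_gte(hits / nrep, 0.95)
})
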