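## Mixed models for regional measurements: a random intercept per animal,
## fixed effects for treatment group and location (anterior/posterior) and
## their interaction. Term F-tests use Satterthwaite denominator degrees of
## freedom (likelihood-ratio tests on ML fits are available as an
## alternative); the method tag in every result records which was used.

#' Convert per-animal measurement records to a long study table
#'
#' @param records a `data.frame` from [measureSection()] rows (several
#'   animals bound together).
#' @param measurands measurand columns to melt into the long format.
#' @param regions which regions to keep (the models use the two halves).
#' @return A StudyTable `data.frame` with columns `animal_id`, `group`,
#'   `region`, `measurand`, `value`.
#' @export
asStudyTable <- function(records, measurands = c("nB.Ar", "Cg.Ar"),
                         regions = c("anterior", "posterior")) {
  stopifnot(is.data.frame(records))
  measurands <- intersect(measurands, names(records))
  if (!length(measurands)) stop("no requested measurand columns present")
  recs <- records[records$region %in% regions, , drop = FALSE]
  out <- do.call(rbind, lapply(measurands, function(m)
    data.frame(animal_id = recs$animal_id, group = recs$group,
               region = recs$region, measurand = m, value = recs[[m]],
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

.checkStudyTable <- function(d) {
  need <- c("animal_id", "group", "region", "value")
  if (!all(need %in% names(d)))
    stop("study table needs columns: ", paste(need, collapse = ", "))
  key <- paste(d$animal_id, d$region, sep = "\r")
  if (anyDuplicated(key))
    stop("each (animal, region) may appear at most once per measurand")
  byAnimal <- tapply(d$group, d$animal_id, function(g) length(unique(g)))
  if (any(byAnimal > 1)) stop("every animal must belong to exactly one group")
  if (length(unique(d$group)) < 2)
    stop("singular design: at least two treatment groups are required")
  if (length(unique(d$region)) < 2)
    stop("singular design: both anterior and posterior records are required")
  invisible(TRUE)
}

.degenerateResult <- function(response, terms, measurand, methodTag,
                              vcNames) {
  fe <- data.frame(term = "(Intercept)", estimate = mean(response), se = 0,
                   stringsAsFactors = FALSE)
  new("LMMResult",
      fixedEffects = fe,
      varianceComponents = stats::setNames(rep(0, length(vcNames)), vcNames),
      tests = data.frame(term = terms, F = 0, numDF = NA_real_,
                         denDF = NA_real_, p = 1, stringsAsFactors = FALSE),
      methodTag = paste(methodTag, "(degenerate: zero response variance)"),
      converged = TRUE,
      flags = "degenerate: response has zero variance; effects fixed at 0, p at 1",
      measurand = measurand, fit = NULL)
}

.collectLmerFit <- function(fit, terms, measurand, methodTag, flags,
                            tests = NULL) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  vcomp <- stats::setNames(vc$sdcor, sub("\\.\\d+$", "", vc$grp))
  names(vcomp)[names(vcomp) == "Residual"] <- "residual"
  if (lme4::isSingular(fit)) flags <- c(flags, "singular fit")
  if (is.null(tests)) {
    an <- as.data.frame(stats::anova(fit)) # lmerTest: Satterthwaite, type III
    tests <- data.frame(term = rownames(an), F = an[["F value"]],
                        numDF = an[["NumDF"]], denDF = an[["DenDF"]],
                        p = an[["Pr(>F)"]], stringsAsFactors = FALSE)
    tests <- tests[match(terms, tests$term), , drop = FALSE]
    tests$term <- terms
  }
  conv <- length(fit@optinfo$conv$lme4) == 0 ||
    is.null(fit@optinfo$conv$lme4$messages)
  fe <- data.frame(term = names(lme4::fixef(fit)),
                   estimate = unname(lme4::fixef(fit)),
                   se = sqrt(diag(as.matrix(stats::vcov(fit)))),
                   stringsAsFactors = FALSE)
  new("LMMResult", fixedEffects = fe, varianceComponents = vcomp,
      tests = tests, methodTag = methodTag, converged = conv,
      flags = unique(flags), measurand = measurand, fit = fit)
}

.quietLmer <- function(expr) {
  flags <- character(0)
  fit <- withCallingHandlers(
    expr,
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      flags <<- c(flags, sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  list(fit = fit, flags = flags)
}

#' Fit the regional area mixed model
#'
#' Fits `value ~ group * region + (1 | animal_id)` to one measurand of a
#' study table (nB.Ar or Cg.Ar in the emulated design): a random intercept
#' per animal, fixed effects for treatment group and location
#' (anterior/posterior, posterior as reference) and their interaction.
#' REML estimation with Satterthwaite F-tests by default; `method = "lrt"`
#' switches to ML fits compared by likelihood-ratio tests (the statistic is
#' then a chi-square, reported in the `F` column with `denDF = NA`).
#'
#' A response with zero variance (e.g. identical groups with all SDs zero)
#' is handled as a documented degenerate case: effects 0, p-values 1,
#' flagged. Non-convergence is flagged on the result, never silent.
#'
#' @param table StudyTable `data.frame`; see [asStudyTable()],
#'   [generateStudy()].
#' @param measurand which measurand to model (matched against the
#'   `measurand` column when present).
#' @param method `"satterthwaite"` (default) or `"lrt"`.
#' @param reml use REML (default) for the Satterthwaite path; ignored for
#'   `"lrt"`, which requires ML.
#' @return An [LMMResult-class].
#' @examples
#' tab <- generateStudy(studyConfig(seed = 3))
#' fitAreaModel(tab)
#' @export
fitAreaModel <- function(table, measurand = "nB.Ar",
                         method = c("satterthwaite", "lrt"), reml = TRUE) {
  method <- match.arg(method)
  d <- table
  if ("measurand" %in% names(d))
    d <- d[d$measurand == measurand, , drop = FALSE]
  if (!nrow(d)) stop(sprintf("no rows for measurand '%s'", measurand))
  .checkStudyTable(d)
  d$group <- factor(d$group)
  d$region <- factor(d$region, levels = c("posterior", "anterior"))
  d$animal_id <- factor(d$animal_id)
  terms <- c("group", "region", "group:region")
  vcNames <- c("animal_id", "residual")

  if (stats::sd(d$value) == 0)
    return(.degenerateResult(d$value, terms, measurand,
                             "REML + Satterthwaite F", vcNames))

  if (method == "satterthwaite") {
    q <- .quietLmer(lmerTest::lmer(value ~ group * region + (1 | animal_id),
                                   data = d, REML = reml))
    return(.collectLmerFit(q$fit, terms, measurand,
                           sprintf("%s + Satterthwaite F",
                                   if (reml) "REML" else "ML"), q$flags))
  }

  ## likelihood-ratio route on ML fits, respecting marginality
  qFull <- .quietLmer(lme4::lmer(value ~ group * region + (1 | animal_id),
                                 data = d, REML = FALSE))
  qAdd  <- .quietLmer(lme4::lmer(value ~ group + region + (1 | animal_id),
                                 data = d, REML = FALSE))
  qNoG  <- .quietLmer(lme4::lmer(value ~ region + (1 | animal_id),
                                 data = d, REML = FALSE))
  qNoR  <- .quietLmer(lme4::lmer(value ~ group + (1 | animal_id),
                                 data = d, REML = FALSE))
  lrt <- function(big, small) {
    a <- stats::anova(big, small)
    c(stat = a$Chisq[2], df = a$Df[2], p = a[["Pr(>Chisq)"]][2])
  }
  rows <- rbind(group = lrt(qAdd$fit, qNoG$fit),
                region = lrt(qAdd$fit, qNoR$fit),
                `group:region` = lrt(qFull$fit, qAdd$fit))
  tests <- data.frame(term = terms, F = rows[, "stat"],
                      numDF = rows[, "df"], denDF = NA_real_,
                      p = rows[, "p"], stringsAsFactors = FALSE)
  .collectLmerFit(qFull$fit, terms, measurand,
                  "ML + likelihood-ratio tests",
                  c(qFull$flags, qAdd$flags), tests = tests)
}

#' Fit the density-composition mixed model
#'
#' Models the three density-class percentages of every animal and region
#' jointly: `percent ~ class * group + class * region` with a random
#' intercept per animal plus an additional animal-by-class random level, so
#' that all three densities of an animal are accounted for simultaneously.
#' The treatment effect on callus composition is the `class:group`
#' interaction (a uniform shift of all classes is impossible since
#' percentages sum to 100); the location effect on composition is
#' `class:region`.
#'
#' @param table `data.frame` with columns `animal_id`, `group`, `region`,
#'   `class` (low/medium/high) and `percent`; per (animal, region) the three
#'   percentages must sum to 100 within `tol`.
#' @param tol tolerance on the 100% sum check (percentage points).
#' @return An [LMMResult-class] with F-tests for `class`, `group`, `region`,
#'   `class:group` and `class:region`.
#' @export
fitDensityModel <- function(table, tol = 0.5) {
  need <- c("animal_id", "group", "region", "class", "percent")
  if (!all(need %in% names(table)))
    stop("density table needs columns: ", paste(need, collapse = ", "))
  d <- table
  sums <- tapply(d$percent, paste(d$animal_id, d$region, sep = "\r"), sum)
  if (any(abs(sums - 100) > tol))
    stop(sprintf(
      "density-class percentages must sum to 100 (± %g) per animal and region",
      tol))
  d$class <- factor(d$class, levels = c("low", "medium", "high"))
  d$group <- factor(d$group)
  d$region <- factor(d$region, levels = c("posterior", "anterior"))
  d$animal_id <- factor(d$animal_id)
  terms <- c("class", "group", "region", "class:group", "class:region")
  vcNames <- c("animal_id:class", "animal_id", "residual")

  withinClassVar <- tapply(d$percent, d$class, function(v)
    if (length(v) > 1) stats::var(v) else 0)
  if (all(withinClassVar < 1e-12))
    return(.degenerateResult(d$percent, terms, "density composition",
                             "REML + Satterthwaite F", vcNames))

  q <- .quietLmer(lmerTest::lmer(
    percent ~ class * group + class * region +
      (1 | animal_id) + (1 | animal_id:class),
    data = d, REML = TRUE))
  .collectLmerFit(q$fit, terms, "density composition",
                  "REML + Satterthwaite F", q$flags)
}
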