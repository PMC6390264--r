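## End-to-end orchestration: sections in (from disk or the synthetic
## generator), per-animal morphometry and density tables, group summaries,
## overlays, mixed-model fits and a machine-readable run manifest out.
## Outputs contain no timestamps, so identical seeds give byte-identical
## files.

#' Read a pipeline run configuration
#'
#' Reads a YAML run configuration with blocks:
#' \preformatted{
#' seed: 1
#' output_dir: out
#' input:
#'   synthetic:                  # XOR 'manifest'
#'     group_sizes: {0.0mm: 6, 0.2mm: 6, 0.4mm: 7, 0.8mm: 8, control: 4}
#'     resolution: 15
#'   manifest:
#'     - {image: a.png, meta: a.yaml}
#' roi:     {window_halfwidth_mm: 15, connectivity: 4}
#' density: {radius_mm: 0.8, thresholds: [0.33, 0.66]}
#' stats:   {fit: true, method: satterthwaite}
#' overlays: true
#' }
#'
#' @param path YAML file path.
#' @return The configuration list (validated by [runPipeline()]).
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

.cfgGet <- function(cfg, keys, default) {
  for (k in keys) {
    if (is.null(cfg)) return(default)
    cfg <- cfg[[k]]
  }
  cfg %||% default
}

.loadInputSections <- function(config) {
  man <- .cfgGet(config, c("input", "manifest"), NULL)
  syn <- .cfgGet(config, c("input", "synthetic"), NULL)
  if (is.null(man) == is.null(syn))
    stop("validation error: configure exactly one input source ",
         "(input$manifest XOR input$synthetic)")
  if (!is.null(man))
    return(lapply(man, function(e) readSection(e$image, e$meta)))
  sizes <- unlist(.cfgGet(syn, "group_sizes",
                          c("0.0mm" = 6, "0.2mm" = 6, "0.4mm" = 7,
                            "0.8mm" = 8, control = 4)))
  res <- .cfgGet(syn, "resolution", 15)
  seed <- .cfgGet(config, "seed", 1)
  sections <- list()
  idx <- 0L
  for (g in names(sizes)) {
    for (i in seq_len(sizes[[g]])) {
      idx <- idx + 1L
      cfg <- sectionConfig(
        seed = (as.integer(seed) * 1000L + idx) %% .Machine$integer.max,
        resolution = res,
        profile = if (g == "control") "control" else "treatment",
        animalId = sprintf("A%02d", idx), group = g)
      sections[[idx]] <- generateSection(cfg)$section
    }
  }
  sections
}

#' Run the full histomorphometry pipeline
#'
#' For every input section: build and partition the callus ROI, measure the
#' area/fraction measurands, compute the local bone-density map and class
#' areas, and (optionally) write a false-colour overlay. Then write the
#' per-animal and group-summary report CSVs, fit the mixed models when the
#' study design allows it (at least two groups and two animals), and write a
#' run manifest recording parameters, seed and package version. Warnings
#' (empty ROI, non-convergence) never abort the batch; they are tabulated in
#' the manifest.
#'
#' @param config a configuration list (see [readRunConfig()]) or a path to a
#'   YAML file.
#' @param outputDir overrides `config$output_dir`.
#' @return Invisibly, a list with `records`, `densityRows`, `summaries`,
#'   `models`, `warnings` and `files`.
#' @examples
#' cfg <- list(seed = 11,
#'             input = list(synthetic = list(
#'               group_sizes = list("0.0mm" = 1, control = 1),
#'               resolution = 8)),
#'             overlays = FALSE)
#' res <- runPipeline(cfg, outputDir = tempfile("run"))
#' names(res$files)
#' @export
runPipeline <- function(config, outputDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  outDir <- outputDir %||% .cfgGet(config, "output_dir", NULL)
  if (is.null(outDir))
    stop("validation error: an output directory is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("output directory is not creatable: ", outDir)

  windowMm <- .cfgGet(config, c("roi", "window_halfwidth_mm"), 15)
  conn <- .cfgGet(config, c("roi", "connectivity"), 4)
  radiusMm <- .cfgGet(config, c("density", "radius_mm"), 0.8)
  thresholds <- unlist(.cfgGet(config, c("density", "thresholds"),
                               c(0.33, 0.66)))
  doOverlays <- isTRUE(.cfgGet(config, "overlays", TRUE))
  doStats <- isTRUE(.cfgGet(config, c("stats", "fit"), TRUE))
  statMethod <- .cfgGet(config, c("stats", "method"), "satterthwaite")

  sections <- .loadInputSections(config)
  records <- list(); densityRows <- list(); warns <- list(); files <- list()

  for (sec in sections) {
    id <- animalId(sec)
    roi <- withCallingHandlers(
      buildROI(sec, windowHalfwidthMm = windowMm, connectivity = conn),
      warning = function(w) {
        warns[[length(warns) + 1L]] <<- data.frame(
          stage = "roi", animal_id = id, message = conditionMessage(w),
          stringsAsFactors = FALSE)
        invokeRestart("muffleWarning")
      })
    roi <- splitAnteriorPosterior(roi, sec)
    records[[length(records) + 1L]] <- measureSection(sec, roi)
    if (!isEmptyROI(roi)) {
      dres <- densityAnalysis(sec, roi, radiusMm = radiusMm,
                              thresholds = thresholds)
      ca <- classAreaTable(dres)
      ca$animal_id <- id
      ca$group <- groupLabel(sec)
      densityRows[[length(densityRows) + 1L]] <-
        ca[, c("animal_id", "group", "region", "class", "px", "area",
               "percent")]
      if (doOverlays) {
        op <- file.path(outDir, sprintf("overlay_%s.png", id))
        writeOverlay(sec, dres, op)
        files[[sprintf("overlay_%s", id)]] <- op
      }
    }
  }

  records <- do.call(rbind, records)
  densityRows <- if (length(densityRows)) do.call(rbind, densityRows)
                 else NULL

  files$morphometry <- file.path(outDir, "morphometry.csv")
  writeReport(records, files$morphometry)
  files$group_summary <- file.path(outDir, "group_summary.csv")
  utils::write.csv(summarizeGroups(records), files$group_summary,
                   row.names = FALSE)
  if (!is.null(densityRows)) {
    files$density <- file.path(outDir, "density_classes.csv")
    writeDensityReport(densityRows, files$density)
  }

  models <- list()
  enoughDesign <- length(unique(records$group)) >= 2 &&
    length(unique(records$animal_id)) >= 2
  if (doStats && enoughDesign) {
    tab <- asStudyTable(records)
    for (m in c("nB.Ar", "Cg.Ar")) {
      fit <- tryCatch(fitAreaModel(tab, measurand = m, method = statMethod),
                      error = function(e) e)
      if (inherits(fit, "error"))
        warns[[length(warns) + 1L]] <- data.frame(
          stage = "stats", animal_id = "",
          message = sprintf("%s model: %s", m, conditionMessage(fit)),
          stringsAsFactors = FALSE)
      else models[[m]] <- fit
    }
    if (!is.null(densityRows)) {
      dtab <- densityRows[densityRows$region %in%
                            c("anterior", "posterior"), ]
      fit <- tryCatch(fitDensityModel(dtab), error = function(e) e)
      if (inherits(fit, "error"))
        warns[[length(warns) + 1L]] <- data.frame(
          stage = "stats", animal_id = "",
          message = paste("density model:", conditionMessage(fit)),
          stringsAsFactors = FALSE)
      else models[["density"]] <- fit
    }
    if (length(models)) {
      files$models <- file.path(outDir, "models.csv")
      mrows <- do.call(rbind, lapply(names(models), function(nm) {
        tt <- modelTests(models[[nm]])
        cbind(data.frame(model = nm, method = models[[nm]]@methodTag,
                         converged = models[[nm]]@converged,
                         stringsAsFactors = FALSE), tt)
      }))
      utils::write.csv(mrows, files$models, row.names = FALSE)
    }
  }

  warns <- if (length(warns)) do.call(rbind, warns)
           else data.frame(stage = character(0), animal_id = character(0),
                           message = character(0))
  manifest <- list(
    package = "callusHisto",
    version = as.character(utils::packageVersion("callusHisto")),
    seed = .cfgGet(config, "seed", NA),
    parameters = list(window_halfwidth_mm = windowMm, connectivity = conn,
                      radius_mm = radiusMm, thresholds = thresholds,
                      stats_method = statMethod),
    n_sections = length(sections),
    warnings = warns,
    files = lapply(files, basename))
  files$manifest <- file.path(outDir, "run_manifest.json")
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(records = records, densityRows = densityRows,
                 summaries = summarizeGroups(records), models = models,
                 warnings = warns, files = files))
}
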