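# End-to-end pipeline commands and run manifests. These functions back the
# command-line entry point (inst/cli/enmscreen.R) but are ordinary exported
# functions usable from R.

packageVersionString <- function() {
  as.character(utils::packageVersion("enmscreen"))
}

writeManifest <- function(path, config, seed, inputs = character(),
                          outputs = character(), timings = list(),
                          status = "ok", error = NULL) {
  digests <- if (length(inputs)) {
    d <- tools::md5sum(inputs[file.exists(inputs)])
    as.list(d)
  } else list()
  obj <- list(software = list(package = "enmscreen",
                              version = packageVersionString()),
              master_seed = seed, config = config,
              input_digests = digests,
              timings_sec = timings, outputs = as.list(outputs),
              status = status)
  if (!is.null(error)) obj$error <- error
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

readScenarioFile <- function(path) {
  y <- yaml::read_yaml(path)
  syntheticScenario(
    gridShape = unlist(y$grid_shape %||% c(60, 60)),
    nLayers = y$n_layers %||% 12,
    smoothness = y$smoothness %||% 5,
    crossCorrelation = if (!is.null(y$cross_correlation)) {
      cc <- y$cross_correlation
      if (is.list(cc)) do.call(rbind, lapply(cc, unlist)) else unlist(cc)
    },
    trueVariables = unlist(y$true_variables %||% c("env01", "env02", "env03")),
    trueCoefficients = list(
      linear = unlist(y$true_coefficients$linear %||% c(2, -2, 2)),
      quadratic = unlist(y$true_coefficients$quadratic)),
    nPresences = y$n_presences %||% 150,
    nodataFraction = y$nodata_fraction %||% 0,
    jitter = isTRUE(y$jitter),
    seed = y$seed %||% 1)
}

readScreenConfigFile <- function(path, pool) {
  y <- yaml::read_yaml(path)
  s <- y$settings %||% list()
  screenConfig(
    pool = pool,
    kPerRun = y$k_per_run %||% 6,
    runsPerSprint = y$runs_per_sprint %||% 10,
    nSprints = y$n_sprints %||% 100,
    topK = y$top_k %||% 6,
    settings = modelSettings(
      featureClasses = s$feature_classes %||% "LQHP",
      rm = s$regularization_multiplier %||% 1.0,
      hingeKnots = s$hinge_knots %||% 50,
      thresholdKnots = s$threshold_knots %||% 50),
    masterSeed = y$master_seed %||% 1,
    checkpoints = unlist(y$checkpoints %||% c(25, 50, 100)))
}

#' Simulate a synthetic study area to files
#'
#' Reads a scenario description (YAML), generates the landscape, true
#' suitability surface and presence records, and writes them as ASCII grid
#' rasters and CSV plus a run manifest.
#'
#' @param scenarioFile YAML scenario path (fields \code{grid_shape},
#'   \code{n_layers}, \code{smoothness}, \code{cross_correlation},
#'   \code{true_variables}, \code{true_coefficients}, \code{n_presences},
#'   \code{nodata_fraction}, \code{seed}; all optional).
#' @param outDir output directory.
#' @param seed optional override of the scenario seed.
#' @return invisible list of output paths.
#' @export
cmdSimulate <- function(scenarioFile, outDir, seed = NULL) {
  t0 <- proc.time()[["elapsed"]]
  scenario <- readScenarioFile(scenarioFile)
  if (!is.null(seed)) scenario$seed <- as.integer(seed)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  grid <- genLandscape(scenario)
  suit <- scenarioSuitability(scenario, grid)
  pres <- samplePresences(suit, scenario$nPresences,
                          seed = deriveRunSeed(scenario$seed, 1),
                          jitter = scenario$jitter)
  rasterPaths <- writeEnvGrid(grid, file.path(outDir, "layers"))
  suitPath <- file.path(outDir, "suitability.asc")
  writeAsciiGrid(gridLayer(suit, 1), suitPath, xll = suit@xll,
                 yll = suit@yll, cellSize = suit@cellSize)
  occPath <- file.path(outDir, "occurrences.csv")
  writeOccurrences(pres, occPath)
  outputs <- c(rasterPaths, suitPath, occPath)
  manifest <- file.path(outDir, "manifest.json")
  writeManifest(manifest, config = unclass(scenario), seed = scenario$seed,
                inputs = scenarioFile, outputs = outputs,
                timings = list(total = proc.time()[["elapsed"]] - t0))
  invisible(list(rasters = rasterPaths, suitability = suitPath,
                 occurrences = occPath, manifest = manifest))
}

#' Run the screening pipeline on raster + occurrence files
#'
#' Reads and aligns the rasters, ingests, deduplicates and spatially thins
#' the occurrences, samples background points, extracts the predictor
#' matrices and runs the Monte Carlo screening ensemble. Writes the sprint
#' log, tally table, checkpoint models, ensemble summary and a manifest.
#'
#' @param configFile YAML screening configuration (see
#'   \code{inst/extdata/screen-config.yml} for the fields; defaults follow
#'   the package's standard ensemble design: 100 sprints of 10 runs,
#'   top 6, LQHP, RM 1.0).
#' @param rasterPaths character vector of aligned ASCII grid files (the
#'   predictor pool; layer names are the file base names).
#' @param occFile occurrence CSV with \code{lon}, \code{lat} columns.
#' @param outDir output directory.
#' @param seed optional override of the config's master seed.
#' @param workers parallel workers per sprint (identical results for any
#'   value).
#' @param thinKm spatial thinning radius in km (default 16; 0 disables).
#' @param nBackground background sample size (default 10000, capped at the
#'   number of valid cells).
#' @return invisible list with the [EnsembleResult-class] and output paths.
#' @export
cmdScreen <- function(configFile, rasterPaths, occFile, outDir, seed = NULL,
                      workers = 1L, thinKm = 16, nBackground = 10000) {
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  missing <- rasterPaths[!file.exists(rasterPaths)]
  if (length(missing))
    stop("missing raster file(s): ", paste(missing, collapse = ", "))
  grid <- readEnvGrid(rasterPaths)
  occ <- readOccurrences(occFile)
  occ <- deduplicate(occ)
  if (thinKm > 0) occ <- thinOccurrences(occ, radiusKm = thinKm)
  timings$prepare <- proc.time()[["elapsed"]] - t0
  cfg <- readScreenConfigFile(configFile, pool = layerNames(grid))
  if (!is.null(seed)) cfg$masterSeed <- as.integer(seed)
  bg <- sampleBackground(grid, n = min(nBackground, sum(gridMask(grid))),
                         seed = deriveRunSeed(cfg$masterSeed, 999983))
  presenceX <- gridExtract(grid, occ)
  backgroundX <- gridExtract(grid, bg)
  t1 <- proc.time()[["elapsed"]]
  result <- runEnsemble(cfg, list(presenceX = presenceX,
                                  backgroundX = backgroundX),
                        workers = workers)
  timings$ensemble <- proc.time()[["elapsed"]] - t1
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  logPath <- file.path(outDir, "sprint_log.csv")
  writeSprintLog(result, logPath)
  tallyPath <- file.path(outDir, "tally.csv")
  writeTally(tallyOf(result), tallyPath)
  ckPaths <- character()
  for (nm in names(result@checkpoints)) {
    ck <- result@checkpoints[[nm]]
    if (!is.null(ck$model)) {
      p <- file.path(outDir, paste0("model_", nm, ".json"))
      modelToJson(ck$model, p)
      ckPaths <- c(ckPaths, p)
    }
  }
  summaryPath <- file.path(outDir, "summary.json")
  jsonlite::write_json(
    list(final_top_k = finalTopK(result),
         stability_sprint_set = result@stabilitySet,
         stability_sprint_order = result@stabilityOrder,
         total_runs = totalRuns(result),
         n_presences = nrow(presenceX), n_background = nrow(backgroundX),
         checkpoints = lapply(result@checkpoints, function(ck)
           ck[c("sprint", "topK", "aicc", "auc", "meanUseCount")])),
    summaryPath, auto_unbox = TRUE, digits = NA, null = "null")
  outputs <- c(logPath, tallyPath, ckPaths, summaryPath)
  manifest <- file.path(outDir, "manifest.json")
  timings$total <- proc.time()[["elapsed"]] - t0
  writeManifest(manifest, config = unclass(cfg)[setdiff(names(unclass(cfg)),
                                                        "settings")],
                seed = cfg$masterSeed,
                inputs = c(configFile, rasterPaths, occFile),
                outputs = outputs, timings = timings)
  invisible(list(result = result, sprintLog = logPath, tally = tallyPath,
                 checkpointModels = ckPaths, summary = summaryPath,
                 manifest = manifest))
}

#' Compare suitability maps: pairwise niche-overlap matrices
#'
#' Reads suitability maps (ASCII grids on a shared grid) and writes their
#' pairwise Schoener's D and Warren's I matrices as CSV plus a manifest.
#'
#' @param mapPaths >= 1 ASCII grid paths (a single map is compared with
#'   itself).
#' @param outDir output directory.
#' @return invisible list with the matrices and output paths.
#' @export
cmdEvaluate <- function(mapPaths, outDir) {
  t0 <- proc.time()[["elapsed"]]
  maps <- lapply(mapPaths, function(p) readAsciiGrid(p)$values)
  names(maps) <- sub("\\.[^.]*$", "", basename(mapPaths))
  if (length(maps) == 1L) maps <- c(maps, maps)
  sim <- similarityMatrix(maps)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  simPath <- file.path(outDir, "similarity.csv")
  writeSimilarityCsv(sim, simPath)
  manifest <- file.path(outDir, "manifest.json")
  writeManifest(manifest, config = list(maps = mapPaths), seed = NA,
                inputs = mapPaths, outputs = simPath,
                timings = list(total = proc.time()[["elapsed"]] - t0))
  invisible(list(similarity = sim, csv = simPath, manifest = manifest))
}
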