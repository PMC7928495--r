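#' @import methods
NULL

#' EnvGrid: an aligned stack of environmental raster layers
#'
#' Holds one or more single-band raster layers on a shared regular
#' longitude/latitude grid, together with a shared validity mask (the union
#' of the input layers' nodata cells) and the geotransform (lower-left
#' corner and square cell size in degrees). Row 1 is the northernmost row;
#' column 1 the westernmost column.
#'
#' @slot values numeric array of dimension rows x cols x layers.
#' @slot layerNames character vector of unique layer identifiers, one per
#'   layer, in stack order.
#' @slot mask logical matrix (rows x cols); \code{TRUE} marks a valid cell.
#'   A cell that is nodata in any layer is invalid in all layers.
#' @slot xll,yll numeric; longitude/latitude of the outer corner of the
#'   lower-left (southernmost, westernmost) cell.
#' @slot cellSize positive numeric; cell edge length in degrees.
#' @slot crs character CRS identifier (informational; layers must already be
#'   aligned — the package performs no reprojection).
#'
#' @seealso [readEnvGrid()], [gridExtract()], [sampleBackground()]
#' @export
setClass("EnvGrid",
  representation(
    values = "array",
    layerNames = "character",
    mask = "matrix",
    xll = "numeric",
    yll = "numeric",
    cellSize = "numeric",
    crs = "character"
  )
)

setValidity("EnvGrid", function(object) {
  d <- dim(object@values)
  msgs <- character()
  if (length(d) != 3L)
    msgs <- c(msgs, "values must be a rows x cols x layers array")
  else {
    if (length(object@layerNames) != d[3])
      msgs <- c(msgs, "one layer name per layer required")
    if (!identical(dim(object@mask), d[1:2]))
      msgs <- c(msgs, "mask must match layer shape")
  }
  if (anyDuplicated(object@layerNames))
    msgs <- c(msgs, "layer names must be unique")
  if (length(object@cellSize) != 1L || object@cellSize <= 0)
    msgs <- c(msgs, "cellSize must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' MaxentModel: a fitted penalized maximum-entropy niche model
#'
#' The model is a Gibbs distribution over the training background,
#' \eqn{p(x) \propto \exp(\lambda \cdot f(x))}, where \eqn{f} is the feature
#' expansion of the predictors and \eqn{\lambda} the penalized coefficients.
#' Raw output is normalized to sum to one over the training background.
#'
#' @slot coefficients named numeric vector of feature weights.
#' @slot featureMeta data.frame describing each feature column (class,
#'   source variable(s), knot).
#' @slot scaling data.frame of per-variable min/max used to map raw predictor
#'   values to [0, 1] before feature expansion.
#' @slot logZ log partition constant over the training background.
#' @slot entropy entropy H of the fitted raw distribution over the training
#'   background.
#' @slot bgEta linear predictor over the training background (kept so the
#'   normalizer and information criteria can be recomputed without the
#'   original rasters).
#' @slot settings the [modelSettings()] list used for the fit.
#' @slot variableNames predictors the model was fitted on.
#' @slot converged logical; optimizer convergence flag.
#' @slot objective final penalized objective value.
#'
#' @seealso [maxentFit()], [maxentPredict()]
#' @export
setClass("MaxentModel",
  representation(
    coefficients = "numeric",
    featureMeta = "data.frame",
    scaling = "data.frame",
    logZ = "numeric",
    entropy = "numeric",
    bgEta = "numeric",
    settings = "list",
    variableNames = "character",
    converged = "logical",
    objective = "numeric"
  )
)

setValidity("MaxentModel", function(object) {
  msgs <- character()
  if (length(object@entropy) == 1L && is.finite(object@entropy) &&
      object@entropy < -1e-8)
    msgs <- c(msgs, "entropy must be non-negative")
  if (length(object@coefficients) != nrow(object@featureMeta))
    msgs <- c(msgs, "one coefficient per feature required")
  if (length(msgs)) msgs else TRUE
})

#' TallyTable: running per-variable screening record
#'
#' For each variable in the screening pool, the number of runs that used it
#' and the cumulative sum of its run-level permutation importance (each run's
#' importances sum to 100 over that run's subset). The screening score is
#' the ratio \code{cumImportance / useCount}.
#'
#' @slot variables ordered pool of variable names.
#' @slot useCount integer vector of run-use counts.
#' @slot cumImportance numeric vector of cumulative permutation-importance
#'   percentages.
#'
#' @seealso [newTally()], [updateTally()], [avgImportance()], [topVariables()]
#' @export
setClass("TallyTable",
  representation(
    variables = "character",
    useCount = "integer",
    cumImportance = "numeric"
  )
)

setValidity("TallyTable", function(object) {
  n <- length(object@variables)
  msgs <- character()
  if (length(object@useCount) != n || length(object@cumImportance) != n)
    msgs <- c(msgs, "useCount and cumImportance must match variables")
  if (any(object@useCount < 0L))
    msgs <- c(msgs, "useCount must be non-negative")
  if (anyDuplicated(object@variables))
    msgs <- c(msgs, "variables must be unique")
  if (length(msgs)) msgs else TRUE
})

#' EnsembleResult: outcome of a Monte Carlo screening ensemble
#'
#' @slot sprints list of sprint records; each has the per-run subsets and
#'   importance vectors, a tally snapshot (as a data.frame), the sprint-end
#'   top-k variable list and the sprint-end model's AICc/AUC.
#' @slot tally final [TallyTable-class].
#' @slot finalTopK ordered top-k variables at the end of the ensemble.
#' @slot stabilitySet,stabilityOrder earliest sprint from which the top-k
#'   set (respectively its full order) never changes again; \code{NA} if
#'   never stable.
#' @slot checkpoints named list of checkpoint entries (sprint-end model and
#'   metrics at the configured checkpoint sprints).
#' @slot totalRuns number of runs executed.
#' @slot config the [screenConfig()] used.
#' @slot dryRun logical; \code{TRUE} when only subset draws were performed.
#'
#' @seealso [runEnsemble()]
#' @export
setClass("EnsembleResult",
  representation(
    sprints = "list",
    tally = "TallyTable",
    finalTopK = "character",
    stabilitySet = "numeric",
    stabilityOrder = "numeric",
    checkpoints = "list",
    totalRuns = "numeric",
    config = "list",
    dryRun = "logical"
  )
)

setValidity("EnsembleResult", function(object) {
  cfg <- object@config
  if (length(cfg) && !is.null(cfg$nSprints) && !is.null(cfg$runsPerSprint) &&
      object@totalRuns != cfg$nSprints * cfg$runsPerSprint)
    return("totalRuns must equal nSprints * runsPerSprint")
  TRUE
})
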