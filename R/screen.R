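# Monte Carlo variable screening: sprints of independent model runs on
# random predictor subsets, accumulated in a tally of permutation
# importance whose running averages rank the pool.

#' Configuration for a screening ensemble
#'
#' @param pool ordered character vector of candidate variable names.
#' @param kPerRun number of variables drawn (without replacement) for each
#'   run; typical choices are small (2 or 6) relative to the pool.
#' @param runsPerSprint runs per sprint (default 10).
#' @param nSprints sprints per ensemble (default 100).
#' @param topK size of the selected subset (default 6).
#' @param settings [modelSettings()] used for every run (default LQHP,
#'   RM 1.0, the historical MaxEnt default for large samples).
#' @param masterSeed integer seed; per-run seeds are derived from it with
#'   [deriveRunSeed()], so results are independent of execution order.
#' @param checkpoints sprint indices at which the sprint-end model is
#'   retained (default 25, 50, 100, intersected with \code{nSprints}).
#' @param stopAfterStable experimental early-stopping rule: if a positive
#'   integer, the ensemble stops once the top-k set has been unchanged for
#'   that many consecutive sprints. Off (\code{NULL}) by default.
#' @return validated list of class \code{"ScreenConfig"}.
#' @export
screenConfig <- function(pool, kPerRun, runsPerSprint = 10L, nSprints = 100L,
                         topK = 6L, settings = modelSettings(),
                         masterSeed = 1L, checkpoints = c(25L, 50L, 100L),
                         stopAfterStable = NULL) {
  pool <- as.character(pool)
  if (anyDuplicated(pool)) stop("pool names must be unique")
  if (kPerRun < 1 || kPerRun > length(pool))
    stop("configuration error: kPerRun must be in 1..|pool|")
  if (topK > length(pool)) stop("topK must not exceed the pool size")
  checkpoints <- intersect(as.integer(checkpoints), seq_len(nSprints))
  structure(list(pool = pool, kPerRun = as.integer(kPerRun),
                 runsPerSprint = as.integer(runsPerSprint),
                 nSprints = as.integer(nSprints), topK = as.integer(topK),
                 settings = settings, masterSeed = as.integer(masterSeed),
                 checkpoints = checkpoints,
                 stopAfterStable = stopAfterStable),
            class = "ScreenConfig")
}

#' Draw a random variable subset
#'
#' k distinct variables, uniform over the pool, from the caller's current
#' RNG stream (seed before calling to reproduce).
#'
#' @param pool character vector of variable names.
#' @param k subset size.
#' @return character vector of k names.
#' @export
drawSubset <- function(pool, k) {
  if (k > length(pool))
    stop("configuration error: k exceeds the pool size")
  if (k == length(pool)) return(pool)
  sample(pool, k)
}

#' Create an empty tally table over a pool
#'
#' @param pool ordered variable names.
#' @return a [TallyTable-class] with zero counts.
#' @export
newTally <- function(pool) {
  pool <- as.character(pool)
  new("TallyTable", variables = pool,
      useCount = integer(length(pool)),
      cumImportance = numeric(length(pool)))
}

#' @rdname TallyTable-accessors
#' @export
setMethod("useCount", "TallyTable",
          function(x) stats::setNames(x@useCount, x@variables))
#' @rdname TallyTable-accessors
#' @export
setMethod("cumImportance", "TallyTable",
          function(x) stats::setNames(x@cumImportance, x@variables))
#' @rdname TallyTable-accessors
#' @export
setMethod("avgImportance", "TallyTable", function(x) {
  avg <- ifelse(x@useCount > 0, x@cumImportance / x@useCount, 0)
  stats::setNames(avg, x@variables)
})

setMethod("show", "TallyTable", function(object) {
  cat("TallyTable:", length(object@variables), "variables,",
      sum(object@useCount), "total uses\n")
  df <- as.data.frame(object)
  print(utils::head(df[order(-df$avg_importance), ], 10), row.names = FALSE)
})

#' Convert a tally to a data.frame
#'
#' @param x a [TallyTable-class].
#' @param ... unused.
#' @return data.frame with \code{variable}, \code{use_count},
#'   \code{cum_importance}, \code{avg_importance}.
#' @export
as.data.frame.TallyTable <- function(x, ...) {
  data.frame(variable = x@variables, use_count = x@useCount,
             cum_importance = x@cumImportance,
             avg_importance = as.numeric(avgImportance(x)))
}

#' Add one run's importances to a tally
#'
#' Each variable in the run's subset gets its use count incremented and the
#' run's permutation importance (a percentage; 0 counts as 0) added to its
#' cumulative sum.
#'
#' @param tally a [TallyTable-class].
#' @param runImportances named numeric vector over the run's subset.
#' @return the updated [TallyTable-class].
#' @export
updateTally <- function(tally, runImportances) {
  idx <- match(names(runImportances), tally@variables)
  if (anyNA(idx))
    stop("schema error: unknown variable(s): ",
         paste(names(runImportances)[is.na(idx)], collapse = ", "))
  tally@useCount[idx] <- tally@useCount[idx] + 1L
  tally@cumImportance[idx] <- tally@cumImportance[idx] + runImportances
  tally
}

#' Current top-k variables of a tally
#'
#' Ranks variables with positive use count by average permutation
#' importance, descending; ties break by pool order. Returns \code{NULL}
#' (a deferred-selection signal, not an error) while fewer than k variables
#' have been used — expected in early sprints.
#'
#' @param tally a [TallyTable-class].
#' @param k subset size.
#' @return ordered character vector of k names, or \code{NULL}.
#' @export
topVariables <- function(tally, k) {
  used <- which(tally@useCount > 0L)
  if (length(used) < k) return(NULL)
  avg <- (tally@cumImportance / tally@useCount)[used]
  ord <- used[order(-avg, used)]  # ties -> pool order
  tally@variables[ord[seq_len(k)]]
}

#' Execute one screening run
#'
#' Fits a model on exactly the given subset and returns its permutation
#' importance (summing to 100 over the subset). Runs are independent: the
#' result depends only on (subset, data, settings, runSeed), never on other
#' runs, which is what makes the ensemble embarrassingly parallel.
#'
#' @param subset character vector of variable names.
#' @param presenceX,backgroundX full predictor matrices (columns are
#'   subset from them).
#' @param settings [modelSettings()].
#' @param runSeed integer seed for the permutation-importance stream.
#' @return named importance vector over the subset, with the run's
#'   \code{baseline_auc} attribute.
#' @export
executeRun <- function(subset, presenceX, backgroundX,
                       settings = modelSettings(), runSeed = 1L) {
  if (!length(subset)) stop("subset must be non-empty")
  pX <- as.matrix(presenceX)[, subset, drop = FALSE]
  bX <- as.matrix(backgroundX)[, subset, drop = FALSE]
  s <- settings
  if (length(subset) < 2 && "P" %in% s$featureClasses) {
    s$featureClasses <- setdiff(s$featureClasses, "P")
    if (!length(s$featureClasses)) s$featureClasses <- "L"
  }
  m <- suppressWarnings(maxentFit(pX, bX, s))
  imp <- permutationImportance(m, pX, bX, seed = runSeed)
  if (length(subset) == 1L) imp[subset] <- 100  # degenerate normalization
  imp[subset]
}

# Seed a run's subset draw: independent stream keyed on (master, index).
drawRunSubset <- function(config, runIndex) {
  withLocalSeed(deriveRunSeed(config$masterSeed, runIndex),
                drawSubset(config$pool, config$kPerRun))
}

#' Run one sprint of a screening ensemble
#'
#' Executes \code{runsPerSprint} independent runs (their subsets and seeds
#' derived from the master seed and global run indices), applies their
#' importances to the tally in run-index order, then fits the sprint-end
#' model on the current top-k variables and records its AICc and training
#' AUC. While fewer than top-k variables have been used, the sprint-end
#' model is deferred.
#'
#' @param config a [screenConfig()].
#' @param data list with elements \code{presenceX} and \code{backgroundX}.
#' @param sprintIndex 1-based sprint number.
#' @param tally the current [TallyTable-class].
#' @param workers parallel workers for the runs (results are identical for
#'   any worker count; requires the parallel package when > 1).
#' @param dryRun if TRUE, only subset draws are performed (use counts
#'   update; importances and models are skipped).
#' @return list with \code{record} (the sprint record) and \code{tally}.
#' @export
runSprint <- function(config, data, sprintIndex, tally, workers = 1L,
                      dryRun = FALSE) {
  rps <- config$runsPerSprint
  runIdx <- (sprintIndex - 1L) * rps + seq_len(rps)
  subsets <- lapply(runIdx, function(i) drawRunSubset(config, i))
  if (dryRun) {
    imps <- lapply(subsets, function(s) stats::setNames(numeric(length(s)), s))
  } else {
    runOne <- function(j) {
      tryCatch(
        executeRun(subsets[[j]], data$presenceX, data$backgroundX,
                   config$settings,
                   runSeed = deriveRunSeed(config$masterSeed, runIdx[j])),
        error = function(e) structure(list(message = conditionMessage(e)),
                                      class = "runFailure"))
    }
    imps <- if (workers > 1L &&
                requireNamespace("parallel", quietly = TRUE)) {
      parallel::mclapply(seq_len(rps), runOne, mc.cores = workers)
    } else {
      lapply(seq_len(rps), runOne)
    }
  }
  failed <- vapply(imps, inherits, logical(1), "runFailure")
  if (all(failed) && !dryRun)
    stop("sprint error: every run in sprint ", sprintIndex, " failed")
  # tally updates applied in run-index order for deterministic logs
  for (j in which(!failed)) tally <- updateTally(tally, imps[[j]])
  topk <- topVariables(tally, config$topK)
  endModel <- NULL
  aicc <- auc <- NA_real_
  if (!dryRun && !is.null(topk)) {
    pX <- as.matrix(data$presenceX)[, topk, drop = FALSE]
    bX <- as.matrix(data$backgroundX)[, topk, drop = FALSE]
    endModel <- suppressWarnings(maxentFit(pX, bX, config$settings))
    aicc <- as.numeric(suppressWarnings(aiccScore(endModel, pX)))
    auc <- aucScore(maxentEta(endModel, pX), endModel@bgEta)
  }
  record <- list(sprint = sprintIndex, runs = runIdx, subsets = subsets,
                 importances = imps[!failed], nFailed = sum(failed),
                 tally = as.data.frame(tally), topK = topk,
                 aicc = aicc, auc = auc, model = endModel)
  list(record = record, tally = tally)
}

#' Run a full Monte Carlo screening ensemble
#'
#' Executes \code{nSprints} sprints of \code{runsPerSprint} independent
#' runs each. Every run fits a model on a fresh random k-variable subset
#' and its permutation importance accrues in the tally; sprint-end models
#' on the running top-k variables trace the convergence of the selection.
#'
#' @param config a [screenConfig()].
#' @param data list with \code{presenceX} and \code{backgroundX} matrices
#'   whose columns cover \code{config$pool}.
#' @param workers parallel workers per sprint (identical results for any
#'   value).
#' @param dryRun draw subsets and update use counts only; no models are
#'   fitted (used for sampling-design accounting).
#' @return an [EnsembleResult-class].
#' @export
runEnsemble <- function(config, data = NULL, workers = 1L, dryRun = FALSE) {
  if (!dryRun) {
    stopifnot(is.list(data))
    missing <- setdiff(config$pool, colnames(data$presenceX))
    if (length(missing))
      stop("schema error: pool variable(s) absent from data: ",
           paste(missing, collapse = ", "))
  }
  tally <- newTally(config$pool)
  records <- vector("list", config$nSprints)
  checkpoints <- list()
  executed <- 0L
  for (s in seq_len(config$nSprints)) {
    step <- runSprint(config, data, s, tally, workers = workers,
                      dryRun = dryRun)
    tally <- step$tally
    rec <- step$record
    if (s %in% config$checkpoints) {
      checkpoints[[paste0("sprint", s)]] <-
        list(sprint = s, topK = rec$topK, aicc = rec$aicc, auc = rec$auc,
             model = rec$model,
             meanUseCount = mean(useCount(tally)))
      rec$model <- NULL  # keep per-sprint records light
    } else rec$model <- NULL
    records[[s]] <- rec
    executed <- executed + config$runsPerSprint
    if (!is.null(config$stopAfterStable) && s >= config$stopAfterStable) {
      recent <- lapply(records[(s - config$stopAfterStable + 1L):s],
                       `[[`, "topK")
      if (!any(vapply(recent, is.null, logical(1))) &&
          all(vapply(recent, setequal, logical(1), recent[[1]]))) {
        records <- records[seq_len(s)]
        break
      }
    }
  }
  records <- records[!vapply(records, is.null, logical(1))]
  sSet <- stabilitySprint(records, "set")
  sOrd <- stabilitySprint(records, "order")
  final <- records[[length(records)]]$topK
  new("EnsembleResult", sprints = records, tally = tally,
      finalTopK = if (is.null(final)) character() else final,
      stabilitySet = if (is.null(sSet)) NA_real_ else sSet,
      stabilityOrder = if (is.null(sOrd)) NA_real_ else sOrd,
      checkpoints = checkpoints, totalRuns = executed,
      config = unclass(config), dryRun = dryRun)
}

#' @rdname EnsembleResult-accessors
#' @export
setMethod("sprintRecords", "EnsembleResult", function(x) x@sprints)
#' @rdname EnsembleResult-accessors
#' @export
setMethod("finalTopK", "EnsembleResult", function(x) x@finalTopK)
#' @rdname EnsembleResult-accessors
#' @export
setMethod("tallyOf", "EnsembleResult", function(x) x@tally)
#' @rdname EnsembleResult-accessors
#' @export
setMethod("totalRuns", "EnsembleResult", function(x) x@totalRuns)

setMethod("show", "EnsembleResult", function(object) {
  cfg <- object@config
  cat("EnsembleResult:", length(object@sprints), "sprints x",
      cfg$runsPerSprint, "runs (", object@totalRuns, "runs,",
      if (object@dryRun) "dry-run )\n" else ")\n")
  cat("  pool:", length(cfg$pool), "variables, k per run:", cfg$kPerRun, "\n")
  if (length(object@finalTopK))
    cat("  final top", cfg$topK, ":",
        paste(object@finalTopK, collapse = ", "), "\n")
  cat("  stability sprint (set/order):", object@stabilitySet, "/",
      object@stabilityOrder, "\n")
})

#' Earliest sprint from which the top-k selection never changes
#'
#' @param records list of sprint records (from [sprintRecords()]).
#' @param mode \code{"set"} (membership only) or \code{"order"} (full rank
#'   order).
#' @return the 1-based sprint index, or \code{NULL} if the selection still
#'   changes in the final sprint (or was never available).
#' @export
stabilitySprint <- function(records, mode = c("set", "order")) {
  mode <- match.arg(mode)
  if (!length(records)) stop("at least one sprint record is required")
  tops <- lapply(records, `[[`, "topK")
  last <- tops[[length(tops)]]
  if (is.null(last)) return(NULL)
  same <- vapply(tops, function(t) {
    if (is.null(t)) return(FALSE)
    if (mode == "set") setequal(t, last) else identical(t, last)
  }, logical(1))
  # longest all-TRUE suffix; a selection that changed in the final sprint
  # (suffix of length one) does not count as stable
  if (!same[length(same)]) return(NULL)
  idx <- which(!same)
  s <- if (!length(idx)) 1L else max(idx) + 1L
  if (length(same) > 1L && s == length(same)) return(NULL)
  s
}

#' Write a sprint log as CSV
#'
#' One row per sprint: membership of each pool variable in that sprint's
#' top-k (1/0), plus the sprint-end model's AICc and training AUC —
#' the tabular equivalent of the usual sprint-log figure.
#'
#' @param result an [EnsembleResult-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeSprintLog <- function(result, path) {
  cfg <- result@config
  rows <- lapply(result@sprints, function(r) {
    member <- as.integer(cfg$pool %in% (r$topK %||% character()))
    df <- data.frame(sprint = r$sprint, t(member))
    names(df) <- c("sprint", cfg$pool)
    df$aicc <- r$aicc
    df$auc <- r$auc
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a tally table as CSV
#'
#' @param tally a [TallyTable-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeTally <- function(tally, path) {
  utils::write.csv(as.data.frame(tally), path, row.names = FALSE)
  invisible(path)
}
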