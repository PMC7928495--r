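# Feature-class expansion for the maximum-entropy engine.
#
# Raw predictors are mapped to [0,1] per variable (min/max over the supplied
# data, or a stored scaling at prediction time) and then expanded into the
# classical MaxEnt feature classes: linear (L), quadratic (Q), product (P),
# hinge (H, forward and reverse) and threshold (T).

#' Model settings for the maximum-entropy engine
#'
#' @param featureClasses string over the alphabet L, Q, H, P, T (e.g.
#'   \code{"LQHP"}, the historical MaxEnt default for large samples).
#' @param rm positive regularization multiplier scaling all per-feature L1
#'   penalties (default 1.0).
#' @param hingeKnots,thresholdKnots number of knots per variable for hinge
#'   and threshold features (default 50 each; a hinge variable contributes
#'   \code{2 * hingeKnots} columns, forward plus reverse).
#' @param maxIterations optimizer iteration cap.
#' @param tolerance convergence tolerance on the penalized objective.
#' @param betaTables optional override of the per-class base-penalty
#'   interpolation tables; see Details.
#' @details Per-feature penalties follow the published MaxEnt defaults:
#'   for feature j, \code{beta_j = rm * classBeta(np) * sd_j / sqrt(np)}
#'   where np is the presence sample size, sd_j the feature's standard
#'   deviation over the presences (floored at 0.001 on the [0,1] feature
#'   scale), and \code{classBeta} interpolates a per-class table against np:
#'   L/Q/P use samples (0, 10, 30, 100) -> (1, 1, 0.2, 0.05); hinge is the
#'   constant 0.5; threshold uses (0, 100) -> (2, 1). The tables are
#'   settings, not constants, so alternative conventions can be supplied.
#' @return a validated settings list of class \code{"ModelSettings"}.
#' @export
modelSettings <- function(featureClasses = "LQHP", rm = 1.0,
                          hingeKnots = 50L, thresholdKnots = 50L,
                          maxIterations = 3000L, tolerance = 1e-7,
                          betaTables = NULL) {
  fc <- sort(unique(strsplit(toupper(featureClasses), "")[[1]]))
  if (!length(fc) || !all(fc %in% c("L", "Q", "H", "P", "T")))
    stop("featureClasses must be a non-empty subset of L, Q, H, P, T")
  if (rm <= 0) stop("regularization multiplier must be positive")
  if (is.null(betaTables))
    betaTables <- list(
      LQP = list(samples = c(0, 10, 30, 100), beta = c(1, 1, 0.2, 0.05)),
      H = list(samples = c(0, 1), beta = c(0.5, 0.5)),
      T = list(samples = c(0, 100), beta = c(2, 1)))
  structure(list(featureClasses = fc, rm = rm,
                 hingeKnots = as.integer(hingeKnots),
                 thresholdKnots = as.integer(thresholdKnots),
                 maxIterations = as.integer(maxIterations),
                 tolerance = tolerance, betaTables = betaTables),
            class = "ModelSettings")
}

# Piecewise-linear interpolation of a class beta table at sample size np;
# constant beyond the table ends.
interpBeta <- function(table, np) {
  stats::approx(table$samples, table$beta, xout = np, rule = 2)$y
}

#' Expand predictors into MaxEnt feature classes
#'
#' @param x numeric matrix (samples x variables) with column names.
#' @param settings a [modelSettings()] list.
#' @param scaling optional data.frame (\code{variable}, \code{min},
#'   \code{max}) from a previous expansion; when supplied, values are scaled
#'   with it and clamped to [0, 1] (the MaxEnt clamping convention for
#'   projection outside the training range).
#' @return list of class \code{"FeatureExpansion"}: \code{design} (numeric
#'   matrix), \code{meta} (data.frame: \code{feature}, \code{class},
#'   \code{var1}, \code{var2}, \code{knot}), \code{scaling}.
#' @export
expandFeatures <- function(x, settings = modelSettings(), scaling = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("predictor columns must be named")
  vars <- colnames(x)
  fc <- settings$featureClasses
  if ("P" %in% fc && length(vars) < 2)
    stop("configuration error: product features need at least two variables")
  if (is.null(scaling)) {
    scaling <- data.frame(variable = vars,
                          min = apply(x, 2, min, na.rm = TRUE),
                          max = apply(x, 2, max, na.rm = TRUE))
  }
  z <- x
  for (j in seq_along(vars)) {
    s <- scaling[scaling$variable == vars[j], ]
    if (nrow(s) != 1) stop("schema error: no scaling for variable ", vars[j])
    rng <- s$max - s$min
    z[, j] <- if (rng > 0) pmin(pmax((x[, j] - s$min) / rng, 0), 1) else 0
  }
  cols <- list()
  meta <- list()
  addCol <- function(v, name, class, var1, var2 = NA_character_,
                     knot = NA_real_) {
    cols[[length(cols) + 1L]] <<- v
    meta[[length(meta) + 1L]] <<- data.frame(
      feature = name, class = class, var1 = var1, var2 = var2, knot = knot)
  }
  if ("L" %in% fc)
    for (j in seq_along(vars))
      addCol(z[, j], paste0("L_", vars[j]), "L", vars[j])
  if ("Q" %in% fc)
    for (j in seq_along(vars))
      addCol(z[, j]^2, paste0("Q_", vars[j]), "Q", vars[j])
  if ("P" %in% fc)
    for (j in seq_len(length(vars) - 1))
      for (k in (j + 1):length(vars))
        addCol(z[, j] * z[, k], paste0("P_", vars[j], "_", vars[k]), "P",
               vars[j], vars[k])
  if ("H" %in% fc) {
    nk <- settings$hingeKnots
    fknots <- seq(0, 1, length.out = nk + 1)[seq_len(nk)]
    rknots <- seq(0, 1, length.out = nk + 1)[-1]
    for (j in seq_along(vars)) {
      for (t in fknots)
        addCol(pmax(0, (z[, j] - t) / (1 - t)),
               sprintf("Hf_%s_%.6g", vars[j], t), "H", vars[j], knot = t)
      for (t in rknots)
        addCol(pmax(0, (t - z[, j]) / t),
               sprintf("Hr_%s_%.6g", vars[j], t), "H", vars[j], knot = -t)
    }
  }
  if ("T" %in% fc) {
    nk <- settings$thresholdKnots
    tknots <- seq(0, 1, length.out = nk + 2)[2:(nk + 1)]
    for (j in seq_along(vars))
      for (t in tknots)
        addCol(as.numeric(z[, j] > t),
               sprintf("T_%s_%.6g", vars[j], t), "T", vars[j], knot = t)
  }
  design <- do.call(cbind, cols)
  meta <- do.call(rbind, meta)
  colnames(design) <- meta$feature
  rownames(meta) <- NULL
  structure(list(design = design, meta = meta, scaling = scaling),
            class = "FeatureExpansion")
}
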