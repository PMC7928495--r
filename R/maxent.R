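# Penalized maximum-entropy (MaxEnt-style) presence-background engine.
#
# The model is the Gibbs distribution q(x) = exp(lambda . f(x)) / Z over the
# background sample, fitted by minimizing the penalized negative
# log-likelihood of the presences
#
#   J(lambda) = -mean_presence(lambda . f(x)) + log Z(lambda)
#               + sum_j beta_j |lambda_j|
#
# which is convex. The L1 term is handled exactly by splitting lambda into
# non-negative positive/negative parts and running bound-constrained
# L-BFGS-B on the smooth reformulation; coefficients at the bound come out
# exactly zero, giving genuine sparsity. The fit is deterministic (zero
# start, fixed tolerances); no randomness is involved.

#' @include features.R
NULL

# Per-feature penalty: rm * classBeta(np) * sd over presences / sqrt(np),
# with sd floored at 0.001 on the [0,1] feature scale.
featurePenalties <- function(designP, meta, settings) {
  np <- nrow(designP)
  bt <- settings$betaTables
  classBeta <- function(cl) {
    switch(cl,
           L = , Q = , P = interpBeta(bt$LQP, np),
           H = interpBeta(bt$H, np),
           T = interpBeta(bt$T, np))
  }
  base <- vapply(meta$class, classBeta, numeric(1))
  sds <- pmax(apply(designP, 2, stats::sd), 0.001)
  settings$rm * base * sds / sqrt(np)
}

#' Fit a penalized maximum-entropy model
#'
#' Maximizes the penalized log-likelihood of the Gibbs distribution
#' \eqn{p(x) \propto \exp(\lambda \cdot f(x))} over the background sample,
#' evaluated at the presence samples, with a per-feature L1 penalty equal to
#' the regularization multiplier times the class-dependent base penalty
#' (interpolated by presence sample size). Constant feature columns are
#' dropped with a warning. The optimization is deterministic; \code{seed}
#' is accepted for interface uniformity but unused by the default
#' zero-start optimizer.
#'
#' @param presenceX numeric matrix of predictor values at presences
#'   (>= 2 rows), columns named.
#' @param backgroundX matrix of predictor values at background points, same
#'   columns.
#' @param settings a [modelSettings()] list.
#' @param seed integer, unused by the deterministic fit (kept for API
#'   symmetry with the stochastic components).
#' @return a [MaxentModel-class].
#' @examples
#' set.seed(1)
#' bg <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("a", "b")))
#' pr <- matrix(rnorm(60, mean = 1), 30, 2, dimnames = list(NULL, c("a", "b")))
#' m <- maxentFit(pr, bg, modelSettings("LQ"))
#' sum(maxentPredict(m, bg, "raw"))  # 1 by construction
#' @export
maxentFit <- function(presenceX, backgroundX, settings = modelSettings(),
                      seed = NULL) {
  presenceX <- as.matrix(presenceX)
  backgroundX <- as.matrix(backgroundX)
  if (nrow(presenceX) < 2) stop("at least two presence samples are required")
  if (!identical(colnames(presenceX), colnames(backgroundX)))
    stop("schema error: presence and background columns must match")
  vars <- colnames(presenceX)
  # the Gibbs model's domain is the background sample: features are scaled
  # by the background range and presence values clamp into it, which keeps
  # the penalized objective coercive even under complete separation
  bgScaling <- data.frame(variable = vars,
                          min = apply(backgroundX, 2, min, na.rm = TRUE),
                          max = apply(backgroundX, 2, max, na.rm = TRUE))
  all <- rbind(presenceX, backgroundX)
  fx <- expandFeatures(all, settings, scaling = bgScaling)
  np <- nrow(presenceX)
  Fp <- fx$design[seq_len(np), , drop = FALSE]
  Fb <- fx$design[-seq_len(np), , drop = FALSE]
  keep <- apply(fx$design, 2, function(v) diff(range(v)) > 0)
  if (!any(keep)) {
    # no informative features: the fitted distribution is uniform
    nb <- nrow(Fb)
    lam <- stats::setNames(numeric(ncol(fx$design)), colnames(fx$design))
    return(new("MaxentModel", coefficients = lam, featureMeta = fx$meta,
               scaling = fx$scaling, logZ = log(nb), entropy = log(nb),
               bgEta = numeric(nb), settings = unclass(settings),
               variableNames = vars, converged = TRUE,
               objective = log(nb)))
  }
  if (!all(keep))
    warning("dropping ", sum(!keep), " constant feature column(s)")
  FpK <- Fp[, keep, drop = FALSE]
  FbK <- Fb[, keep, drop = FALSE]
  beta <- featurePenalties(FpK, fx$meta[keep, , drop = FALSE], settings)
  p <- ncol(FpK)
  fmeanP <- colMeans(FpK)
  nb <- nrow(FbK)

  objGrad <- function(uv) {
    lam <- uv[seq_len(p)] - uv[p + seq_len(p)]
    eta <- drop(FbK %*% lam)
    m <- max(eta)
    w <- exp(eta - m)
    sw <- sum(w)
    lz <- m + log(sw)
    q <- w / sw
    g <- -fmeanP + drop(crossprod(FbK, q))
    list(value = -sum(fmeanP * lam) + lz + sum(beta * (uv[seq_len(p)] +
                                                         uv[p + seq_len(p)])),
         grad = c(g + beta, -g + beta))
  }
  fn <- function(uv) objGrad(uv)$value
  gr <- function(uv) objGrad(uv)$grad
  opt <- stats::optim(rep(0, 2 * p), fn, gr, method = "L-BFGS-B",
                      lower = 0,
                      control = list(maxit = settings$maxIterations,
                                     factr = settings$tolerance /
                                       .Machine$double.eps / 100,
                                     pgtol = 1e-8))
  if (opt$convergence != 0 && opt$convergence != 52)
    stop("convergence error: optimizer stopped with code ", opt$convergence,
         " (", opt$message, ") after ", opt$counts[1], " evaluations")
  lamK <- opt$par[seq_len(p)] - opt$par[p + seq_len(p)]
  lamK[abs(lamK) < 1e-10] <- 0
  lam <- stats::setNames(numeric(ncol(fx$design)), colnames(fx$design))
  lam[keep] <- lamK
  eta <- drop(FbK %*% lamK)
  lz <- logSumExp(eta)
  raw <- exp(eta - lz)
  H <- -sum(raw * log(raw))
  new("MaxentModel", coefficients = lam, featureMeta = fx$meta,
      scaling = fx$scaling, logZ = lz, entropy = H, bgEta = eta,
      settings = unclass(settings), variableNames = vars,
      converged = opt$convergence == 0, objective = opt$value)
}

setMethod("show", "MaxentModel", function(object) {
  nz <- sum(object@coefficients != 0)
  cat("MaxentModel:", length(object@variableNames), "variable(s),",
      length(object@coefficients), "features,", nz, "nonzero coefficients\n")
  cat("  variables:", paste(object@variableNames, collapse = ", "), "\n")
  cat(sprintf("  entropy H = %.4f, feature classes %s, RM = %g\n",
              object@entropy,
              paste(object@settings$featureClasses, collapse = ""),
              object@settings$rm))
})

#' @describeIn maxentFit extract the named coefficient vector.
#' @param object a [MaxentModel-class].
#' @param ... unused.
#' @export
setMethod("coef", "MaxentModel", function(object, ...) object@coefficients)

#' Number of nonzero coefficients of a fitted model
#'
#' The parameter count K used by the information criteria.
#'
#' @param model a [MaxentModel-class].
#' @return integer count.
#' @export
nParams <- function(model) sum(model@coefficients != 0)

# Linear predictor lambda . f(x) for new data (matrix or EnvGrid cells).
maxentEta <- function(model, x) {
  x <- as.matrix(x)
  missing <- setdiff(model@variableNames, colnames(x))
  if (length(missing))
    stop("schema error: missing variable(s): ",
         paste(missing, collapse = ", "))
  x <- x[, model@variableNames, drop = FALSE]
  fx <- expandFeatures(x, settingsFromModel(model), scaling = model@scaling)
  drop(fx$design %*% model@coefficients)
}

settingsFromModel <- function(model) {
  s <- model@settings
  class(s) <- "ModelSettings"
  s
}

#' Predict suitability from a fitted model
#'
#' Raw output is the Gibbs density normalized over the training background
#' (it sums to 1 over the training background by construction). Logistic
#' output applies the historical MaxEnt transform
#' \eqn{\tau e^H r / (1 - \tau + \tau e^H r)} with \eqn{\tau = 0.5}, so the
#' no-information model maps to 0.5 everywhere and values lie in (0, 1).
#'
#' @param model a [MaxentModel-class].
#' @param x numeric matrix with the model's variables as columns, or an
#'   [EnvGrid-class] containing them as layers.
#' @param output \code{"raw"}, \code{"logistic"} or \code{"link"} (the
#'   linear predictor).
#' @param tau prevalence constant of the logistic transform.
#' @return numeric vector of predictions (for an [EnvGrid-class], a matrix
#'   shaped like the grid with \code{NA} at masked cells).
#' @export
maxentPredict <- function(model, x, output = c("logistic", "raw", "link"),
                          tau = 0.5) {
  output <- match.arg(output)
  if (is(x, "EnvGrid")) {
    d <- dim(x@values)
    valid <- which(x@mask)
    vm <- vapply(model@variableNames, function(nm) gridLayer(x, nm)[valid],
                 numeric(length(valid)))
    vm <- matrix(vm, ncol = length(model@variableNames),
                 dimnames = list(NULL, model@variableNames))
    pred <- maxentPredict(model, vm, output = output, tau = tau)
    out <- matrix(NA_real_, d[1], d[2])
    out[valid] <- pred
    return(out)
  }
  eta <- maxentEta(model, x)
  if (output == "link") return(eta)
  raw <- exp(eta - model@logZ)
  if (output == "raw") return(raw)
  s <- tau * exp(model@entropy) * raw
  s / (1 - tau + s)
}

#' k-fold cross-validation of a maximum-entropy model
#'
#' Presences are partitioned into \code{nReplicates} folds (seeded); each
#' replicate trains on the remaining folds against the full background and
#' reports test AUC on the held-out presences.
#'
#' @param presenceX,backgroundX predictor matrices as in [maxentFit()].
#' @param settings a [modelSettings()] list.
#' @param nReplicates number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return data.frame with one row per replicate (\code{replicate},
#'   \code{n_train}, \code{n_test}, \code{train_auc}, \code{test_auc}) and
#'   attributes \code{mean} and \code{sd} of the test AUC.
#' @export
crossValidate <- function(presenceX, backgroundX, settings = modelSettings(),
                          nReplicates = 10L, seed = 1L) {
  presenceX <- as.matrix(presenceX)
  np <- nrow(presenceX)
  if (nReplicates < 2) stop("at least two replicates are required")
  if (np < nReplicates)
    stop("partition error: fewer presences than folds")
  folds <- withLocalSeed(seed, sample(rep(seq_len(nReplicates),
                                          length.out = np)))
  rows <- lapply(seq_len(nReplicates), function(k) {
    test <- folds == k
    m <- maxentFit(presenceX[!test, , drop = FALSE], backgroundX, settings)
    bgEta <- m@bgEta
    data.frame(replicate = k, n_train = sum(!test), n_test = sum(test),
               train_auc = aucScore(maxentEta(m, presenceX[!test, , drop = FALSE]), bgEta),
               test_auc = aucScore(maxentEta(m, presenceX[test, , drop = FALSE]), bgEta))
  })
  out <- do.call(rbind, rows)
  attr(out, "mean") <- mean(out$test_auc)
  attr(out, "sd") <- stats::sd(out$test_auc)
  out
}

#' Scan feature-class and regularization-multiplier settings
#'
#' Fits one model per (feature-class set, RM) combination and reports AICc
#' and training AUC; the best row is the AICc minimum. The default grids
#' reproduce the conventional tuning scan: five nested feature-class sets
#' by RM from 0.5 to 4.0 in half steps (40 rows).
#'
#' @param presenceX,backgroundX predictor matrices as in [maxentFit()].
#' @param fcGrid character vector of feature-class strings.
#' @param rmGrid numeric vector of regularization multipliers.
#' @param settings base [modelSettings()] whose other fields (knots,
#'   tolerances) are reused across the scan.
#' @return data.frame with columns \code{fc}, \code{rm}, \code{K},
#'   \code{lnL}, \code{aicc}, \code{train_auc}, \code{best}; failed fits
#'   produce NA rows. Errors if every fit fails.
#' @export
tuneModel <- function(presenceX, backgroundX,
                      fcGrid = c("L", "LQ", "LQH", "LQHP", "LQHPT"),
                      rmGrid = seq(0.5, 4, by = 0.5),
                      settings = modelSettings()) {
  if (!length(fcGrid) || !length(rmGrid)) stop("grids must be non-empty")
  grid <- expand.grid(fc = fcGrid, rm = rmGrid, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- modelSettings(grid$fc[i], rm = grid$rm[i],
                       hingeKnots = settings$hingeKnots,
                       thresholdKnots = settings$thresholdKnots,
                       maxIterations = settings$maxIterations,
                       tolerance = settings$tolerance,
                       betaTables = settings$betaTables)
    tryCatch({
      m <- suppressWarnings(maxentFit(presenceX, backgroundX, s))
      ic <- aiccScore(m, presenceX)
      data.frame(fc = grid$fc[i], rm = grid$rm[i], K = nParams(m),
                 lnL = attr(ic, "lnL"), aicc = as.numeric(ic),
                 train_auc = aucScore(maxentEta(m, presenceX), m@bgEta))
    }, error = function(e)
      data.frame(fc = grid$fc[i], rm = grid$rm[i], K = NA_integer_,
                 lnL = NA_real_, aicc = NA_real_, train_auc = NA_real_))
  })
  out <- do.call(rbind, rows)
  if (all(is.na(out$aicc))) stop("scan error: every fit failed")
  out$best <- !is.na(out$aicc) & out$aicc == min(out$aicc, na.rm = TRUE)
  out
}

#' Serialize a fitted model to JSON
#'
#' Writes coefficients, feature metadata, scaling, normalizer, entropy and
#' settings so the model can be reloaded and used for prediction without the
#' training data.
#'
#' @param model a [MaxentModel-class].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
modelToJson <- function(model, path) {
  obj <- list(
    coefficients = as.list(model@coefficients),
    featureMeta = model@featureMeta,
    scaling = model@scaling,
    logZ = model@logZ, entropy = model@entropy, bgEta = model@bgEta,
    settings = model@settings[setdiff(names(model@settings), "betaTables")],
    betaTables = model@settings$betaTables,
    variableNames = model@variableNames,
    converged = model@converged, objective = model@objective)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model serialized by [modelToJson()]
#'
#' @param path JSON path.
#' @return a [MaxentModel-class].
#' @export
modelFromJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  settings <- c(obj$settings, list(betaTables = obj$betaTables))
  new("MaxentModel",
      coefficients = unlist(obj$coefficients),
      featureMeta = as.data.frame(obj$featureMeta),
      scaling = as.data.frame(obj$scaling),
      logZ = obj$logZ, entropy = obj$entropy, bgEta = as.numeric(obj$bgEta),
      settings = settings, variableNames = obj$variableNames,
      converged = obj$converged, objective = obj$objective)
}
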