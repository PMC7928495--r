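# Synthetic landscapes with known ground truth.
#
# Emulates the real-data inputs of a screening study: a stack of spatially
# smooth, cross-correlated continuous environmental layers; a true
# suitability surface driven by a known subset of layers; presence points
# sampled proportionally to suitability. Every output is consumable by the
# rest of the package through the same containers and file formats as real
# data.

#' Describe a synthetic screening scenario
#'
#' @param gridShape \code{c(rows, cols)} of the landscape.
#' @param nLayers number of environmental layers (named
#'   \code{env01, env02, ...}).
#' @param smoothness spatial correlation length in cells of the Gaussian
#'   random fields (Gaussian kernel standard deviation).
#' @param crossCorrelation target inter-layer correlation: a symmetric
#'   positive semi-definite matrix with unit diagonal, a single scalar
#'   (exchangeable correlation), or NULL for independent layers.
#' @param trueVariables layer names that drive suitability.
#' @param trueCoefficients list with numeric vectors \code{linear} and
#'   optionally \code{quadratic}, one entry per true variable (applied to
#'   the standardized layer).
#' @param nPresences number of presence points to sample.
#' @param nodataFraction fraction of cells masked as nodata (shared across
#'   layers; default 0).
#' @param jitter if TRUE, presence coordinates are jittered uniformly
#'   within their cell instead of sitting at cell centres.
#' @param seed integer seed governing the landscape and the presences.
#' @return validated list of class \code{"SyntheticScenario"}.
#' @export
syntheticScenario <- function(gridShape = c(60, 60), nLayers = 12,
                              smoothness = 3, crossCorrelation = NULL,
                              trueVariables = c("env01", "env02", "env03"),
                              trueCoefficients = list(
                                linear = c(2, -2, 2),
                                quadratic = c(-2, -2, -2)),
                              nPresences = 150, nodataFraction = 0,
                              jitter = FALSE, seed = 1L) {
  layers <- sprintf("env%02d", seq_len(nLayers))
  if (!all(trueVariables %in% layers))
    stop("trueVariables must be a subset of the generated layers")
  C <- crossCorrelation
  if (is.null(C)) C <- diag(nLayers)
  if (length(C) == 1L && is.numeric(C) && !is.matrix(C)) {
    rho <- C
    C <- matrix(rho, nLayers, nLayers)
    diag(C) <- 1
  }
  if (!isSymmetric(unname(C)) || any(abs(diag(C) - 1) > 1e-12))
    stop("crossCorrelation must be symmetric with unit diagonal")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("decomposition error: crossCorrelation is not positive semi-definite")
  lin <- trueCoefficients$linear
  qua <- trueCoefficients$quadratic
  if (is.null(qua)) qua <- numeric(length(trueVariables))
  if (length(lin) != length(trueVariables) ||
      length(qua) != length(trueVariables))
    stop("one linear (and optional quadratic) coefficient per true variable")
  structure(list(gridShape = as.integer(gridShape), nLayers = as.integer(nLayers),
                 layers = layers, smoothness = smoothness,
                 crossCorrelation = C, trueVariables = trueVariables,
                 linear = lin, quadratic = qua,
                 nPresences = as.integer(nPresences),
                 nodataFraction = nodataFraction, jitter = isTRUE(jitter),
                 seed = as.integer(seed)),
            class = "SyntheticScenario")
}

# Smooth a white-noise field with a Gaussian kernel by circular (FFT)
# convolution; circularity keeps the field stationary with no edge decay.
smoothField <- function(noise, len) {
  if (len <= 0) return(noise)
  nr <- nrow(noise); nc <- ncol(noise)
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  kern <- exp(-outer(dr^2, dc^2, "+") / (2 * len^2))
  sm <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) /
    (nr * nc)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Generate the synthetic environmental layer stack
#'
#' Gaussian random fields built by Gaussian-kernel smoothing of white noise
#' at the scenario's correlation length, standardized, then linearly mixed
#' (Cholesky of the target correlation, with an eigenvalue fallback for
#' semi-definite targets) so the inter-layer correlations approach the
#' target. Reproducible per scenario seed.
#'
#' @param scenario a [syntheticScenario()].
#' @return an [EnvGrid-class] with layers \code{env01..}.
#' @export
genLandscape <- function(scenario) {
  stopifnot(inherits(scenario, "SyntheticScenario"))
  d <- scenario$gridShape
  n <- scenario$nLayers
  withLocalSeed(scenario$seed, {
    fields <- lapply(seq_len(n), function(i)
      smoothField(matrix(stats::rnorm(prod(d)), d[1], d[2]),
                  scenario$smoothness))
    Fm <- vapply(fields, as.numeric, numeric(prod(d)))
    C <- scenario$crossCorrelation
    L <- tryCatch(chol(C), error = function(e) {
      eg <- eigen(C, symmetric = TRUE)
      t(eg$vectors %*% diag(sqrt(pmax(eg$values, 0))))
    })
    mixed <- Fm %*% L
    layers <- lapply(seq_len(n), function(i) matrix(mixed[, i], d[1], d[2]))
    names(layers) <- scenario$layers
    if (scenario$nodataFraction > 0) {
      bad <- sample(prod(d), round(scenario$nodataFraction * prod(d)))
      for (i in seq_len(n)) layers[[i]][bad] <- NA_real_
    }
    envGrid(layers, xll = 0, yll = 0, cellSize = 0.1)
  })
}

#' True suitability surface of a scenario
#'
#' Inverse-logit of the stated linear (plus optional quadratic) combination
#' of the standardized true layers; masked cells stay \code{NA}.
#'
#' @param grid the landscape [EnvGrid-class].
#' @param trueVariables layer names driving suitability.
#' @param linear,quadratic coefficient vectors (one per true variable).
#' @return a one-layer [EnvGrid-class] (layer \code{"suitability"}) with
#'   values in (0, 1).
#' @export
genSuitability <- function(grid, trueVariables, linear,
                           quadratic = numeric(length(trueVariables))) {
  stopifnot(is(grid, "EnvGrid"))
  missing <- setdiff(trueVariables, layerNames(grid))
  if (length(missing))
    stop("schema error: unknown variable(s): ", paste(missing, collapse = ", "))
  d <- dim(grid@values)
  eta <- matrix(0, d[1], d[2])
  for (i in seq_along(trueVariables)) {
    v <- gridLayer(grid, trueVariables[i])
    z <- (v - mean(v, na.rm = TRUE)) / stats::sd(as.numeric(v), na.rm = TRUE)
    eta <- eta + linear[i] * z + quadratic[i] * z^2
  }
  suit <- stats::plogis(eta)
  suit[!grid@mask] <- NA_real_
  envGrid(list(suitability = suit), xll = grid@xll, yll = grid@yll,
          cellSize = grid@cellSize, crs = grid@crs)
}

#' Convenience: suitability surface straight from a scenario
#'
#' @param scenario a [syntheticScenario()].
#' @param grid the landscape generated from it.
#' @return a one-layer suitability [EnvGrid-class].
#' @export
scenarioSuitability <- function(scenario, grid) {
  genSuitability(grid, scenario$trueVariables, scenario$linear,
                 scenario$quadratic)
}

#' Sample presence records proportionally to suitability
#'
#' Valid cells are drawn without replacement with probability proportional
#' to suitability; coordinates sit at cell centres (or jittered uniformly
#' within the cell). Presences never fall on nodata cells.
#'
#' @param suitGrid one-layer suitability [EnvGrid-class] (or any grid whose
#'   first layer is the sampling weight).
#' @param n number of presences.
#' @param seed integer seed.
#' @param jitter jitter coordinates uniformly within cells.
#' @return occurrence data.frame with \code{lon}, \code{lat}.
#' @export
samplePresences <- function(suitGrid, n, seed = 1L, jitter = FALSE) {
  stopifnot(is(suitGrid, "EnvGrid"), n >= 1)
  w <- suitGrid@values[, , 1]
  valid <- which(suitGrid@mask & !is.na(w) & w > 0)
  if (n > length(valid))
    stop("capacity error: requested ", n, " presences but only ",
         length(valid), " positive-suitability cells")
  d <- dim(suitGrid@values)
  withLocalSeed(seed, {
    pick <- valid[sample.int(length(valid), n, prob = w[valid])]
    row <- (pick - 1L) %% d[1] + 1L
    col <- (pick - 1L) %/% d[1] + 1L
    xy <- cellCenter(suitGrid, row, col)
    if (jitter) {
      cs <- suitGrid@cellSize
      xy[, 1] <- xy[, 1] + stats::runif(n, -cs / 2, cs / 2)
      xy[, 2] <- xy[, 2] + stats::runif(n, -cs / 2, cs / 2)
    }
    data.frame(lon = xy[, 1], lat = xy[, 2])
  })
}

#' Recovery experiment: can screening find the true variables?
#'
#' Runs the full pipeline (landscape, suitability, presences, background,
#' Monte Carlo screening) \code{nReplicates} times with replicate-derived
#' seeds and reports, for each true variable, the fraction of replicates in
#' which it lands in the final top-k, plus the mean stability sprint.
#'
#' @param scenario a [syntheticScenario()].
#' @param config a [screenConfig()] over the scenario's layers.
#' @param nReplicates number of independent replicates.
#' @param seed integer seed from which replicate seeds are derived.
#' @param nBackground background points per replicate (default 1000).
#' @return list with \code{inclusion} (named fractions over the true
#'   variables), \code{topKsets} (per-replicate final top-k),
#'   \code{meanStability}, and \code{results} (the ensemble objects).
#' @export
recoveryExperiment <- function(scenario, config, nReplicates = 5, seed = 1L,
                               nBackground = 1000) {
  reps <- lapply(seq_len(nReplicates), function(r) {
    sc <- scenario
    sc$seed <- deriveRunSeed(seed, r)
    grid <- genLandscape(sc)
    suit <- scenarioSuitability(sc, grid)
    pres <- samplePresences(suit, sc$nPresences,
                            seed = deriveRunSeed(seed, 10000 + r))
    bg <- sampleBackground(grid, n = min(nBackground, sum(gridMask(grid))),
                           seed = deriveRunSeed(seed, 20000 + r))
    cfg <- config
    cfg$masterSeed <- deriveRunSeed(seed, 30000 + r)
    data <- list(presenceX = gridExtract(grid, pres),
                 backgroundX = gridExtract(grid, bg))
    runEnsemble(cfg, data)
  })
  tops <- lapply(reps, finalTopK)
  inclusion <- vapply(scenario$trueVariables, function(v)
    mean(vapply(tops, function(t) v %in% t, logical(1))), numeric(1))
  stab <- vapply(reps, function(r) r@stabilitySet, numeric(1))
  list(inclusion = inclusion, topKsets = tops,
       meanStability = mean(stab, na.rm = TRUE), results = reps)
}
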