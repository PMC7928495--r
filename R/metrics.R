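# Model-evaluation statistics: AUC, permutation importance, AICc and
# niche-overlap (Schoener's D, Warren's I).

#' Rank-based AUC
#'
#' Mann-Whitney form of the area under the ROC curve for presence versus
#' background scores; ties count one half.
#'
#' @param presenceScores,backgroundScores numeric score vectors (any
#'   monotone transform of suitability gives the same value).
#' @return AUC in [0, 1].
#' @examples
#' aucScore(c(0.9, 0.8), c(0.1, 0.2))  # 1
#' @export
aucScore <- function(presenceScores, backgroundScores) {
  np <- length(presenceScores)
  nb <- length(backgroundScores)
  if (!np || !nb) stop("both score vectors must be non-empty")
  r <- rank(c(presenceScores, backgroundScores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Permutation importance of model variables
#'
#' For each variable the model uses, its values are permuted jointly across
#' the presence and background rows, the training AUC is recomputed with
#' the unchanged model, and the drop from the baseline AUC (floored at zero)
#' is recorded; drops are averaged over \code{nPermutations} and normalized
#' to percentages summing to 100. Variables present in the data but absent
#' from the model get 0.
#'
#' @param model a [MaxentModel-class].
#' @param presenceX,backgroundX predictor matrices covering the model's
#'   variables (extra columns allowed).
#' @param seed integer seed for the permutation stream.
#' @param nPermutations permutations per variable (default 1, the
#'   historical convention; larger values reduce Monte Carlo noise).
#' @return named numeric vector of percentages over
#'   \code{union(model variables, data columns)}; attribute
#'   \code{baseline_auc} carries the unpermuted training AUC.
#' @export
permutationImportance <- function(model, presenceX, backgroundX, seed = 1L,
                                  nPermutations = 1L) {
  if (!length(model@variableNames))
    stop("undefined-importance error: model has no variables")
  presenceX <- as.matrix(presenceX)
  backgroundX <- as.matrix(backgroundX)
  np <- nrow(presenceX)
  allX <- rbind(presenceX[, model@variableNames, drop = FALSE],
                backgroundX[, model@variableNames, drop = FALSE])
  eta <- maxentEta(model, allX)
  base <- aucScore(eta[seq_len(np)], eta[-seq_len(np)])
  drops <- withLocalSeed(seed, {
    vapply(model@variableNames, function(v) {
      mean(vapply(seq_len(nPermutations), function(i) {
        xp <- allX
        xp[, v] <- xp[sample(nrow(xp)), v]
        e <- maxentEta(model, xp)
        max(0, base - aucScore(e[seq_len(np)], e[-seq_len(np)]))
      }, numeric(1)))
    }, numeric(1))
  })
  allVars <- union(model@variableNames, colnames(presenceX))
  imp <- stats::setNames(numeric(length(allVars)), allVars)
  tot <- sum(drops)
  imp[model@variableNames] <- if (tot > 0) 100 * drops / tot else 0
  attr(imp, "baseline_auc") <- base
  imp
}

#' AICc from log-likelihood, parameter count and sample size
#'
#' \eqn{AICc = 2K - 2\ln L + 2K(K+1)/(n - K - 1)}. Undefined (NA, with a
#' warning) when \eqn{n \le K + 1}, the usual model-selection convention.
#'
#' @param lnL log-likelihood.
#' @param K number of (nonzero) parameters.
#' @param n sample size.
#' @return the AICc value, or NA.
#' @examples
#' aiccFromLogLik(-20, 3, 10)  # 50
#' @export
aiccFromLogLik <- function(lnL, K, n) {
  if (n <= K + 1) {
    warning("AICc undefined: n <= K + 1")
    return(NA_real_)
  }
  2 * K - 2 * lnL + 2 * K * (K + 1) / (n - K - 1)
}

#' AICc of a fitted maximum-entropy model
#'
#' The likelihood of each presence is the model's raw output renormalized to
#' sum to one over the evaluation extent (the union of presence and
#' background samples by default, the standard information-criterion usage
#' in niche modelling; pass \code{backgroundX = NULL} and
#' \code{extent = "background"} to restrict to the stored training
#' background). K counts nonzero coefficients.
#'
#' @param model a [MaxentModel-class].
#' @param presenceX presence predictor matrix.
#' @param backgroundX background predictor matrix; when NULL the linear
#'   predictor stored from training is reused.
#' @param extent \code{"union"} (presences + background) or
#'   \code{"background"}.
#' @return AICc value (NA when undefined) with attributes \code{lnL} and
#'   \code{K}.
#' @export
aiccScore <- function(model, presenceX, backgroundX = NULL,
                      extent = c("union", "background")) {
  extent <- match.arg(extent)
  presenceX <- as.matrix(presenceX)
  etaP <- maxentEta(model, presenceX[, model@variableNames, drop = FALSE])
  etaB <- if (is.null(backgroundX)) model@bgEta
          else maxentEta(model, as.matrix(backgroundX)[, model@variableNames,
                                                       drop = FALSE])
  lzEval <- if (extent == "union") logSumExp(c(etaP, etaB)) else logSumExp(etaB)
  lnL <- sum(etaP - lzEval)
  K <- nParams(model)
  n <- nrow(presenceX)
  out <- aiccFromLogLik(lnL, K, n)
  attr(out, "lnL") <- lnL
  attr(out, "K") <- K
  out
}

#' Niche overlap between two suitability maps
#'
#' Both maps are normalized to sum to one over their shared valid cells,
#' then compared with Schoener's \eqn{D = 1 - \frac{1}{2}\sum |p_1 - p_2|}
#' and Warren's Hellinger-based
#' \eqn{I = 1 - \frac{1}{2}\sum (\sqrt{p_1} - \sqrt{p_2})^2}. Both lie in
#' [0, 1], are symmetric, and equal 1 for identical maps.
#'
#' @param map1,map2 numeric matrices or vectors of non-negative suitability
#'   values on the same grid; \code{NA} marks masked cells and the masks
#'   must agree.
#' @return named numeric vector \code{c(D = , I = )}.
#' @examples
#' nicheOverlap(c(0.5, 0.5), c(1, 0))  # D = 0.5, I = 1 - (1 - sqrt(0.5))
#' @export
nicheOverlap <- function(map1, map2) {
  v1 <- as.numeric(map1)
  v2 <- as.numeric(map2)
  if (length(v1) != length(v2))
    stop("alignment error: maps differ in size")
  ok1 <- !is.na(v1)
  if (!identical(ok1, !is.na(v2)))
    stop("alignment error: maps have different masks")
  v1 <- v1[ok1]; v2 <- v2[ok1]
  if (any(v1 < 0) || any(v2 < 0)) stop("suitability values must be >= 0")
  s1 <- sum(v1); s2 <- sum(v2)
  if (s1 == 0 || s2 == 0) stop("normalization error: all-zero map")
  p1 <- v1 / s1; p2 <- v2 / s2
  c(D = 1 - sum(abs(p1 - p2)) / 2,
    I = 1 - sum((sqrt(p1) - sqrt(p2))^2) / 2)
}

#' Pairwise niche-overlap matrices for a set of maps
#'
#' @param maps named list of suitability maps on a shared grid.
#' @return list with symmetric matrices \code{D} and \code{I} (unit
#'   diagonal).
#' @export
similarityMatrix <- function(maps) {
  if (length(maps) < 2) stop("at least two maps are required")
  n <- length(maps)
  nms <- names(maps)
  if (is.null(nms)) nms <- paste0("map", seq_len(n))
  D <- I <- matrix(1, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    o <- nicheOverlap(maps[[i]], maps[[j]])
    D[i, j] <- D[j, i] <- o["D"]
    I[i, j] <- I[j, i] <- o["I"]
  }
  list(D = D, I = I)
}

#' Write similarity matrices as CSV (upper-triangular layout)
#'
#' @param sim output of [similarityMatrix()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeSimilarityCsv <- function(sim, path) {
  fmt <- function(m, label) {
    up <- format(round(m, 4))
    up[lower.tri(up)] <- "x"
    df <- data.frame(MODELS = rownames(m), up, check.names = FALSE)
    rbind(stats::setNames(data.frame(t(c(label, rep("", ncol(df) - 1)))),
                          names(df)), df)
  }
  out <- rbind(fmt(sim$D, "Schoener's D"), fmt(sim$I, "Warren's I"))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
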