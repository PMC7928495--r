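# Internal utilities: seed handling and numerics.

# Evaluate `expr` under `set.seed(seed)` without disturbing the caller's RNG
# state. All randomized operations in the package route through this so a
# single integer seed makes any call reproducible.
withLocalSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-run seed from a master seed and run index
#'
#' Each Monte Carlo run is seeded independently from the ensemble's master
#' seed and its global run index, so runs can execute in any order (or in
#' parallel) and still reproduce bit-identical results. The derivation is a
#' fixed multiplicative hash kept below 2^31.
#'
#' @param masterSeed integer master seed.
#' @param runIndex 1-based global run index.
#' @return an integer seed.
#' @export
deriveRunSeed <- function(masterSeed, runIndex) {
  m <- as.double(masterSeed) %% 2147483647
  h <- (m * 48271) %% 2147483647
  as.integer((h + as.double(runIndex) * 104729) %% 2147483647)
}

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Exact binomial coefficient
#'
#' Number of distinct k-variable subsets of an n-variable pool, the size of
#' the combinatorial space the Monte Carlo screen samples. Computed by the
#' exact multiplicative scheme (every intermediate value is an integer).
#'
#' @param n pool size (>= 0).
#' @param k subset size, \code{0 <= k <= n}.
#' @return the exact integer value (as a double; exact up to 2^53).
#' @examples
#' subsetCount(19, 6)  # 27132
#' @export
subsetCount <- function(n, k) {
  if (k < 0 || n < 0) stop("domain error: n and k must be non-negative")
  if (k > n) stop("domain error: k must not exceed n")
  k <- min(k, n - k)
  out <- 1
  for (i in seq_len(k)) {
    out <- out * (n - k + i) / i  # exact: product of i consecutive ints / i!
    if (out > 2^53) stop("subset count exceeds exact integer range")
  }
  round(out)
}
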