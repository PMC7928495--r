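test_that("subset draws are distinct, uniform and reproducible", {
  pool <- sprintf("v%02d", 1:19)
  set.seed(1)
  expect_equal(sort(drawSubset(pool, 19)), sort(pool))  # exhaustive
  set.seed(42); s1 <- drawSubset(pool, 2)
  set.seed(42); s2 <- drawSubset(pool, 2)
  expect_identical(s1, s2)
  expect_equal(anyDuplicated(s1), 0L)
  expect_error(drawSubset(pool, 20), "configuration")
  # binomial sampling check: inclusion frequency ~ k/n within 3 sigma
  set.seed(7)
  nDraw <- 10000
  counts <- table(factor(replicate(nDraw, drawSubset(pool, 2)),
                         levels = pool))
  pHat <- as.numeric(counts) / nDraw
  p0 <- 2 / 19
  sigma <- sqrt(p0 * (1 - p0) / nDraw)
  expect_true(all(abs(pHat - p0) <= 3 * sigma + 1e-12))
})

test_that("tally updates do exact accounting", {
  pool <- c("bio01", "bio03", "bio07")
  t0 <- newTally(pool)
  expect_equal(unname(useCount(t0)), c(0L, 0L, 0L))
  t1 <- updateTally(t0, c(bio03 = 60, bio07 = 40))
  expect_equal(useCount(t1)[["bio03"]], 1L)
  expect_equal(cumImportance(t1)[["bio03"]], 60)
  t2 <- updateTally(t1, c(bio03 = 20, bio01 = 80))
  expect_equal(useCount(t2)[["bio03"]], 2L)
  expect_equal(cumImportance(t2)[["bio03"]], 80)
  expect_equal(avgImportance(t2)[["bio03"]], 40)
  expect_equal(avgImportance(t2)[["bio01"]], 80)
  expect_error(updateTally(t2, c(bio99 = 1)), "schema")
  # conservation: R runs with k = 2 -> total use count 2R
  tt <- newTally(pool)
  set.seed(3)
  for (r in 1:25) {
    s <- drawSubset(pool, 2)
    tt <- updateTally(tt, stats::setNames(c(70, 30), s))
  }
  expect_equal(sum(useCount(tt)), 2L * 25L)
})

test_that("top-k ranking sorts by average importance with pool-order ties", {
  pool <- c("a", "b", "c")
  tt <- newTally(pool)
  tt <- updateTally(tt, c(a = 50, b = 50, c = 10))
  expect_equal(topVariables(tt, 2), c("a", "b"))  # tie -> pool order
  expect_equal(topVariables(tt, 3), c("a", "b", "c"))
  # deferred-selection signal while fewer than k variables are used
  t1 <- updateTally(newTally(pool), c(a = 100))
  expect_null(topVariables(t1, 2))
  # sort oracle on a random tally
  set.seed(11)
  pool2 <- sprintf("x%02d", 1:10)
  tr <- newTally(pool2)
  for (i in 1:30) {
    s <- drawSubset(pool2, 3)
    w <- runif(3); w <- 100 * w / sum(w)
    tr <- updateTally(tr, stats::setNames(w, s))
  }
  avg <- avgImportance(tr)
  oracle <- names(sort(avg[useCount(tr) > 0], decreasing = TRUE))
  expect_equal(topVariables(tr, 5), oracle[1:5])
})

test_that("runs are independent and deterministic in (subset, seed)", {
  w <- makeTinyWorld()
  s <- modelSettings("LQ")
  # singleton subset -> importance 100
  one <- executeRun("env01", w$presenceX, w$backgroundX, s, runSeed = 4)
  expect_equal(unname(one), 100)
  # identical (subset, seed) -> identical vector
  r1 <- executeRun(c("env01", "env04"), w$presenceX, w$backgroundX, s, 123)
  r2 <- executeRun(c("env01", "env04"), w$presenceX, w$backgroundX, s, 123)
  expect_identical(r1, r2)
  expect_equal(sum(r1), 100, tolerance = 1e-9)
  # a strong signal variable beats a noise variable in almost every run
  wins <- vapply(1:50, function(sd) {
    r <- executeRun(c("env01", "env05"), w$presenceX, w$backgroundX, s, sd)
    r[["env01"]] > r[["env05"]]
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("a sprint does exact accounting and models its own top-k", {
  w <- makeTinyWorld()
  cfg <- screenConfig(layerNames(w$grid), kPerRun = 2, runsPerSprint = 10,
                      nSprints = 1, topK = 3, settings = modelSettings("L"),
                      masterSeed = 5)
  out <- runSprint(cfg, list(presenceX = w$presenceX,
                             backgroundX = w$backgroundX), 1, newTally(cfg$pool))
  expect_equal(sum(useCount(out$tally)), 20L)  # 10 runs x k = 2
  rec <- out$record
  if (!is.null(rec$topK)) {
    expect_equal(rec$topK, topVariables(out$tally, 3))
    expect_true(is.finite(rec$aicc))
    expect_true(rec$auc > 0 && rec$auc <= 1)
  }
})

test_that("ensembles account for every run and reduce to a single sprint", {
  w <- makeTinyWorld()
  cfg1 <- screenConfig(layerNames(w$grid), kPerRun = 2, runsPerSprint = 4,
                       nSprints = 3, topK = 3, settings = modelSettings("L"),
                       masterSeed = 9, checkpoints = c(2, 3))
  data <- list(presenceX = w$presenceX, backgroundX = w$backgroundX)
  res <- runEnsemble(cfg1, data)
  expect_equal(totalRuns(res), 12)
  expect_equal(sum(useCount(tallyOf(res))), 24L)
  expect_named(res@checkpoints, c("sprint2", "sprint3"))
  # reduction: nSprints = 1 equals the bare sprint
  cfg2 <- screenConfig(layerNames(w$grid), kPerRun = 2, runsPerSprint = 4,
                       nSprints = 1, topK = 3, settings = modelSettings("L"),
                       masterSeed = 9, checkpoints = integer())
  res1 <- runEnsemble(cfg2, data)
  direct <- runSprint(cfg2, data, 1, newTally(cfg2$pool))
  expect_equal(useCount(tallyOf(res1)), useCount(direct$tally))
  expect_equal(finalTopK(res1), direct$record$topK)
  # whole-ensemble seed reproducibility
  resAgain <- runEnsemble(cfg1, data)
  expect_equal(as.data.frame(tallyOf(resAgain)), as.data.frame(tallyOf(res)))
  expect_equal(finalTopK(resAgain), finalTopK(res))
})

test_that("dry-run mode reproduces the sampling design without any fits", {
  cfg <- screenConfig(sprintf("b%02d", 1:19), kPerRun = 6, runsPerSprint = 10,
                      nSprints = 10, topK = 6, masterSeed = 2)
  res <- runEnsemble(cfg, dryRun = TRUE)
  expect_equal(totalRuns(res), 100)
  expect_equal(sum(useCount(tallyOf(res))), 600L)  # conservation, exact
  expect_true(res@dryRun)
})

test_that("k = n screening equals replicate-baseline importance averaging", {
  # oracle reduction: with k = n every run refits the same full model, so
  # the tally average must equal the mean of full-model permutation
  # importances computed independently with the matching run seeds.
  w <- makeTinyWorld(nLayers = 4)
  pool <- layerNames(w$grid)
  cfg <- screenConfig(pool, kPerRun = 4, runsPerSprint = 3, nSprints = 1,
                      topK = 4, settings = modelSettings("LQ"), masterSeed = 77)
  data <- list(presenceX = w$presenceX, backgroundX = w$backgroundX)
  res <- runEnsemble(cfg, data)
  m <- maxentFit(w$presenceX, w$backgroundX, modelSettings("LQ"))
  oracle <- rowMeans(vapply(1:3, function(r)
    permutationImportance(m, w$presenceX, w$backgroundX,
                          seed = deriveRunSeed(77, r))[pool],
    numeric(4)))
  expect_equal(avgImportance(tallyOf(res))[pool], oracle, tolerance = 1e-9)
})

test_that("stability detection reads hand-built sprint logs correctly", {
  mkrec <- function(tops) lapply(seq_along(tops), function(i)
    list(sprint = i, topK = tops[[i]]))
  # identical in all sprints -> 1
  allSame <- mkrec(rep(list(c("a", "b")), 5))
  expect_equal(stabilitySprint(allSame, "set"), 1L)
  expect_equal(stabilitySprint(allSame, "order"), 1L)
  # changes in the final sprint -> none
  lastChange <- mkrec(c(rep(list(c("a", "b")), 4), list(c("a", "c"))))
  expect_null(stabilitySprint(lastChange, "set"))
  # constructed log: set stable from sprint 7, order only from sprint 9
  tops <- c(rep(list(c("x", "y")), 6),            # sprints 1-6 (differ below)
            list(c("b", "a"), c("b", "a"),        # 7, 8: right set, wrong order
                 c("a", "b"), c("a", "b")))       # 9, 10: final order
  log <- mkrec(tops)
  expect_equal(stabilitySprint(log, "set"), 7L)
  expect_equal(stabilitySprint(log, "order"), 9L)
})

test_that("subset counts are exact binomial coefficients", {
  expect_equal(subsetCount(19, 6), 27132)
  expect_equal(subsetCount(19, 2), 171)      # 19 * 18 / 2
  expect_equal(subsetCount(7, 7), 1)
  expect_equal(subsetCount(0, 0), 1)
  expect_error(subsetCount(5, 6), "domain")
  # factorial oracle on moderate values
  for (n in c(5, 9, 12)) for (k in 0:n)
    expect_equal(subsetCount(n, k),
                 round(factorial(n) / (factorial(k) * factorial(n - k))))
})

test_that("per-run seeds are stable, bounded and order-free", {
  s1 <- vapply(1:100, function(i) deriveRunSeed(123, i), integer(1))
  s2 <- vapply(100:1, function(i) deriveRunSeed(123, i), integer(1))
  expect_equal(s1, rev(s2))
  expect_equal(anyDuplicated(s1), 0L)
  expect_true(all(s1 >= 0 & s1 < 2^31))
})

test_that("sprint logs and tallies serialize to CSV", {
  w <- makeTinyWorld()
  cfg <- screenConfig(layerNames(w$grid), kPerRun = 2, runsPerSprint = 4,
                      nSprints = 2, topK = 3, settings = modelSettings("L"),
                      masterSeed = 4, checkpoints = integer())
  res <- runEnsemble(cfg, list(presenceX = w$presenceX,
                               backgroundX = w$backgroundX))
  dir <- withr::local_tempdir()
  writeSprintLog(res, file.path(dir, "log.csv"))
  writeTally(tallyOf(res), file.path(dir, "tally.csv"))
  log <- read.csv(file.path(dir, "log.csv"))
  expect_equal(nrow(log), 2L)
  expect_true(all(layerNames(w$grid) %in% names(log)))
  tal <- read.csv(file.path(dir, "tally.csv"))
  expect_equal(sum(tal$use_count), 16L)
})
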