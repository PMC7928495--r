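test_that("all-constant predictors give the uniform no-information model", {
  pX <- matrix(5, 10, 2, dimnames = list(NULL, c("a", "b")))
  bX <- matrix(5, 100, 2, dimnames = list(NULL, c("a", "b")))
  m <- suppressWarnings(maxentFit(pX, bX, modelSettings("LQ")))
  expect_true(all(coef(m) == 0))
  raw <- maxentPredict(m, bX, "raw")
  expect_equal(raw, rep(1 / 100, 100))       # uniform over the background
  expect_equal(maxentPredict(m, bX, "logistic"), rep(0.5, 100))
  expect_equal(m@entropy, log(100))
})

test_that("L-only low-penalty fit moment-matches the presence means", {
  # independent oracle: the max-ent solution with vanishing penalty equates
  # E_q[f] under the fitted background distribution with the presence mean;
  # both sides computed by direct summation.
  d <- makeSeparableData(np = 60, nb = 600, gap = 1.2, seed = 8)
  s <- modelSettings("L", rm = 1e-6)
  m <- maxentFit(d$presenceX, d$backgroundX, s)
  raw <- maxentPredict(m, d$backgroundX, "raw")
  # expand in the model's own (background-scaled, clamped) feature basis
  fx <- expandFeatures(rbind(d$presenceX, d$backgroundX), s,
                       scaling = m@scaling)
  Fp <- fx$design[1:60, ]
  Fb <- fx$design[-(1:60), ]
  bruteExpectation <- colSums(Fb * raw)      # E_q[f], brute force
  expect_equal(unname(bruteExpectation), unname(colMeans(Fp)),
               tolerance = 1e-4)
})

test_that("a separating variable earns a positive coefficient and AUC ~ 1", {
  set.seed(31)
  bg <- cbind(a = runif(300, 0, 1))
  pr <- cbind(a = runif(40, 2, 3))           # fully separated, high side
  m <- maxentFit(pr, bg, modelSettings("L"))
  expect_gt(coef(m)[["L_a"]], 0)
  # presences clamp to the top of the background range, so the single most
  # extreme background point ties with them; AUC approaches 1
  auc <- aucScore(maxentPredict(m, pr, "link"), m@bgEta)
  expect_gt(auc, 0.995)
})

test_that("raw output is a distribution over the training background", {
  w <- makeTinyWorld()
  for (fc in c("L", "LQ", "LQHP")) {
    m <- maxentFit(w$presenceX, w$backgroundX,
                   modelSettings(fc, hingeKnots = 8))
    expect_equal(sum(maxentPredict(m, w$backgroundX, "raw")), 1,
                 tolerance = 1e-9)
    # entropy oracle: recompute -sum(raw log raw) directly
    raw <- maxentPredict(m, w$backgroundX, "raw")
    expect_equal(m@entropy, -sum(raw * log(raw)), tolerance = 1e-8)
    expect_gte(m@entropy, 0)
  }
})

test_that("logistic output is a monotone map of raw into (0,1)", {
  w <- makeTinyWorld()
  m <- maxentFit(w$presenceX, w$backgroundX, modelSettings("LQ"))
  raw <- maxentPredict(m, w$backgroundX, "raw")
  lg <- maxentPredict(m, w$backgroundX, "logistic")
  expect_true(all(lg > 0 & lg < 1))
  ord <- order(raw)
  expect_true(all(diff(lg[ord]) >= 0))
  # prediction on an EnvGrid returns a grid-shaped map with NA off-mask
  map <- maxentPredict(m, w$grid, "logistic")
  expect_equal(dim(map), dim(gridMask(w$grid)))
  expect_true(all(is.na(map[!gridMask(w$grid)])))
})

test_that("increasing the regularization multiplier never adds coefficients", {
  w <- makeTinyWorld()
  sizes <- vapply(c(0.5, 1, 2, 4), function(rm) {
    nParams(maxentFit(w$presenceX, w$backgroundX,
                      modelSettings("LQ", rm = rm)))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("the fit is invariant to affine rescaling of an input variable", {
  w <- makeTinyWorld()
  m1 <- maxentFit(w$presenceX, w$backgroundX, modelSettings("LQ"))
  pX2 <- w$presenceX; bX2 <- w$backgroundX
  pX2[, "env01"] <- 1000 * pX2[, "env01"] - 37
  bX2[, "env01"] <- 1000 * bX2[, "env01"] - 37
  m2 <- maxentFit(pX2, bX2, modelSettings("LQ"))
  expect_equal(maxentPredict(m1, w$backgroundX, "raw"),
               maxentPredict(m2, bX2, "raw"), tolerance = 1e-6)
})

test_that("prediction demands the model's variables", {
  w <- makeTinyWorld()
  m <- maxentFit(w$presenceX[, 1:3], w$backgroundX[, 1:3],
                 modelSettings("L"))
  expect_error(maxentPredict(m, w$presenceX[, 1:2]), "schema")
})

test_that("cross-validation partitions presences and is seed-reproducible", {
  w <- makeTinyWorld()
  cv <- crossValidate(w$presenceX, w$backgroundX, modelSettings("L"),
                      nReplicates = 10, seed = 5)
  expect_equal(nrow(cv), 10L)
  expect_equal(sum(cv$n_test), nrow(w$presenceX))
  expect_false(is.na(attr(cv, "mean")))
  cv2 <- crossValidate(w$presenceX, w$backgroundX, modelSettings("L"),
                       nReplicates = 10, seed = 5)
  expect_equal(cv, cv2, ignore_attr = FALSE)
  expect_error(crossValidate(w$presenceX[1:5, ], w$backgroundX,
                             nReplicates = 10, seed = 1), "partition")

  d <- makeSeparableData(np = 30, nb = 300, gap = 4, seed = 2)
  cvSep <- crossValidate(d$presenceX, d$backgroundX, modelSettings("L"),
                         nReplicates = 5, seed = 3)
  expect_gt(attr(cvSep, "mean"), 0.98)
})

test_that("the settings scan covers the grid and flags the AICc minimum", {
  w <- makeTinyWorld(nPresence = 60, nBackground = 400)
  scan <- tuneModel(w$presenceX[, 1:3], w$backgroundX[, 1:3],
                    fcGrid = c("L", "LQ"), rmGrid = c(0.5, 1, 2),
                    settings = modelSettings(hingeKnots = 8))
  expect_equal(nrow(scan), 6L)
  best <- scan[scan$best, ]
  expect_equal(nrow(best), 1L)
  expect_true(all(best$aicc <= scan$aicc, na.rm = TRUE))
  single <- tuneModel(w$presenceX[, 1:3], w$backgroundX[, 1:3],
                      fcGrid = "L", rmGrid = 1)
  expect_equal(nrow(single), 1L)
  expect_true(single$best)
})

test_that("models survive a JSON round trip", {
  w <- makeTinyWorld()
  m <- maxentFit(w$presenceX, w$backgroundX, modelSettings("LQ"))
  path <- withr::local_tempfile(fileext = ".json")
  modelToJson(m, path)
  m2 <- modelFromJson(path)
  expect_equal(coef(m2), coef(m))
  expect_equal(maxentPredict(m2, w$backgroundX, "logistic"),
               maxentPredict(m, w$backgroundX, "logistic"), tolerance = 1e-12)
})
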