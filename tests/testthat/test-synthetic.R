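# independent oracle for a cell-centre coordinate (row 1 = north)
cellCenterOracle <- function(row, col, nrows, cellSize, xll = 0, yll = 0) {
  cbind(xll + (col - 0.5) * cellSize,
        yll + (nrows - row + 0.5) * cellSize)
}

test_that("scenario validation rejects malformed correlation targets", {
  bad <- matrix(c(1, 0.99, 0.2, 0.99, 1, -0.99, 0.2, -0.99, 1), 3, 3)
  expect_error(syntheticScenario(nLayers = 3, crossCorrelation = bad,
                                 trueVariables = "env01",
                                 trueCoefficients = list(linear = 1)),
               "positive semi-definite")
  expect_error(syntheticScenario(nLayers = 3, trueVariables = "env09",
                                 trueCoefficients = list(linear = 1)),
               "subset")
})

test_that("generated landscapes hit the target cross-correlation", {
  # independent layers: empirical |r| small
  sc1 <- syntheticScenario(gridShape = c(100, 100), nLayers = 4,
                           smoothness = 3, trueVariables = "env01",
                           trueCoefficients = list(linear = 2), seed = 5)
  g1 <- genLandscape(sc1)
  v <- vapply(1:4, function(i) as.numeric(gridLayer(g1, i)), numeric(10000))
  offDiag <- cor(v)[upper.tri(diag(4))]
  expect_true(all(abs(offDiag) < 0.1))
  # strong target: r = 0.9 between the first two layers at 200 x 200
  C <- diag(4); C[1, 2] <- C[2, 1] <- 0.9
  sc2 <- syntheticScenario(gridShape = c(200, 200), nLayers = 4,
                           smoothness = 3, crossCorrelation = C,
                           trueVariables = "env01",
                           trueCoefficients = list(linear = 2), seed = 6)
  g2 <- genLandscape(sc2)
  r12 <- cor(as.numeric(gridLayer(g2, 1)), as.numeric(gridLayer(g2, 2)))
  expect_equal(r12, 0.9, tolerance = 0.05)
  # same seed -> identical grids
  expect_identical(gridValues(genLandscape(sc1)), gridValues(g1))
})

test_that("increasing smoothness increases spatial autocorrelation", {
  lag1 <- function(s) {
    sc <- syntheticScenario(gridShape = c(80, 80), nLayers = 1,
                            smoothness = s, trueVariables = "env01",
                            trueCoefficients = list(linear = 1), seed = 8)
    m <- gridLayer(genLandscape(sc), 1)
    cor(as.numeric(m[-1, ]), as.numeric(m[-nrow(m), ]))
  }
  acs <- vapply(c(1, 4, 10), lag1, numeric(1))
  expect_true(all(diff(acs) > 0))
})

test_that("suitability is the inverse-logit of the stated combination", {
  sc <- syntheticScenario(gridShape = c(30, 30), nLayers = 3, smoothness = 3,
                          trueVariables = c("env01", "env02"),
                          trueCoefficients = list(linear = c(1.5, -1),
                                                  quadratic = c(0, -0.5)),
                          seed = 3)
  g <- genLandscape(sc)
  suit <- scenarioSuitability(sc, g)
  s <- gridLayer(suit, 1)
  expect_true(all(s > 0 & s < 1, na.rm = TRUE))
  # per-cell oracle
  z1 <- scale(as.numeric(gridLayer(g, 1)))
  z2 <- scale(as.numeric(gridLayer(g, 2)))
  oracle <- plogis(1.5 * z1 - 1 * z2 - 0.5 * z2^2)
  expect_equal(as.numeric(s), as.numeric(oracle), tolerance = 1e-12)
  # all-zero coefficients -> 0.5 everywhere
  flat <- genSuitability(g, "env01", linear = 0)
  expect_true(all(abs(gridLayer(flat, 1) - 0.5) < 1e-12, na.rm = TRUE))
  # single positive linear coefficient -> strictly increasing in that layer
  mono <- genSuitability(g, "env01", linear = 2)
  ord <- order(as.numeric(gridLayer(g, 1)))
  expect_true(all(diff(as.numeric(gridLayer(mono, 1))[ord]) >= 0))
  expect_error(genSuitability(g, "nope", linear = 1), "schema")
})

test_that("presences follow suitability, avoid nodata and honour seeds", {
  sc <- syntheticScenario(gridShape = c(20, 20), nLayers = 2, smoothness = 2,
                          trueVariables = "env01",
                          trueCoefficients = list(linear = 2),
                          nodataFraction = 0.1, seed = 9)
  g <- genLandscape(sc)
  suit <- scenarioSuitability(sc, g)
  pres <- samplePresences(suit, 50, seed = 2)
  expect_equal(nrow(pres), 50L)
  # never on nodata: extraction must keep every presence
  ex <- gridExtract(g, pres)
  expect_true(all(attr(ex, "kept")))
  expect_identical(samplePresences(suit, 50, seed = 2), pres)
  # one-hot map: the single hot cell is drawn
  hot <- matrix(0, 20, 20); hot[7, 13] <- 1
  hotGrid <- envGrid(list(suitability = hot), cellSize = 1)
  p1 <- samplePresences(hotGrid, 1, seed = 1)
  expect_equal(unname(as.matrix(p1)), unname(cellCenterOracle(7, 13, 20, 1)))
  expect_error(samplePresences(hotGrid, 2, seed = 1), "capacity")
})

test_that("uniform suitability yields uniform cell frequencies", {
  flat <- envGrid(list(suitability = matrix(1, 5, 5)))
  set.seed(41)
  counts <- integer(25)
  for (i in 1:500) {
    p <- samplePresences(flat, 20, seed = i)
    counts <- counts + tabulate(
      (floor(p$lon) ) * 5 + (5 - floor(p$lat)), nbins = 25)
  }
  # each cell drawn in 20/25 of samples on average: Binomial(500, 0.8)
  p0 <- 20 / 25
  sigma <- sqrt(p0 * (1 - p0) / 500)
  expect_true(all(abs(counts / 500 - p0) <= 4 * sigma))
})

test_that("synthetic outputs round-trip through the file formats", {
  sc <- syntheticScenario(gridShape = c(15, 15), nLayers = 3, smoothness = 2,
                          trueVariables = "env01",
                          trueCoefficients = list(linear = 2), seed = 12)
  g <- genLandscape(sc)
  dir <- withr::local_tempdir()
  paths <- writeEnvGrid(g, dir)
  g2 <- readEnvGrid(paths)
  expect_equal(layerNames(g2), layerNames(g))
  expect_equal(gridValues(g2), gridValues(g), tolerance = 1e-8)
  pres <- samplePresences(scenarioSuitability(sc, g), 30, seed = 1)
  f <- file.path(dir, "occ.csv")
  writeOccurrences(pres, f)
  back <- readOccurrences(f)
  expect_equal(back$lon, pres$lon)
  ex <- gridExtract(g2, back)
  expect_equal(nrow(ex), 30L)
})

test_that("a strong-signal recovery experiment finds the true variables", {
  sc <- syntheticScenario(gridShape = c(30, 30), nLayers = 5, smoothness = 3,
                          trueVariables = c("env01", "env02"),
                          trueCoefficients = list(linear = c(3, -3)),
                          nPresences = 80, seed = 21)
  cfg <- screenConfig(sc$layers, kPerRun = 2, runsPerSprint = 10,
                      nSprints = 4, topK = 2, settings = modelSettings("L"),
                      checkpoints = integer())
  rec <- recoveryExperiment(sc, cfg, nReplicates = 2, seed = 5,
                            nBackground = 400)
  expect_named(rec$inclusion, c("env01", "env02"))
  expect_true(all(rec$inclusion >= 0 & rec$inclusion <= 1))
  expect_equal(length(rec$topKsets), 2L)
  expect_gte(mean(unlist(rec$inclusion)), 0.5)
})
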