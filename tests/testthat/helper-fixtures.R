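# Shared fixtures: everything is generated in code at test time.

# Small landscape with two signal layers and noise layers.
makeTinyWorld <- function(nLayers = 6, shape = c(40, 40), nPresence = 100,
                          nBackground = 800, seed = 7,
                          strength = 2.5, smoothness = 4) {
  sc <- syntheticScenario(
    gridShape = shape, nLayers = nLayers, smoothness = smoothness,
    trueVariables = c("env01", "env02"),
    trueCoefficients = list(linear = c(strength, -strength),
                            quadratic = c(0, 0)),
    nPresences = nPresence, seed = seed)
  g <- genLandscape(sc)
  suit <- scenarioSuitability(sc, g)
  pres <- samplePresences(suit, nPresence, seed = seed + 1)
  bg <- sampleBackground(g, nBackground, seed = seed + 2)
  list(scenario = sc, grid = g, suit = suit, pres = pres, bg = bg,
       presenceX = gridExtract(g, pres), backgroundX = gridExtract(g, bg))
}

# Presence/background matrices where `a` separates the classes and `b` is
# pure noise.
makeSeparableData <- function(np = 40, nb = 400, gap = 3, seed = 5) {
  set.seed(seed)
  bg <- cbind(a = rnorm(nb), b = rnorm(nb))
  pr <- cbind(a = rnorm(np, mean = gap), b = rnorm(np))
  list(presenceX = pr, backgroundX = bg)
}

# Write a tiny ASCII grid file and return its path.
writeTempAsc <- function(values, dir = withr::local_tempdir(.local_envir = parent.frame()),
                         name = "layer.asc", xll = 0, yll = 0, cellSize = 1) {
  path <- file.path(dir, name)
  writeAsciiGrid(values, path, xll = xll, yll = yll, cellSize = cellSize)
  path
}
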