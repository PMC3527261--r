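## Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixtureOnce <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

## A small synthetic benchmark (one condition) for fast end-to-end tests.
smallBenchmark <- function(conditions = 1L, nGenes = 40L, nTrain = 15L,
                           seed = 42L) {
  makeSyntheticBenchmark(syntheticConfig(
    nGenes = nGenes, nTrain = nTrain, conditions = conditions,
    gridN = 60L, seed = seed))
}

## A quick (deliberately short) training posterior on the small benchmark.
quickPosterior <- function() {
  fixtureOnce("quickPosterior", {
    bm <- smallBenchmark()
    runTraining(benchmarkExpression(bm), bm@network,
                trainingConfig(iterations = 1200L, burnin = 600L,
                               nStore = 60L, gridN = 40L, seed = 3L))
  })
}

## A TrainingPosterior whose activity "samples" are all equal to a known
## activity matrix: lets prediction be tested against known TF activities.
fixedPosterior <- function(pMat, gridTimes, tfn, S = 3L) {
  I <- length(tfn)
  act <- list(lapply(seq_len(I), function(i)
    matrix(rep(pMat[, i], each = S), S)))
  new("TrainingPosterior", tfNames = tfn, geneIds = "train1",
      gridTimes = gridTimes,
      series = data.frame(condition = 1, replicate = "1"),
      activity = act, fmrna = act,
      delta = matrix(1, S, I, dimnames = list(NULL, tfn)),
      p0 = list(matrix(1, S, I)),
      geneParams = list(),
      adaptiveVar = matrix(0, S, 1L),
      hyper = matrix(1, S, 2L * I),
      network = matrix(0L, 1L, I, dimnames = list("train1", tfn)),
      acceptance = c(gene = 0.25), config = list(seed = 1L))
}

## Smooth toy activity profiles for two TFs on a grid.
toyActivities <- function(gridTimes) {
  cbind(TFa = 1.5 + sin(gridTimes / 3) + 0.5 * cos(gridTimes / 1.7),
        TFb = 0.4 + 2.2 * exp(-((gridTimes - 6) / 3)^2))
}

## Build an ExpressionTimeSeries for a single synthetic gene driven by a
## known activity matrix p on a grid (plus optional extra genes).
geneSeriesFromModel <- function(pGrid, gridTimes, w, w0, kp, obsTimes,
                                noiseVar = 0.01, seed = 1L,
                                tfNames = colnames(pGrid),
                                geneId = "gene1") {
  set.seed(seed)
  m <- solveTranscription(pGrid, gridTimes, responseWeights(w, w0), kp,
                          outTimes = obsTimes)
  y <- m + rnorm(length(obsTimes), 0, sqrt(noiseVar))
  vals <- matrix(y, 1L, dimnames = list(geneId, NULL))
  expressionTimeSeries(vals, matrix(noiseVar, 1L, length(obsTimes)),
                       time = obsTimes, tfNames = character())
}
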