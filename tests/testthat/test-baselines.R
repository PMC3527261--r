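## toy two-TF data set generated from the ODE model, for baseline tests
mlToyData <- function(noiseVar = 0.004, seed = 1L) {
  g <- denseGrid(0, 12, 60)
  fm <- cbind(TFa = 1 + 0.8 * sin(g / 2.5) + 0.3 * g / 12,
              TFb = 2.5 * exp(-((g - 7) / 3.5)^2) + 0.3)
  delta <- c(TFa = 0.9, TFb = 1.3)
  pm <- vapply(1:2, function(i)
    solveTranslation(fm[, i], g, proteinParams(delta[i], fm[1, i] / delta[i])),
    numeric(length(g)))
  colnames(pm) <- colnames(fm)
  obsT <- c(0, 1.5, 3, 4.5, 6, 7.5, 9, 10.5, 12)
  X <- matrix(c(1L, 0L, 1L, 0L, 1L, 1L), 3, 2,
              dimnames = list(c("gA", "gB", "gAB"), colnames(fm)))
  kin <- list(gA = kineticParams(0.2, 0.8, 2.5, 0.5),
              gB = kineticParams(0.1, 0.5, 2.0, 0.8),
              gAB = kineticParams(0.3, 1.1, 3.0, 0.2))
  W <- rbind(gA = c(2, 0), gB = c(0, 1.8), gAB = c(1.5, 1.2))
  set.seed(seed)
  vals <- rbind(
    t(vapply(rownames(X), function(j)
      solveTranscription(pm, g, responseWeights(W[j, ], 0.2), kin[[j]],
                         outTimes = obsT) +
        rnorm(length(obsT), 0, sqrt(noiseVar)), numeric(length(obsT)))),
    t(vapply(colnames(fm), function(tf)
      approx(g, fm[, tf], xout = obsT)$y +
        rnorm(length(obsT), 0, sqrt(noiseVar)), numeric(length(obsT)))))
  ets <- expressionTimeSeries(vals, matrix(noiseVar, nrow(vals), length(obsT)),
                              time = obsT, tfNames = colnames(fm))
  list(ets = ets, X = X, truth = list(f = fm, p = pm, grid = g,
                                      delta = delta, W = W, kin = kin))
}

mlToyFit <- function() fixtureOnce("mlToyFit", {
  toy <- mlToyData()
  fit <- mlTrainActivities(toy$ets, toy$X,
                           mlConfig(gridN = 50, restarts = 2, maxit = 600))
  list(toy = toy, fit = fit)
})

test_that("ML training recovers activities and attains the generating fit", {
  tf <- mlToyFit()
  fit <- tf$fit; toy <- tf$toy
  ## recovered activities correlate with the generating ones (point
  ## estimates sit on a degradation-rate ridge, so recovery is decent but
  ## not sharp - the motivation for the Bayesian treatment)
  for (i in 1:2) {
    ptrue <- approx(toy$truth$grid, toy$truth$p[, i],
                    xout = fit$gridTimes)$y
    expect_gt(cor(fit$p[[1]][, i], ptrue), 0.75)
  }
  ## point estimates exist for every training gene
  expect_named(fit$geneEstimates, rownames(toy$X))
})

test_that("maximized likelihood respects nesting across structures", {
  tf <- mlToyFit()
  mst <- mlScoreStructures(tf$toy$ets, tf$fit,
                           config = mlConfig(restarts = 2, maxit = 150))
  le <- mst@logEvidence
  S <- mst@structures
  for (gn in rownames(le)) for (k1 in seq_len(nrow(S)))
    for (k2 in seq_len(nrow(S)))
      if (all(S[k1, ] >= S[k2, ]) && k1 != k2)
        expect_gte(le[gn, k1], le[gn, k2] - 0.05)
  ## the generating regulator is identified for the single-TF genes
  expect_gt(linkProbabilities(mst)["gA", "TFa"],
            linkProbabilities(mst)["gA", "TFb"])
  expect_gt(linkProbabilities(mst)["gB", "TFb"],
            linkProbabilities(mst)["gB", "TFa"])
})

test_that("activation-only ML fits keep weights non-negative", {
  toy <- mlToyData()
  fit <- mlTrainActivities(toy$ets, toy$X,
                           mlConfig(gridN = 40, restarts = 1, maxit = 60,
                                    activationOnly = TRUE))
  w <- do.call(rbind, lapply(fit$geneEstimates, function(e) e[1:2]))
  expect_true(all(w >= 0))
})

test_that("regression CV recovers exact linear relationships", {
  obsT <- c(0:9)
  set.seed(9)
  fvals <- matrix(runif(3 * 10, 0.5, 3), 3, 10,
                  dimnames = list(c("TF1", "TF2", "TF3"), NULL))
  vals <- rbind(gLin = 2 * fvals["TF1", ] + 1,
                gConst = 2.4 + rnorm(10, 0, 0.05),
                fvals)
  ets <- expressionTimeSeries(vals, NULL, time = obsT,
                              tfNames = c("TF1", "TF2", "TF3"))
  res <- regressionSelect(ets, genes = c("gLin", "gConst"))
  expect_equal(res$structure[res$gene == "gLin"], "100")
  expect_equal(res$cvMSE[res$gene == "gLin"], 0, tolerance = 1e-20)
  expect_equal(res[res$gene == "gLin", "TF1"], 2, tolerance = 1e-10)
  expect_equal(res$structure[res$gene == "gConst"], "000")
  ## exact fits rank before noisy ones
  expect_equal(res$gene[1], "gLin")
})

test_that("regression CV rarely hallucinates regulators on random genes", {
  set.seed(10)
  nGenes <- 200
  obsT <- 0:9
  fvals <- matrix(runif(5 * 10, 0.5, 3), 5, 10,
                  dimnames = list(paste0("TF", 1:5), NULL))
  vals <- rbind(matrix(rnorm(nGenes * 10), nGenes, 10,
                       dimnames = list(sprintf("r%03d", 1:nGenes), NULL)),
                fvals)
  ets <- expressionTimeSeries(vals, NULL, time = obsT,
                              tfNames = rownames(fvals))
  res <- regressionSelect(ets, genes = sprintf("r%03d", 1:nGenes))
  nullFrac <- mean(res$structure == "00000")
  expect_gt(nullFrac, 4 / 32)
})

test_that("regression selection is invariant to TF ordering", {
  toy <- mlToyData()
  resA <- regressionSelect(toy$ets, genes = rownames(toy$X))
  v <- SummarizedExperiment::assay(toy$ets, "exprs")
  vv <- SummarizedExperiment::assay(toy$ets, "var")
  cd <- SummarizedExperiment::colData(toy$ets)
  etsB <- expressionTimeSeries(v, vv, time = cd$time,
                               condition = cd$condition,
                               replicate = cd$replicate,
                               tfNames = rev(tfNames(toy$ets)))
  resB <- regressionSelect(etsB, genes = rownames(toy$X))
  expect_equal(resA$cvMSE, resB$cvMSE[match(resA$gene, resB$gene)])
})

test_that("the Inferelator combination rule follows its formula", {
  expect_equal(inferelatorCombine(0.2, 0.5, 0.1), 0.2)
  expect_equal(inferelatorCombine(0, 0.7, 0.4), 0.4)
  expect_equal(inferelatorCombine(0, 0, 0), 0)
  expect_equal(inferelatorCombine(-0.6, 0.5, -0.2), 0.5)
  expect_error(inferelatorCombine(Inf, 1, 1), "non-finite")
  tbl <- data.frame(gene = "g1",
                    term = c("A", "B", "A:B"),
                    beta = c(0.2, 0.5, 0.1))
  rk <- inferelatorRank(tbl, c("A", "B"))
  expect_equal(rk$pair$score, 0.2)
  expect_equal(rk$single$score[rk$single$tf == "A"], 0.2)
  expect_equal(rk$single$score[rk$single$tf == "B"], 0.5)
})
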