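## Gene-parameter posteriors can be checked exactly on "null" training
## genes (no active TF links): the model curve reduces to
## m(t) = a e^{-d t} + (c / d)(1 - e^{-d t}) with c = b + s G(w0),
## so posterior moments follow from dense quadrature over (c, d, a), with
## the prior of c obtained by Monte Carlo from the priors of (b, s, w0).
nullGeneOracle <- function(y, tt, v) {
  set.seed(4242)
  N <- 2e6
  lc <- log(rlnorm(N, 0, 1.5) + rlnorm(N, 0, 1.5) * plogis(rnorm(N, 0, 2)))
  dns <- density(lc, from = -6, to = 7, n = 300)
  pic <- dns$y / sum(dns$y)
  ldG <- seq(-5.5, 5.5, length.out = 320)
  laG <- seq(-5.5, 5.5, length.out = 300)
  pid <- dnorm(ldG, 0, 1.5); pid <- pid / sum(pid)
  pia <- dnorm(laG, 0, 1.5); pia <- pia / sum(pia)
  cg <- exp(dns$x); dg <- exp(ldG); ag <- exp(laG)
  ed <- exp(-outer(dg, tt))
  post <- array(0, c(length(cg), length(dg), length(ag)))
  for (ia in seq_along(ag)) {
    acc <- matrix(0, length(dg), length(cg))
    for (it in seq_along(tt)) {
      mu <- ag[ia] * ed[, it] + outer((1 - ed[, it]) / dg, cg)
      acc <- acc - 0.5 * (y[it] - mu)^2 / v
    }
    post[, , ia] <- t(acc)
  }
  post <- exp(post - max(post)) * outer(outer(pic, pid), pia)
  Z <- sum(post)
  Ed <- sum(post * rep(dg, each = length(cg))) / Z
  Ed2 <- sum(post * rep(dg^2, each = length(cg))) / Z
  Ea <- sum(aperm(post, c(3, 1, 2)) * ag) / Z
  c(Ed = Ed, sdd = sqrt(Ed2 - Ed^2), Ea = Ea)
}

test_that("gene-parameter posteriors match grid quadrature on a null gene", {
  set.seed(1)
  tt <- c(0, 1, 2, 3, 4.5, 6, 7.5, 9, 10.5, 12)
  mtrue <- 0.1 * exp(-1.5 * tt) + 2 * (1 - exp(-1.5 * tt))
  v <- 0.01
  y <- mtrue + rnorm(length(tt), 0, sqrt(v))
  oracle <- nullGeneOracle(y, tt, v)
  vals <- rbind(g1 = y, T1 = rep(1, length(tt)) + 0.1 * sin(tt))
  ets <- expressionTimeSeries(vals, matrix(v, 2, length(tt)), time = tt,
                              tfNames = "T1")
  X <- matrix(0L, 1, 1, dimnames = list("g1", "T1"))
  mom <- vapply(1:3, function(sd) {
    tp <- runTraining(ets, X, trainingConfig(
      iterations = 9000, burnin = 3000, nStore = 600, gridN = 30,
      seed = sd, varFloor = 1e-4))
    gp <- tp@geneParams[["g1"]]
    c(mean(gp[, "d"]), sd(gp[, "d"]), mean(gp[, "a"]))
  }, numeric(3))
  avg <- rowMeans(mom)
  expect_equal(avg[1], unname(oracle["Ed"]), tolerance = 0.15)
  expect_equal(avg[2], unname(oracle["sdd"]), tolerance = 0.5)
  expect_lt(abs(avg[3] - oracle["Ea"]), 0.06)
})

test_that("chains are exactly reproducible and respect structural zeros", {
  bm <- smallBenchmark()
  cfg <- trainingConfig(iterations = 400, burnin = 200, nStore = 20,
                        gridN = 30, seed = 5)
  tp1 <- runTraining(benchmarkExpression(bm), trainingNetwork(bm), cfg)
  tp2 <- runTraining(benchmarkExpression(bm), trainingNetwork(bm), cfg)
  expect_identical(deltaSamples(tp1), deltaSamples(tp2))
  expect_identical(activitySamples(tp1)[[1]], activitySamples(tp2)[[1]])
  ## weights fixed to zero by the training network stay exactly zero
  X <- trainingNetwork(bm)
  for (g in rownames(X)) {
    w <- tp1@geneParams[[g]][, paste0("w.", colnames(X))]
    zero <- which(X[g, ] == 0L)
    if (length(zero)) expect_true(all(w[, zero] == 0))
    on <- which(X[g, ] == 1L)
    if (length(on)) expect_true(all(colSums(w[, on, drop = FALSE] != 0) > 0))
  }
  ## activity samples are non-negative (class invariant)
  expect_true(all(vapply(activitySamples(tp1)[[1]],
                         function(m) all(m >= 0), logical(1))))
})

test_that("input validation rejects malformed training problems", {
  bm <- smallBenchmark()
  ets <- benchmarkExpression(bm)
  X <- trainingNetwork(bm)
  expect_error(runTraining(ets, X[0, , drop = FALSE]), "empty")
  colnames(X) <- c("ANT", "BEE", "WRONG")
  expect_error(runTraining(ets, X), "match")
  X <- trainingNetwork(bm); X[1, 1] <- 2L
  expect_error(runTraining(ets, X), "binary")
})

test_that("robust filtering excludes genes driven by an unmodelled factor", {
  ## eight genes regulated only by the modelled TFs plus one gene strongly
  ## driven by the confounder
  cfg <- syntheticConfig(nGenes = 9, nTrain = 9, conditions = 1L,
                         gridN = 60, seed = 13)
  wts <- sampleWeights(9, seed = 2)
  W <- wts$W
  W[, "UNK"] <- 0
  W["g0009", ] <- c(0, 0, 0, 4)    # confounder-driven gene
  W["g0001", "ANT"] <- 1.5         # ensure some real structure
  truthKin <- sampleKinetics(9, seed = 3)
  truthKin$s <- pmax(truthKin$s, 0.8)
  truthKin["g0009", "s"] <- 2.5    # strong, clearly visible effect
  truthKin["g0009", "d"] <- 0.8
  grid <- denseGrid(0, 18, 60)
  prof1 <- makeTFProfiles(1, grid)
  w0 <- wts$w0
  ## centre the confounder response so it swings through its dynamic range
  w0["g0009"] <- -4 * mean(log(prof1$p[, "UNK"]))
  truth <- list(W = W, w0 = w0,
                kinetics = truthKin,
                profiles = list(`1` = prof1))
  ets <- simulateObservations(truth, cfg, seed = 7)
  X <- (W[, 1:3] != 0) + 0L
  tp <- runTraining(ets, X, trainingConfig(iterations = 3000, burnin = 1500,
                                           nStore = 150, gridN = 40,
                                           seed = 17, useAdaptive = TRUE))
  av <- adaptiveVariances(tp)
  expect_equal(names(which.max(av)), "g0009")
  expect_false("g0009" %in% robustFilter(tp, 0.01))
  ## threshold edge cases
  expect_identical(robustFilter(tp, Inf), tp@geneIds)
  expect_error(robustFilter(tp, -1), "non-negative")
  tpPlain <- quickPosterior()
  expect_error(robustFilter(tpPlain), "useAdaptive")
  ## all-zero adaptive variances retain everything
  tpZero <- tp
  tpZero@adaptiveVar[] <- 0
  expect_identical(robustFilter(tpZero, 0.01), tp@geneIds)
})

test_that("pooling both conditions shrinks the TF activity posteriors", {
  bm <- smallBenchmark(conditions = c(1L, 2L), seed = 23)
  ets <- benchmarkExpression(bm)
  cd <- SummarizedExperiment::colData(ets)
  cfg <- function(sd) trainingConfig(iterations = 2600, burnin = 1200,
                                     nStore = 140, gridN = 40, seed = sd)
  meanVar <- function(tp, series = 1L)
    mean(vapply(activitySamples(tp, series),
                function(m) mean(apply(m, 2, var)), numeric(1)))
  tpBoth <- runTraining(ets, trainingNetwork(bm), cfg(31))
  tp1 <- runTraining(ets[, cd$condition == 1], trainingNetwork(bm), cfg(31))
  tp2 <- runTraining(ets[, cd$condition == 2], trainingNetwork(bm), cfg(31))
  v1 <- meanVar(tp1); v2 <- meanVar(tp2)
  idx2 <- which(tpBoth@series$condition == 2)
  vb <- mean(c(meanVar(tpBoth, 1L), meanVar(tpBoth, idx2)))
  expect_lt(vb, v1)
  expect_lt(vb, v2)
})
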