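test_that("structure enumeration covers the model space", {
  S <- allStructures(c("A", "B", "C", "D", "E"))
  expect_equal(dim(S), c(32L, 5L))
  expect_equal(anyDuplicated(rownames(S)), 0L)
  expect_identical(rownames(S)[1], "00000")
  expect_identical(rownames(S)[32], "11111")
  expect_equal(sum(rowSums(S) == 1L), 5L)
})

test_that("posterior over structures follows Bayes' rule", {
  S <- allStructures(c("A", "B", "C", "D", "E"))
  ## equal evidences + uniform prior: every structure, including the
  ## unregulated one, gets probability 1/32
  post <- posteriorOverStructures(rep(-12.3, 32))
  expect_equal(post, rep(1 / 32, 32))
  expect_equal(post[match("00000", rownames(S))], 1 / 32)
  ## a dominating evidence takes all the mass
  le <- rep(0, 32); le[5] <- 1e4
  expect_equal(posteriorOverStructures(le)[5], 1)
  expect_error(posteriorOverStructures(rep(-Inf, 4)), "zero evidence")
  ## a non-uniform prior tilts the posterior
  pr <- c(3, rep(1, 31)); pr <- pr / sum(pr)
  post <- posteriorOverStructures(rep(0, 32), prior = pr)
  expect_equal(post, pr)
})

test_that("link marginals equal brute-force enumeration", {
  tfn <- c("A", "B", "C")
  S <- allStructures(tfn)
  ## uniform posterior: singles 0.5, pairs 0.25 by symmetry
  u <- rep(1 / 8, 8)
  for (i in 1:3) expect_equal(marginalLinkProb(u, S, i), 0.5)
  expect_equal(pairMarginal(u, S, 1, 3), 0.25)
  ## hand-set table vs direct sum
  set.seed(31)
  post <- posteriorOverStructures(rnorm(8))
  for (i in 1:3) {
    brute <- sum(vapply(1:8, function(k) post[k] * (S[k, i] == 1),
                        numeric(1)))
    expect_equal(marginalLinkProb(post, S, i), brute)
  }
  brute <- sum(vapply(1:8, function(k)
    post[k] * (S[k, 1] == 1 && S[k, 2] == 1), numeric(1)))
  expect_equal(pairMarginal(post, S, "A", "B"), brute)
  expect_error(marginalLinkProb(post, S, 9), "out of range")
})

test_that("MAP structure breaks ties toward parsimony", {
  tfn <- c("A", "B")
  S <- allStructures(tfn)
  post <- c(0, 1, 0, 0); names(post) <- rownames(S)
  expect_equal(unname(mapStructure(post, S)), c(0L, 1L))
  ## exact tie between "10" and "11": fewer links wins
  post <- c(0, 0, 0.5, 0.5); names(post) <- rownames(S)
  expect_equal(unname(mapStructure(post, S)), c(1L, 0L))
  ## flat posterior: the unregulated structure wins
  expect_equal(unname(mapStructure(rep(0.25, 4), S)), c(0L, 0L))
})

test_that("restricted posteriors renormalize over the reduced model set", {
  tfn <- c("A", "B", "C")
  S <- allStructures(tfn)
  le <- rep(-3.7, 8); names(le) <- rownames(S)
  expect_equal(unname(restrictedPosterior(le, S, "B")), c(0.5, 0.5))
  p4 <- restrictedPosterior(le, S, c("A", "C"))
  expect_equal(unname(p4), rep(0.25, 4))
  expect_identical(names(p4), c("101", "100", "001", "000"))
  set.seed(4)
  le <- rnorm(8); names(le) <- rownames(S)
  expect_equal(sum(restrictedPosterior(le, S, c("A", "B"))), 1)
  expect_error(restrictedPosterior(le, S, character()), "empty")
})

test_that("evidence scoring is deterministic and data-driven, not id-driven", {
  g <- denseGrid(0, 12, 40)
  pm <- toyActivities(g)
  tp <- fixedPosterior(pm, g, colnames(pm))
  obsT <- c(0, 2, 4, 6, 8, 10, 12)
  ets1 <- geneSeriesFromModel(pm, g, c(2, 0), 0,
                              kineticParams(0.2, 0.8, 2, 0.5), obsT,
                              seed = 5)
  ## a second gene with identical measurements gets identical evidence
  v <- SummarizedExperiment::assay(ets1, "exprs")
  ets2 <- expressionTimeSeries(rbind(gene1 = v[1, ], dup = v[1, ]),
                               matrix(0.01, 2, length(obsT)),
                               time = obsT)
  cfg <- predictionConfig(nTemp = 30L, nPart = 48L,
                          nActivitySamples = 2L, seed = 9L)
  mst <- predictRegulators(ets2, tp, config = cfg)
  expect_equal(mst@logEvidence["gene1", ], mst@logEvidence["dup", ])
  ## gene order does not change per-gene results
  mstR <- predictRegulators(ets2, tp, genes = c("dup", "gene1"),
                            config = cfg)
  expect_equal(mstR@logEvidence["gene1", ], mst@logEvidence["gene1", ])
})

test_that("a strongly regulated gene is attributed to its regulator", {
  g <- denseGrid(0, 12, 40)
  pm <- toyActivities(g)
  tp <- fixedPosterior(pm, g, colnames(pm))
  obsT <- c(0, 1.5, 3, 4.5, 6, 8, 10, 12)
  cfg <- predictionConfig(nTemp = 30L, nPart = 48L,
                          nActivitySamples = 2L, seed = 2L)
  wins <- vapply(1:3, function(sd) {
    ets <- geneSeriesFromModel(pm, g, c(3, 0), 0,
                               kineticParams(0.1, 0.9, 3, 0.3), obsT,
                               noiseVar = 0.005, seed = sd)
    leOn <- scoreStructure(ets, "gene1", c(1L, 0L), tp, cfg)
    leOff <- scoreStructure(ets, "gene1", c(0L, 0L), tp, cfg)
    leOn > leOff
  }, logical(1))
  expect_true(all(wins))
})

test_that("stronger-sensitivity genes rank higher for their true regulator", {
  ## genes with one random regulator and log-normal sensitivities: the
  ## marginal probability of the true link should grow with the signal
  ## strength s (rank correlation over genes)
  set.seed(77)
  g <- denseGrid(0, 12, 40)
  pm <- toyActivities(g)
  tp <- fixedPosterior(pm, g, colnames(pm))
  obsT <- seq(0, 12, length.out = 10)
  n <- 50
  svals <- rlnorm(n, log(1), 1.2)
  tfidx <- sample(1:2, n, replace = TRUE)
  seeds <- sample.int(10000, n)
  cfg <- predictionConfig(nTemp = 40L, nPart = 96L,
                          nActivitySamples = 2L, seed = 6L)
  pTrue <- vapply(seq_len(n), function(k) {
    w <- c(0, 0); w[tfidx[k]] <- 1.2
    ets <- geneSeriesFromModel(pm, g, w, 0,
                               kineticParams(0.2, 0.7, svals[k], 0.4),
                               obsT, noiseVar = 0.02, seed = seeds[k])
    mst <- predictRegulators(ets, tp, config = cfg)
    linkProbabilities(mst)[1, tfidx[k]]
  }, numeric(1))
  expect_gt(cor(svals, pTrue, method = "spearman"), 0.15)
})
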