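## Synthetic benchmark generator: an artificial regulatory system with four
## TFs -- ANT, BEE, CAR and a confounder UNK that drives the data but is
## never shown to the inference machinery -- two experimental conditions,
## and ~1030 target genes simulated from the transcription ODE with
## spike-and-slab interaction weights and empirically calibrated kinetics.
## Observations are taken at ten unevenly spaced time points with
## signal-proportional Gaussian noise and zero-truncation.

.SYN_TFS <- c("ANT", "BEE", "CAR", "UNK")
.SYN_DELTA <- c(ANT = 0.994, BEE = 0.945, CAR = 0.640, UNK = 1.2)

#' Configuration of the synthetic benchmark
#'
#' Defaults reproduce the benchmark protocol: 1030 target genes of which 30
#' form the training subnetwork, ten unevenly spaced time points over 18 h,
#' Gaussian observation noise with variance 0.025 times the signal, 15%
#' corruption of the training links, and TF protein degradation rates
#' (0.994, 0.945, 0.640, 1.2)/h for ANT, BEE, CAR, UNK.
#'
#' @param nGenes number of target genes.
#' @param nTrain number of training genes (taken as the first genes).
#' @param times observation times (h), strictly increasing.
#' @param noiseFactor observation noise variance per unit of signal.
#' @param linkNoise probability with which each training link is flipped.
#' @param delta TF protein degradation rates (1/h), one per TF.
#' @param conditions which experimental conditions to simulate (subset of
#'   \code{c(1, 2)}).
#' @param gridN dense-grid size used when integrating the ODEs.
#' @param seed integer seed governing all randomness of the generator.
#' @return a list of class \code{SyntheticConfig}.
#' @export
syntheticConfig <- function(nGenes = 1030L, nTrain = 30L,
                            times = c(0, 1, 2, 3, 5, 7, 9, 11, 14, 18),
                            noiseFactor = 0.025, linkNoise = 0.15,
                            delta = .SYN_DELTA, conditions = c(1L, 2L),
                            gridN = 100L, seed = 1L) {
  stopifnot(all(diff(times) > 0), linkNoise >= 0, linkNoise <= 1,
            noiseFactor >= 0, nGenes >= 1L, nTrain <= nGenes,
            all(conditions %in% 1:2), all(delta > 0))
  structure(list(nGenes = as.integer(nGenes), nTrain = as.integer(nTrain),
                 times = times, noiseFactor = noiseFactor,
                 linkNoise = linkNoise, delta = delta,
                 conditions = as.integer(conditions),
                 gridN = as.integer(gridN), seed = as.integer(seed)),
            class = "SyntheticConfig")
}

## Smooth positive TF mRNA profile shapes: sums of Gaussian bumps over the
## 18 h time course. Condition 1 makes the protein activities of ANT and BEE
## strongly overlapping; condition 2 moves the BEE pulse late in the time
## course, decorrelating it from ANT. CAR peaks early and UNK is a broad
## pulse overlapping all three.
.tfBump <- function(t, centre, width, height) {
  height * exp(-0.5 * ((t - centre) / width)^2)
}

.tfMRNAShapes <- function(condition) {
  beeCentre <- if (condition == 1L) 6.8 else 11
  list(
    ANT = function(t) .tfBump(t, 6, 2.5, 6) + 0.4,
    BEE = function(t) .tfBump(t, beeCentre, 2.6, 5.5) + 0.4,
    CAR = function(t) .tfBump(t, 2, 1.8, 7) + 0.3,
    UNK = function(t) .tfBump(t, 9, 5, 3) + 0.8)
}

#' Ground-truth TF mRNA and protein activity profiles
#'
#' Deterministic smooth profiles for the four TFs under one experimental
#' condition, with protein activities obtained by solving the translation
#' ODE at the stated degradation rates (protein initialized at the t=0
#' steady state f(0)/delta).
#'
#' @param condition 1 or 2.
#' @param gridTimes dense time grid (h) on which to evaluate.
#' @param delta TF protein degradation rates.
#' @return list with matrices \code{f} and \code{p} (grid x TF) and the grid.
#' @export
makeTFProfiles <- function(condition,
                           gridTimes = denseGrid(0, 18, 100L),
                           delta = .SYN_DELTA) {
  shapes <- .tfMRNAShapes(condition)
  f <- vapply(shapes, function(fn) fn(gridTimes), numeric(length(gridTimes)))
  p <- vapply(seq_along(shapes), function(i)
    solveTranslation(f[, i], gridTimes,
                     proteinParams(delta[i], p0 = f[1L, i] / delta[i])),
    numeric(length(gridTimes)))
  colnames(p) <- colnames(f) <- names(shapes)
  list(times = gridTimes, f = f, p = p)
}

#' Draw spike-and-slab interaction weights for the synthetic genes
#'
#' For the modelled TFs (ANT, BEE, CAR) each weight is zero with probability
#' 0.5 and otherwise N(0.5, 1); for the confounder UNK it is zero with
#' probability 0.75 and otherwise N(0.5, 1). Biases are N(0, 1). On average
#' a gene therefore has 1.75 regulators.
#'
#' @param nGenes number of genes.
#' @param seed integer seed.
#' @return list with weight matrix \code{W} (genes x 4 TFs) and bias vector
#'   \code{w0}.
#' @export
sampleWeights <- function(nGenes, seed = 1L) {
  set.seed(seed)
  zeroProb <- c(ANT = 0.5, BEE = 0.5, CAR = 0.5, UNK = 0.75)
  W <- vapply(zeroProb, function(q) {
    on <- stats::runif(nGenes) >= q
    ifelse(on, stats::rnorm(nGenes, mean = 0.5, sd = 1), 0)
  }, numeric(nGenes))
  rownames(W) <- .syntheticGeneIds(nGenes)
  list(W = W, w0 = stats::setNames(stats::rnorm(nGenes), rownames(W)))
}

## Two-piece log-normal sampler for the mRNA degradation rate: log d has
## median log(0.610) with separate lower/upper normal scales chosen so that
## the 5% and 95% quantiles hit 0.123 and 4.807 / h exactly.
.D_QUANTILES <- c(q05 = 0.123, q50 = 0.610, q95 = 4.807)

.sampleDegradation <- function(n) {
  mu <- log(.D_QUANTILES[["q50"]])
  z95 <- stats::qnorm(0.95)
  sdLow <- (mu - log(.D_QUANTILES[["q05"]])) / z95
  sdHigh <- (log(.D_QUANTILES[["q95"]]) - mu) / z95
  z <- stats::qnorm(stats::runif(n))
  exp(mu + ifelse(z < 0, sdLow, sdHigh) * z)
}

#' Draw kinetic parameters for the synthetic genes
#'
#' mRNA degradation rates follow a two-piece log-normal whose 5%, 50% and
#' 95% quantiles are (0.123, 0.610, 4.807)/h, emulating rates estimated
#' from real developmental expression data. Basal rate, sensitivity and
#' initial condition are log-normal with medians (0.1, 1.0, 0.5) and
#' log-scale sd 0.5.
#'
#' @param nGenes number of genes.
#' @param seed integer seed.
#' @return data.frame with columns \code{b}, \code{d}, \code{s}, \code{a}.
#' @export
sampleKinetics <- function(nGenes, seed = 1L) {
  set.seed(seed)
  data.frame(
    row.names = .syntheticGeneIds(nGenes),
    b = stats::rlnorm(nGenes, log(0.1), 0.5),
    d = .sampleDegradation(nGenes),
    s = stats::rlnorm(nGenes, log(1.0), 0.5),
    a = stats::rlnorm(nGenes, log(0.5), 0.5))
}

.syntheticGeneIds <- function(n) sprintf("g%04d", seq_len(n))

#' Flip training-network links at random
#'
#' Each entry of the binary training network is flipped independently with
#' the given probability, emulating an approximately known subnetwork.
#'
#' @param X binary genes x TFs matrix.
#' @param rate flip probability in [0, 1].
#' @param seed integer seed.
#' @return corrupted binary matrix of the same shape.
#' @export
corruptTrainingLinks <- function(X, rate = 0.15, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  set.seed(seed)
  flip <- matrix(stats::runif(length(X)) < rate, nrow(X), ncol(X))
  Xc <- X
  Xc[flip] <- 1L - Xc[flip]
  Xc
}

#' Simulate noisy observations from a synthetic ground truth
#'
#' Solves the transcription ODE for every gene under every requested
#' condition, evaluates gene and TF mRNA at the configured observation
#' times, and adds zero-mean Gaussian noise with variance
#' \code{noiseFactor} times the signal value; negative observations are
#' truncated to zero. Per-observation generating variances are emitted
#' alongside the values. Only the modelled TFs (ANT, BEE, CAR) contribute
#' TF mRNA rows; the confounder UNK drives the genes but is never observed.
#'
#' @param truth list as built by \code{\link{makeSyntheticBenchmark}}
#'   (weights, kinetics, TF profiles per condition).
#' @param config a \code{\link{syntheticConfig}}.
#' @param seed integer seed for the observation noise.
#' @return an \linkS4class{ExpressionTimeSeries}.
#' @export
simulateObservations <- function(truth, config, seed = config$seed) {
  set.seed(seed)
  times <- config$times
  nG <- nrow(truth$W)
  obsTF <- setdiff(.SYN_TFS, "UNK")
  valList <- list(); varList <- list(); condList <- integer()
  for (cond in config$conditions) {
    prof <- truth$profiles[[as.character(cond)]]
    M <- t(vapply(seq_len(nG), function(j) {
      rw <- responseWeights(truth$W[j, ], truth$w0[j])
      kp <- kineticParams(truth$kinetics$b[j], truth$kinetics$d[j],
                          truth$kinetics$s[j], truth$kinetics$a[j])
      solveTranscription(prof$p, prof$times, rw, kp, outTimes = times)
    }, numeric(length(times))))
    Ftf <- t(vapply(obsTF, function(tf)
      .interpGrid(prof$times, prof$f[, tf], times), numeric(length(times))))
    signal <- rbind(M, Ftf)
    rownames(signal) <- c(rownames(truth$W), obsTF)
    v <- config$noiseFactor * pmax(signal, 0)
    obs <- pmax(signal + stats::rnorm(length(signal), 0, sqrt(v)), 0)
    valList[[length(valList) + 1L]] <- obs
    varList[[length(varList) + 1L]] <- v
    condList <- c(condList, rep(cond, length(times)))
  }
  expressionTimeSeries(do.call(cbind, valList), do.call(cbind, varList),
                       time = rep(times, length(config$conditions)),
                       condition = condList, replicate = 1L,
                       tfNames = obsTF)
}

#' SyntheticBenchmark class
#'
#' Bundles a simulated \linkS4class{ExpressionTimeSeries} with its ground
#' truth: interaction weights, kinetics, TF profiles, the true training
#' network over the modelled TFs and its corrupted counterpart actually
#' handed to training.
#'
#' @aliases SyntheticBenchmark-class
#' @exportClass SyntheticBenchmark
setClass("SyntheticBenchmark",
         representation(expression = "ExpressionTimeSeries", truth = "list",
                        network = "matrix", corruptedNetwork = "matrix",
                        config = "list"))

setValidity("SyntheticBenchmark", function(object) {
  if (!all(object@network %in% 0:1)) return("network must be binary")
  if (!identical(dim(object@network), dim(object@corruptedNetwork)))
    return("network matrices must have identical shape")
  TRUE
})

setMethod("show", "SyntheticBenchmark", function(object) {
  cat("SyntheticBenchmark:", nrow(object@truth$W), "genes,",
      nrow(object@network), "training genes, conditions",
      paste(object@config$conditions, collapse = "+"),
      "( seed", object@config$seed, ")\n")
})

#' @describeIn makeSyntheticBenchmark the simulated observations.
#' @param x a \code{SyntheticBenchmark}.
#' @export
benchmarkExpression <- function(x) x@expression

#' @describeIn makeSyntheticBenchmark the corrupted training network handed
#'   to inference.
#' @export
trainingNetwork <- function(x) x@corruptedNetwork

#' @describeIn makeSyntheticBenchmark ground-truth binary structures over
#'   the modelled TFs for all genes (for evaluation).
#' @export
trueStructures <- function(x) {
  S <- (x@truth$W[, setdiff(.SYN_TFS, "UNK"), drop = FALSE] != 0) + 0L
  storage.mode(S) <- "integer"
  S
}

#' Generate a full synthetic benchmark
#'
#' Draws weights and kinetics, builds the deterministic TF profiles for the
#' requested conditions, simulates noisy observations, and corrupts the
#' training subnetwork links. All randomness derives from
#' \code{config$seed}.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return a \linkS4class{SyntheticBenchmark}.
#' @export
makeSyntheticBenchmark <- function(config = syntheticConfig()) {
  seeds <- .subSeeds(config$seed, 4L)
  wts <- sampleWeights(config$nGenes, seeds[1L])
  kin <- sampleKinetics(config$nGenes, seeds[2L])
  grid <- denseGrid(min(config$times), max(config$times), config$gridN)
  profiles <- lapply(stats::setNames(config$conditions,
                                     config$conditions), function(cond)
    makeTFProfiles(cond, grid, config$delta))
  truth <- list(W = wts$W, w0 = wts$w0, kinetics = kin, profiles = profiles)
  expr <- simulateObservations(truth, config, seed = seeds[3L])
  trainIds <- .syntheticGeneIds(config$nGenes)[seq_len(config$nTrain)]
  X <- (wts$W[trainIds, setdiff(.SYN_TFS, "UNK"), drop = FALSE] != 0) + 0L
  storage.mode(X) <- "integer"
  Xc <- corruptTrainingLinks(X, config$linkNoise, seeds[4L])
  new("SyntheticBenchmark", expression = expr, truth = truth,
      network = X, corruptedNetwork = Xc, config = unclass(config))
}
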