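## Prediction phase: for each test gene, approximate the Bayesian evidence
## p(y* | x*, Y) of every candidate structure x* in {0,1}^I by an annealed
## importance-sampling estimator, averaging over the posterior samples of
## the TF activities obtained in the training phase; then form posterior
## probabilities over structures, MAP structures and single/pair link
## marginals by Bayesian model averaging.

#' Prediction-phase configuration
#'
#' @param nTemp,nPart,nMove annealing rungs, particles and Metropolis moves
#'   per rung of the per-gene evidence estimate.
#' @param nActivitySamples how many stored TF-activity posterior samples to
#'   average the evidence over.
#' @param plugin if \code{TRUE}, use the posterior-mean TF activity instead
#'   of averaging over samples.
#' @param useAdaptive include a per-gene adaptive noise variance in the
#'   test-gene likelihood (robust prediction).
#' @param activationOnly constrain weights to be non-negative.
#' @param varFloor floor on per-observation noise variances.
#' @param seed integer seed; evidence values are deterministic given the
#'   seed and the gene's data (identical data give identical evidence).
#' @param cores parallel workers for per-gene scoring (results are
#'   independent of the worker count).
#' @return a list of class \code{PredictionConfig}.
#' @export
predictionConfig <- function(nTemp = 40L, nPart = 64L, nMove = 2L,
                             nActivitySamples = 10L, plugin = FALSE,
                             useAdaptive = FALSE, activationOnly = FALSE,
                             varFloor = 1e-3, seed = 1L, cores = 1L) {
  stopifnot(nTemp >= 2L, nPart >= 2L, nMove >= 1L, nActivitySamples >= 1L)
  structure(as.list(environment()), class = "PredictionConfig")
}

#' All candidate regulation structures
#'
#' @param tfn character vector of TF names.
#' @return a 2^I x I binary matrix, one row per structure, rownames the
#'   structure strings (e.g. \code{"101"}).
#' @export
allStructures <- function(tfn) {
  I <- length(tfn)
  S <- as.matrix(expand.grid(rep(list(0:1), I))[, I:1, drop = FALSE])
  S <- S[order(S %*% 2^((I - 1):0)), , drop = FALSE]
  dimnames(S) <- list(apply(S, 1L, paste, collapse = ""), tfn)
  storage.mode(S) <- "integer"
  S
}

## Log-likelihood of one gene's observations across series given a
## parameter vector e = (w[active], w0, lb, ld, ls, la[, lv]) and per-series
## log TF activities on the grid. Shared by prediction and the ML baseline.
.predGeneLL <- function(e, act, lpList, grid, iwList, vals, vars, useAd) {
  nA <- length(act)
  hh <- grid[2L] - grid[1L]
  ll <- 0
  for (s in seq_along(lpList)) {
    z <- if (nA) drop(lpList[[s]][, act, drop = FALSE] %*% e[seq_len(nA)]) +
      e[[nA + 1L]] else rep(e[[nA + 1L]], length(grid))
    G <- stats::plogis(z)
    m <- .odeStep(exp(e[[nA + 4L]]) * G, hh, exp(e[[nA + 3L]]),
                  exp(e[[nA + 5L]]), basal = exp(e[[nA + 2L]]))
    iw <- iwList[[s]]
    mu <- m[iw$lo] * (1 - iw$fr) + m[iw$hi] * iw$fr
    v <- vars[[s]] + if (useAd) exp(e[[nA + 6L]]) else 0
    ll <- ll - 0.5 * sum(log(2 * pi * v) + (vals[[s]] - mu)^2 / v)
  }
  ll
}

.predPrior <- function(e, nA, useAd, activationOnly) {
  if (nA && activationOnly && any(e[seq_len(nA)] < 0)) return(-Inf)
  pr <- sum(stats::dnorm(e[seq_len(nA + 1L)], 0, .PR_W_SD, log = TRUE)) +
    sum(stats::dnorm(e[nA + 2:5], 0, .PR_LKIN_SD, log = TRUE))
  if (useAd) {
    lv <- e[[nA + 6L]]
    pr <- pr + log(.PR_ADVAR_RATE) - .PR_ADVAR_RATE * exp(lv) + lv
  }
  pr
}

## Batched (one row per particle) versions of the test-gene likelihood and
## prior, used by the annealed evidence estimator. Columns of E are
## (w[active], w0, log b, log d, log s, log a[, log adaptiveVar]).
.predGeneLLBatch <- function(E, act, lpList, grid, iwList, vals, vars,
                             useAd) {
  nA <- length(act)
  N <- nrow(E); nG <- length(grid)
  hh <- grid[2L] - grid[1L]
  w0 <- E[, nA + 1L]
  b <- exp(E[, nA + 2L]); dd <- exp(E[, nA + 3L])
  sens <- exp(E[, nA + 4L]); a0 <- exp(E[, nA + 5L])
  adv <- if (useAd) exp(E[, nA + 6L]) else numeric(N)
  al <- exp(-dd * hh)
  cons <- -b / dd * expm1(-dd * hh)
  ll <- numeric(N)
  for (s in seq_along(lpList)) {
    Z <- if (nA) lpList[[s]][, act, drop = FALSE] %*%
      t(E[, seq_len(nA), drop = FALSE]) else matrix(0, nG, N)
    G <- plogis(Z + rep(w0, each = nG))
    sG <- G * rep(sens, each = nG)
    zz <- rbind(a0, sG[-nG, , drop = FALSE] * rep(al * (hh / 2),
                                                  each = nG - 1L) +
                  sG[-1L, , drop = FALSE] * (hh / 2) +
                  rep(cons, each = nG - 1L))
    m <- .Call(tfode_lin_recurse_mat, zz, al)
    iw <- iwList[[s]]
    mu <- m[iw$lo, , drop = FALSE] * (1 - iw$fr) +
      m[iw$lo + 1L, , drop = FALSE] * iw$fr
    v <- vars[[s]] + rep(adv, each = length(iw$fr))
    r <- vals[[s]] - mu
    ll <- ll - 0.5 * colSums(log(2 * pi * v) + r * r / v)
  }
  ll
}

.predPriorBatch <- function(E, nA, useAd, activationOnly) {
  pr <- rowSums(dnorm(E[, seq_len(nA + 1L), drop = FALSE], 0, .PR_W_SD,
                      log = TRUE)) +
    rowSums(dnorm(E[, nA + 2:5, drop = FALSE], 0, .PR_LKIN_SD, log = TRUE))
  if (useAd) {
    lv <- E[, nA + 6L]
    pr <- pr + log(.PR_ADVAR_RATE) - .PR_ADVAR_RATE * exp(lv) + lv
  }
  if (activationOnly && nA)
    pr[rowSums(E[, seq_len(nA), drop = FALSE] < 0) > 0] <- -Inf
  pr
}

## Evidence p(y* | x*) for one structure under one TF-activity sample,
## estimated by annealed importance sampling: particles start as prior
## draws, are annealed through tempered posteriors pi(eta) L(eta)^beta
## with Metropolis moves at each rung, and the averaged importance weights
## give an (unbiasedly weighted) marginal-likelihood estimate. Annealing
## follows the curved, ridge-shaped parameter posteriors these ODE models
## produce far more reliably than a single posterior-ordinate estimate.
.aisEvidence <- function(act, lpList, grid, iwList, vals, vars, useAd,
                         activationOnly, nTemp, nPart, nMove = 2L) {
  nA <- length(act)
  d <- nA + 5L + useAd
  E <- cbind(matrix(rnorm(nPart * (nA + 1L), 0, .PR_W_SD), nPart),
             matrix(rnorm(nPart * 4L, 0, .PR_LKIN_SD), nPart))
  if (activationOnly && nA)
    E[, seq_len(nA)] <- abs(E[, seq_len(nA), drop = FALSE])
  if (useAd) E <- cbind(E, log(stats::rexp(nPart, .PR_ADVAR_RATE)))
  sdBase <- c(rep(1, nA + 1L), rep(0.75, 4L), if (useAd) 0.75)
  ll <- .predGeneLLBatch(E, act, lpList, grid, iwList, vals, vars, useAd)
  lpr <- .predPriorBatch(E, nA, useAd, activationOnly)
  logw <- numeric(nPart)
  betas <- (seq_len(nTemp) / nTemp)^2
  prevB <- 0
  sc <- 1
  for (bta in betas) {
    logw <- logw + (bta - prevB) * ll
    for (mv in seq_len(nMove)) {
      E2 <- E + matrix(rnorm(nPart * d), nPart) *
        rep(sdBase * sc, each = nPart)
      lpr2 <- .predPriorBatch(E2, nA, useAd, activationOnly)
      ll2 <- .predGeneLLBatch(E2, act, lpList, grid, iwList, vals, vars,
                              useAd)
      lr <- lpr2 + bta * ll2 - lpr - bta * ll
      accept <- is.finite(lr) & log(runif(nPart)) < lr
      E[accept, ] <- E2[accept, , drop = FALSE]
      ll[accept] <- ll2[accept]; lpr[accept] <- lpr2[accept]
      sc <- sc * exp((mean(accept) - 0.3) * 0.25)
    }
    prevB <- bta
  }
  logMeanExp(logw)
}

## Assemble per-series observation pieces for a set of genes, aligned with
## the series stored in a TrainingPosterior.
.alignSeries <- function(data, tp, genes) {
  ser <- .seriesList(data[genes, , drop = FALSE])
  key <- function(cond, rep) paste(cond, rep, sep = "\r")
  want <- key(tp@series$condition, tp@series$replicate)
  have <- vapply(ser, function(s) key(s$condition, s$replicate),
                 character(1L))
  idx <- match(want, have)
  if (anyNA(idx))
    stop("test data lack a (condition, replicate) series present in training",
         call. = FALSE)
  ser[idx]
}

.activityIdx <- function(tp, cfg) {
  S <- nrow(tp@delta)
  if (cfg$plugin) return(NA_integer_)
  unique(round(seq(1L, S, length.out = min(cfg$nActivitySamples, S))))
}

## logP grids for one activity sample index (or the posterior mean).
.logPForSample <- function(tp, r) {
  lapply(tp@activity, function(se) {
    m <- vapply(se, function(a)
      if (is.na(r)) colMeans(a) else a[r, ], numeric(ncol(se[[1L]])))
    log(pmax(m, .P_FLOOR))
  })
}

#' Approximate log-evidence of one structure for one gene
#'
#' Approximates \code{log p(y* | x*, Y)} by annealed importance sampling
#' over the gene's parameters for each stored TF-activity sample, then
#' averages the per-sample evidences (log-mean-exp), integrating over the
#' training-phase uncertainty in the TF activities. Weights of TFs absent
#' from the structure are fixed at zero.
#'
#' @param data an \linkS4class{ExpressionTimeSeries} containing the gene.
#' @param gene gene id (single row of \code{data}).
#' @param x binary structure vector of length I (TF order of the posterior).
#' @param tp a \linkS4class{TrainingPosterior}.
#' @param config a \code{\link{predictionConfig}}.
#' @return scalar approximate log-evidence.
#' @export
scoreStructure <- function(data, gene, x, tp, config = predictionConfig()) {
  ser <- .alignSeries(data, tp, gene)
  if (any(vapply(ser, function(s) length(s$times), integer(1L)) < 2L))
    stop("at least 2 time points per series are required", call. = FALSE)
  ev <- .scoreGeneAllStructures(ser, gene, tp, config,
                                structures = matrix(as.integer(x), 1L))
  ev[1L]
}

.scoreGeneAllStructures <- function(ser, gene, tp, config,
                                    structures = allStructures(tp@tfNames)) {
  grid <- tp@gridTimes
  iwList <- lapply(ser, function(s) .lininterpWeights(grid, s$times))
  vals <- lapply(ser, function(s) s$values[gene, ])
  vars <- lapply(ser, function(s) pmax(s$vars[gene, ], config$varFloor))
  useAd <- isTRUE(config$useAdaptive)
  ridx <- .activityIdx(tp, config)
  lpAll <- lapply(ridx, function(r) .logPForSample(tp, r))
  seeds <- matrix(.subSeeds(config$seed, nrow(structures) * length(ridx)),
                  nrow(structures))
  vapply(seq_len(nrow(structures)), function(k) {
    act <- which(structures[k, ] == 1L)
    perSample <- vapply(seq_along(ridx), function(ri) {
      set.seed(seeds[k, ri])
      .aisEvidence(act, lpAll[[ri]], grid, iwList, vals, vars, useAd,
                   config$activationOnly, nTemp = config$nTemp,
                   nPart = config$nPart, nMove = config$nMove)
    }, numeric(1L))
    logMeanExp(perSample)
  }, numeric(1L))
}

#' Posterior probabilities over regulation structures
#'
#' Applies Bayes' rule over the discrete structure space: softmax of
#' log-evidence plus log-prior. The default structure prior is uniform
#' (each of the 2^I structures equally likely a priori).
#'
#' @param logEv numeric vector of log-evidences, one per structure.
#' @param prior optional prior probabilities (non-negative, summing to 1).
#' @return probabilities summing to 1.
#' @export
posteriorOverStructures <- function(logEv, prior = NULL) {
  if (all(logEv == -Inf)) stop("all structures have zero evidence",
                               call. = FALSE)
  if (any(is.na(logEv))) stop("non-finite log-evidence", call. = FALSE)
  lp <- if (is.null(prior)) logEv else {
    stopifnot(length(prior) == length(logEv), all(prior >= 0))
    logEv + log(prior / sum(prior))
  }
  w <- exp(lp - max(lp[is.finite(lp)]))
  w[!is.finite(w)] <- 0
  w / sum(w)
}

#' Maximum a posteriori structure
#'
#' Ties are broken in favour of fewer active links, then lexicographically
#' on the structure string, so a flat posterior yields the unregulated
#' structure.
#'
#' @param post posterior probabilities over structures.
#' @param structures matrix from \code{\link{allStructures}} (rows aligned
#'   with \code{post}).
#' @return the MAP binary structure vector (named by TF).
#' @export
mapStructure <- function(post, structures) {
  cand <- which(post >= max(post) - 1e-12)
  o <- order(rowSums(structures[cand, , drop = FALSE]),
             rownames(structures)[cand])
  structures[cand[o[1L]], ]
}

#' Marginal probability of a single regulatory link
#'
#' Bayesian model averaging: the posterior mass of all structures in which
#' TF \code{i} is active.
#'
#' @param post posterior probabilities over structures.
#' @param structures matrix from \code{\link{allStructures}}.
#' @param i TF index (or name).
#' @return scalar probability.
#' @export
marginalLinkProb <- function(post, structures, i) {
  if (is.character(i)) i <- match(i, colnames(structures))
  if (is.na(i) || i < 1L || i > ncol(structures))
    stop("TF index out of range", call. = FALSE)
  sum(post[structures[, i] == 1L])
}

#' @rdname marginalLinkProb
#' @param j second TF index for the pair marginal.
#' @export
pairMarginal <- function(post, structures, i, j) {
  if (is.character(i)) i <- match(i, colnames(structures))
  if (is.character(j)) j <- match(j, colnames(structures))
  if (anyNA(c(i, j)) || any(c(i, j) < 1L) || any(c(i, j) > ncol(structures)))
    stop("TF index out of range", call. = FALSE)
  sum(post[structures[, i] == 1L & structures[, j] == 1L])
}

#' Posterior over a restricted model set
#'
#' Renormalizes the evidence over a subset of models: for a single TF the
#' two models \{TF-only, null\}; for a pair the four models \{pair, each
#' partner alone, null\}.
#'
#' @param logEv named log-evidences (names = structure strings).
#' @param structures matrix from \code{\link{allStructures}}.
#' @param activeSet character or integer vector of one or two TFs.
#' @return named probabilities over the restricted model set (sum to 1).
#' @export
restrictedPosterior <- function(logEv, structures, activeSet) {
  if (length(activeSet) == 0L) stop("empty restriction", call. = FALSE)
  if (is.character(activeSet))
    activeSet <- match(activeSet, colnames(structures))
  I <- ncol(structures)
  mk <- function(idx) paste(as.integer(seq_len(I) %in% idx), collapse = "")
  models <- if (length(activeSet) == 1L)
    c(mk(activeSet), mk(integer()))
  else if (length(activeSet) == 2L)
    c(mk(activeSet), mk(activeSet[1L]), mk(activeSet[2L]), mk(integer()))
  else stop("activeSet must have one or two TFs", call. = FALSE)
  le <- logEv[models]
  stats::setNames(posteriorOverStructures(le), models)
}

#' ModelScoreTable class
#'
#' Per-gene results of the prediction phase: log-evidences and posterior
#' probabilities over all 2^I structures, the MAP structure, and single and
#' pair link marginals.
#'
#' @aliases ModelScoreTable-class
#' @exportClass ModelScoreTable
setClass("ModelScoreTable",
         representation(geneIds = "character", tfNames = "character",
                        structures = "matrix", logEvidence = "matrix",
                        posterior = "matrix", map = "character",
                        single = "matrix", pairs = "matrix",
                        method = "character"))

setValidity("ModelScoreTable", function(object) {
  if (!isTRUE(all.equal(unname(rowSums(object@posterior)),
                        rep(1, nrow(object@posterior)), tolerance = 1e-6)))
    return("posterior rows must sum to 1")
  TRUE
})

setMethod("show", "ModelScoreTable", function(object) {
  cat("ModelScoreTable (", object@method, "):", length(object@geneIds),
      "genes x", nrow(object@structures), "structures over TFs",
      paste(object@tfNames, collapse = ", "), "\n")
})

#' @describeIn predictRegulators single-link marginal probabilities
#'   (genes x TFs).
#' @param mst a \linkS4class{ModelScoreTable}.
#' @export
linkProbabilities <- function(mst) mst@single

#' @describeIn predictRegulators pair marginal probabilities (genes x TF
#'   pairs).
#' @export
pairProbabilities <- function(mst) mst@pairs

#' @describeIn predictRegulators MAP structure strings per gene.
#' @export
mapStructures <- function(mst) stats::setNames(mst@map, mst@geneIds)

.buildScoreTable <- function(geneIds, tfn, logEv, method,
                             prior = NULL) {
  S <- allStructures(tfn)
  post <- t(apply(logEv, 1L, posteriorOverStructures, prior = prior))
  map <- apply(post, 1L, function(pr)
    paste(mapStructure(pr, S), collapse = ""))
  single <- vapply(seq_along(tfn), function(i)
    post %*% (S[, i] == 1L), numeric(length(geneIds)))
  single <- matrix(single, ncol = length(tfn),
                   dimnames = list(geneIds, tfn))
  prs <- utils::combn(length(tfn), 2L)
  pairs <- apply(prs, 2L, function(ij)
    post %*% (S[, ij[1L]] == 1L & S[, ij[2L]] == 1L))
  pairs <- matrix(pairs, ncol = ncol(prs),
                  dimnames = list(geneIds,
                                  apply(prs, 2L, function(ij)
                                    paste(tfn[ij], collapse = "&"))))
  dimnames(logEv) <- dimnames(post) <- list(geneIds, rownames(S))
  new("ModelScoreTable", geneIds = geneIds, tfNames = tfn, structures = S,
      logEvidence = logEv, posterior = post, map = unname(map),
      single = single, pairs = pairs, method = method)
}

#' Genome-wide prediction of regulating TFs
#'
#' Scores every candidate structure for every requested gene by the
#' evidence approximation, then assembles posteriors, MAP
#' structures and link marginals. Genes are processed independently (and in
#' parallel if \code{config$cores > 1}); results do not depend on gene
#' order or worker count.
#'
#' @param data an \linkS4class{ExpressionTimeSeries} with the test genes.
#' @param tp a \linkS4class{TrainingPosterior}.
#' @param genes gene ids to score (default: all non-TF rows of
#'   \code{data}).
#' @param config a \code{\link{predictionConfig}}.
#' @param prior optional prior over the 2^I structures (default uniform).
#' @return a \linkS4class{ModelScoreTable}.
#' @export
predictRegulators <- function(data, tp, genes = targetIds(data),
                              config = predictionConfig(), prior = NULL) {
  ser <- .alignSeries(data, tp, genes)
  one <- function(g) {
    .scoreGeneAllStructures(ser, g, tp, config)
  }
  evList <- if (config$cores > 1L)
    parallel::mclapply(genes, one, mc.cores = config$cores)
  else lapply(genes, one)
  logEv <- do.call(rbind, evList)
  .buildScoreTable(genes, tp@tfNames, logEv, method = "bayes", prior = prior)
}

#' Ranked link predictions
#'
#' Flattens a score table into a ranked list of (gene, link, score) rows,
#' sorted by decreasing score with ties broken by gene id, ready for
#' enrichment evaluation.
#'
#' @param mst a \linkS4class{ModelScoreTable}.
#' @param type \code{"single"} for gene-TF links, \code{"pair"} for gene-TF
#'   -pair links.
#' @return data.frame with columns \code{gene}, \code{tf} (or \code{tf1},
#'   \code{tf2}) and \code{score}.
#' @export
linkRanking <- function(mst, type = c("single", "pair")) {
  type <- match.arg(type)
  M <- if (type == "single") mst@single else mst@pairs
  df <- data.frame(gene = rep(rownames(M), ncol(M)),
                   link = rep(colnames(M), each = nrow(M)),
                   score = as.vector(M))
  df <- df[order(-df$score, df$gene, df$link), ]
  if (type == "pair") {
    sp <- strsplit(df$link, "&", fixed = TRUE)
    df$tf1 <- vapply(sp, `[`, character(1L), 1L)
    df$tf2 <- vapply(sp, `[`, character(1L), 2L)
    df <- df[c("gene", "tf1", "tf2", "score")]
  } else names(df)[2L] <- "tf"
  rownames(df) <- NULL
  df
}

#' Write / read a ModelScoreTable as TSV
#'
#' One row per gene: log-evidences and posteriors for all structures
#' (columns \code{logE.<structure>} and \code{post.<structure>}), the MAP
#' structure string, single marginals (\code{p.<TF>}) and pair marginals
#' (\code{p.<TF1>&<TF2>}).
#'
#' @param mst a \linkS4class{ModelScoreTable}.
#' @param path TSV path.
#' @export
writeScores <- function(mst, path) {
  df <- data.frame(gene = mst@geneIds, method = mst@method,
                   stats::setNames(as.data.frame(mst@logEvidence),
                            paste0("logE.", colnames(mst@logEvidence))),
                   stats::setNames(as.data.frame(mst@posterior),
                            paste0("post.", colnames(mst@posterior))),
                   map = mst@map,
                   stats::setNames(as.data.frame(mst@single),
                            paste0("p.", colnames(mst@single))),
                   stats::setNames(as.data.frame(mst@pairs),
                            paste0("p.", colnames(mst@pairs))),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScores
#' @export
readScores <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = c(map = "character"),
                          stringsAsFactors = FALSE)
  le <- as.matrix(df[grep("^logE\\.", names(df))])
  structs <- sub("^logE\\.", "", colnames(le))
  I <- nchar(structs[1L])
  tfnCols <- grep("^p\\.[^&]+$", names(df), value = TRUE)
  tfn <- sub("^p\\.", "", tfnCols)
  colnames(le) <- structs
  post <- as.matrix(df[grep("^post\\.", names(df))])
  colnames(post) <- structs
  single <- as.matrix(df[tfnCols]); colnames(single) <- tfn
  pairCols <- grep("^p\\..*&", names(df), value = TRUE)
  pairs <- as.matrix(df[pairCols]); colnames(pairs) <- sub("^p\\.", "", pairCols)
  rownames(le) <- rownames(post) <- rownames(single) <- rownames(pairs) <- df$gene
  new("ModelScoreTable", geneIds = df$gene, tfNames = tfn,
      structures = allStructures(tfn), logEvidence = le, posterior = post,
      map = sprintf(paste0("%0", I, "d"), as.integer(df$map)),
      single = single, pairs = pairs, method = df$method[1L])
}
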