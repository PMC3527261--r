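## Training phase: Metropolis-within-Gibbs MCMC that jointly infers, from a
## subnetwork of approximately known structure,
##   - the latent TF mRNA functions f_i(t) per series (elliptical slice
##     sampling under the GP prior),
##   - protein degradation rates delta_i and initial protein levels,
##   - per-gene kinetics (b, d, s, a) and response weights (w, w0),
##   - GP hyperparameters, and optionally per-gene adaptive noise variances
##     used to robustify against unmodelled regulators.
## TF activities are condition/replicate specific; kinetics and weights are
## shared across series. All positive parameters are updated by adaptive
## random walks in log space.

## Prior scales (log-normal(0, 1.5^2) on positives, Normal(0, 2^2) on
## weights/bias, exponential with mean 0.05 on adaptive variances).
.PR_LKIN_SD <- 1.5
.PR_W_SD <- 2
.PR_ADVAR_RATE <- 20

#' Training-phase configuration
#'
#' @param iterations total MCMC iterations.
#' @param burnin iterations discarded (and used for proposal adaptation).
#' @param nStore number of thinned posterior samples to keep.
#' @param gridN dense-grid size for the ODE quadrature.
#' @param seed integer seed; chains are reproducible given the seed.
#' @param activationOnly constrain interaction weights to be non-negative
#'   (half-normal prior).
#' @param useAdaptive learn per-gene additive noise variances in addition to
#'   the fixed preprocessing variances (robustified model).
#' @param adaptiveThreshold adaptive-variance threshold of
#'   \code{\link{robustFilter}}.
#' @param varFloor floor applied to the supplied per-observation variances.
#' @param essMaxSteps maximum shrinkage steps per elliptical-slice update.
#' @param logEvery print block acceptance rates every this many iterations
#'   (0 = silent).
#' @return a list of class \code{TrainingConfig}.
#' @export
trainingConfig <- function(iterations = 30000L, burnin = 20000L,
                           nStore = 500L, gridN = 100L, seed = 1L,
                           activationOnly = FALSE, useAdaptive = FALSE,
                           adaptiveThreshold = 0.01, varFloor = 1e-3,
                           essMaxSteps = 30L, logEvery = 0L) {
  stopifnot(iterations > burnin, burnin >= 0, nStore >= 1, gridN >= 10)
  structure(as.list(environment()), class = "TrainingConfig")
}

#' TrainingPosterior class
#'
#' Posterior samples from the training phase: per-series TF protein
#' activities and mRNA functions on the dense grid, protein degradation
#' rates, per-gene kinetics and weights, adaptive variances, GP
#' hyperparameters, and block acceptance rates.
#'
#' @aliases TrainingPosterior-class
#' @exportClass TrainingPosterior
setClass("TrainingPosterior",
         representation(tfNames = "character", geneIds = "character",
                        gridTimes = "numeric", series = "data.frame",
                        activity = "list", fmrna = "list", delta = "matrix",
                        p0 = "list", geneParams = "list",
                        adaptiveVar = "matrix", hyper = "matrix",
                        network = "matrix", acceptance = "numeric",
                        config = "list"))

setValidity("TrainingPosterior", function(object) {
  if (nrow(object@delta) < 1L) return("at least one posterior sample needed")
  if (ncol(object@delta) != length(object@tfNames))
    return("delta sample dimension does not match TF count")
  if (any(vapply(object@activity, function(se)
        any(vapply(se, function(m) any(m < 0), logical(1L))), logical(1L))))
    return("activity samples must be non-negative")
  TRUE
})

setMethod("show", "TrainingPosterior", function(object) {
  cat("TrainingPosterior:", nrow(object@delta), "samples,",
      length(object@tfNames), "TFs,", length(object@geneIds),
      "training genes,", nrow(object@series), "series\n")
  dm <- apply(object@delta, 2, stats::median)
  cat("  posterior median protein degradation rates (1/h):",
      paste(sprintf("%s=%.3f", object@tfNames, dm), collapse = ", "), "\n")
})

#' @describeIn runTraining posterior samples (S x grid matrices) of TF
#'   protein activities for one series.
#' @param tp a \linkS4class{TrainingPosterior}.
#' @param series series index.
#' @export
activitySamples <- function(tp, series = 1L) tp@activity[[series]]

#' @describeIn runTraining posterior samples of protein degradation rates
#'   (S x I matrix).
#' @export
deltaSamples <- function(tp) tp@delta

#' @describeIn runTraining posterior mean adaptive variance per gene.
#' @export
adaptiveVariances <- function(tp) colMeans(tp@adaptiveVar)

## ---- internal sampler ----------------------------------------------------

.lininterpWeights <- function(grid, at) {
  h <- grid[2L] - grid[1L]
  pos <- (at - grid[1L]) / h
  lo <- pmin(pmax(floor(pos) + 1L, 1L), length(grid) - 1L)
  list(lo = lo, hi = lo + 1L, fr = pmin(pmax(pos - (lo - 1L), 0), 1))
}

.mcmcTrain <- function(ser, X, config) {
  set.seed(config$seed)
  tfn <- colnames(X); I <- length(tfn)
  geneIds <- rownames(X); J <- length(geneIds)
  nS <- length(ser)
  tAll <- unlist(lapply(ser, `[[`, "times"))
  grid <- denseGrid(min(tAll), max(tAll), config$gridN)
  nG <- length(grid)
  span <- diff(range(grid))
  hh <- grid[2L] - grid[1L]
  .tr <- function(fv, dl, q0) pmax(.odeStep(pmax(fv, 0), hh, dl, q0), 0)

  ## observation caches per series
  iw <- lapply(ser, function(s) .lininterpWeights(grid, s$times))
  valsG <- lapply(ser, function(s) s$values[geneIds, , drop = FALSE])
  varsG <- lapply(ser, function(s)
    pmax(s$vars[geneIds, , drop = FALSE], config$varFloor))
  valsT <- lapply(ser, function(s) s$values[tfn, , drop = FALSE])
  varsT <- lapply(ser, function(s)
    pmax(s$vars[tfn, , drop = FALSE], config$varFloor))

  active <- lapply(seq_len(J), function(j) which(X[j, ] == 1L))
  genesUsing <- lapply(seq_len(I), function(i)
    which(vapply(active, function(a) i %in% a, logical(1L))))

  ## state: latent functions, activities, parameters
  mf <- matrix(0, nS, I)     # GP prior means (per series, per TF)
  f <- p <- logP <- vector("list", nS)
  for (s in seq_len(nS)) {
    f[[s]] <- matrix(0, nG, I); dimnames(f[[s]]) <- list(NULL, tfn)
    for (i in seq_len(I)) {
      f[[s]][, i] <- stats::approx(ser[[s]]$times, valsT[[s]][i, ],
                                   xout = grid, rule = 2)$y
      mf[s, i] <- mean(valsT[[s]][i, ])
    }
    p[[s]] <- logP[[s]] <- matrix(0, nG, I)
  }
  delta <- rep(1, I)
  p0 <- matrix(0, nS, I)
  hyper <- cbind(variance = pmax(vapply(seq_len(I), function(i)
                   mean(vapply(seq_len(nS), function(s)
                     stats::var(valsT[[s]][i, ]), numeric(1L))),
                   numeric(1L)), 1e-2),
                 lengthscale = rep(span / 4, I))
  hyper0 <- hyper   # anchors the hyperprior medians at the data scale
  cholK <- lapply(seq_len(I), function(i)
    chol(gpCov(grid, gpHyperparams(hyper[i, 1L], hyper[i, 2L]))))

  .updP <- function(s, i) {
    p[[s]][, i] <<- .tr(f[[s]][, i], delta[i], p0[s, i])
    logP[[s]][, i] <<- log(pmax(p[[s]][, i], .P_FLOOR))
  }
  for (s in seq_len(nS)) for (i in seq_len(I)) {
    p0[s, i] <- max(f[[s]][1L, i], 0.05) / delta[i]
    .updP(s, i)
  }

  ## per-gene parameter vectors: active weights, bias, log kinetics
  useAd <- isTRUE(config$useAdaptive)
  eta <- lapply(seq_len(J), function(j) {
    a <- active[[j]]
    e <- c(rep(0.5, length(a)), 0, log(0.1), log(0.6), 0,
           log(max(valsG[[1L]][j, 1L], 0.05)))
    names(e) <- c(if (length(a)) paste0("w.", tfn[a]), "w0",
                  "lb", "ld", "ls", "la")
    if (useAd) e <- c(e, lv = log(0.01))
    e
  })

  ## mirror parameter vectors for vectorized multi-gene likelihoods
  Wfull <- matrix(0, I, J)
  w0v <- bv <- dv <- sv <- av <- advv <- numeric(J)
  .syncPars <- function(j, e) {
    a <- active[[j]]
    w <- numeric(I); if (length(a)) w[a] <- e[seq_along(a)]
    Wfull[, j] <<- w
    w0v[j] <<- e[["w0"]]; bv[j] <<- exp(e[["lb"]]); dv[j] <<- exp(e[["ld"]])
    sv[j] <<- exp(e[["ls"]]); av[j] <<- exp(e[["la"]])
    advv[j] <<- if (useAd) exp(e[["lv"]]) else 0
  }
  for (j in seq_len(J)) .syncPars(j, eta[[j]])
  valsGt <- lapply(valsG, t); varsGt <- lapply(varsG, t)

  ## log-likelihood of a set of genes in one series, vectorized across
  ## genes (columns); parameter arguments default to the current state
  .gLLvec <- function(s, jset, lp = logP[[s]],
                      W = Wfull[, jset, drop = FALSE], w0 = w0v[jset],
                      b = bv[jset], d = dv[jset], sens = sv[jset],
                      a0 = av[jset], adv = advv[jset]) {
    if (length(jset) == 0L) return(numeric(0))
    G <- plogis(lp %*% W + rep(w0, each = nG))
    sG <- G * rep(sens, each = nG)
    al <- exp(-d * hh)
    zz <- rbind(a0, sG[-nG, , drop = FALSE] * rep(al * (hh / 2),
                                                  each = nG - 1L) +
                  sG[-1L, , drop = FALSE] * (hh / 2) +
                  rep(-b / d * expm1(-d * hh), each = nG - 1L))
    m <- .Call(tfode_lin_recurse_mat, zz, al)
    lo <- iw[[s]]$lo; fr <- iw[[s]]$fr
    mu <- m[lo, , drop = FALSE] * (1 - fr) + m[lo + 1L, , drop = FALSE] * fr
    v <- varsGt[[s]][, jset, drop = FALSE] + rep(adv, each = length(fr))
    r <- valsGt[[s]][, jset, drop = FALSE] - mu
    -0.5 * colSums(log(2 * pi * v) + r * r / v)
  }
  .tLL <- function(s, i, fv) {
    mu <- {fc <- pmax(fv, 0)
           fc[iw[[s]]$lo] * (1 - iw[[s]]$fr) + fc[iw[[s]]$hi] * iw[[s]]$fr}
    -0.5 * sum(log(2 * pi * varsT[[s]][i, ]) +
               (valsT[[s]][i, ] - mu)^2 / varsT[[s]][i, ])
  }
  .gPrior <- function(j, e) {
    a <- active[[j]]
    wpart <- if (length(a)) {
      w <- e[seq_along(a)]
      if (config$activationOnly && any(w < 0)) return(-Inf)
      sum(stats::dnorm(w, 0, .PR_W_SD, log = TRUE))
    } else 0
    pr <- wpart + stats::dnorm(e[["w0"]], 0, .PR_W_SD, log = TRUE) +
      sum(stats::dnorm(e[c("lb", "ld", "ls", "la")], 0, .PR_LKIN_SD,
                       log = TRUE))
    if (useAd)
      pr <- pr + log(.PR_ADVAR_RATE) - .PR_ADVAR_RATE * exp(e[["lv"]]) +
        e[["lv"]]
    pr
  }

  geneLL <- matrix(0, nS, J); tfLL <- matrix(0, nS, I)
  for (s in seq_len(nS)) {
    geneLL[s, ] <- .gLLvec(s, seq_len(J))
    for (i in seq_len(I)) tfLL[s, i] <- .tLL(s, i, f[[s]][, i])
  }
  genePr <- vapply(seq_len(J), function(j) .gPrior(j, eta[[j]]), numeric(1L))

  ## adaptive random-walk scales and acceptance counters
  sGene <- rep(0.5, J); sDelta <- rep(0.3, I); sP0 <- matrix(0.3, nS, I)
  sHyp <- rep(0.3, I); sResc <- rep(0.5, I)
  ## per-gene proposal covariance, learned from the chain during burn-in
  dEta <- vapply(eta, length, integer(1L))
  covL <- lapply(dEta, function(d) diag(0.3 / sqrt(d), d))
  mSum <- lapply(dEta, function(d) numeric(d))
  xSum <- lapply(dEta, function(d) matrix(0, d, d))
  nCov <- 0L
  acc <- c(gene = 0, delta = 0, rescale = 0, p0 = 0, hyper = 0)
  try_ <- acc
  .adapt <- function(scale, accepted, it) {
    if (it > config$burnin) return(scale)
    exp(log(scale) + (accepted - 0.25) * min(0.05, 3 / sqrt(it)))
  }

  nKeep <- config$iterations - config$burnin
  thin <- max(1L, nKeep %/% config$nStore)
  keepIts <- seq(config$burnin + thin, config$iterations, by = thin)
  S <- length(keepIts)
  out <- list(
    activity = lapply(seq_len(nS), function(s)
      lapply(seq_len(I), function(i) matrix(0, S, nG))),
    fmrna = lapply(seq_len(nS), function(s)
      lapply(seq_len(I), function(i) matrix(0, S, nG))),
    delta = matrix(0, S, I, dimnames = list(NULL, tfn)),
    p0 = lapply(seq_len(nS), function(s)
      matrix(0, S, I, dimnames = list(NULL, tfn))),
    geneParams = lapply(seq_len(J), function(j)
      matrix(0, S, I + 5L + useAd,
             dimnames = list(NULL, c(paste0("w.", tfn), "w0",
                                     "b", "d", "s", "a",
                                     if (useAd) "adVar")))),
    adaptiveVar = matrix(0, S, J, dimnames = list(NULL, geneIds)),
    hyper = matrix(0, S, 2L * I,
                   dimnames = list(NULL, c(paste0("var.", tfn),
                                           paste0("ell.", tfn)))))
  keep <- 0L

  for (it in seq_len(config$iterations)) {
    ## (1) per-gene parameters: adaptive random walk whose proposal
    ## covariance tracks the per-gene posterior shape
    if (it <= config$burnin) {
      nCov <- nCov + 1L
      for (j in seq_len(J)) {
        mSum[[j]] <- mSum[[j]] + eta[[j]]
        xSum[[j]] <- xSum[[j]] + tcrossprod(eta[[j]])
      }
      if (it %% 250L == 0L && it >= 500L) {
        for (j in seq_len(J)) {
          mu <- mSum[[j]] / nCov
          Sg <- xSum[[j]] / nCov - tcrossprod(mu)
          Sg <- (2.38^2 / dEta[j]) * Sg + diag(1e-4, dEta[j])
          ck <- try(chol(Sg), silent = TRUE)
          if (!inherits(ck, "try-error")) covL[[j]] <- t(ck)
        }
      }
    }
    for (j in seq_len(J)) {
      e2 <- eta[[j]] + drop(covL[[j]] %*% rnorm(dEta[j])) * sGene[j]
      pr2 <- .gPrior(j, e2)
      okAcc <- FALSE
      if (is.finite(pr2)) {
        a <- active[[j]]
        w2 <- numeric(I); if (length(a)) w2[a] <- e2[seq_along(a)]
        ll2 <- vapply(seq_len(nS), function(s)
          .gLLvec(s, j, W = matrix(w2, I, 1L), w0 = e2[["w0"]],
                  b = exp(e2[["lb"]]), d = exp(e2[["ld"]]),
                  sens = exp(e2[["ls"]]), a0 = exp(e2[["la"]]),
                  adv = if (useAd) exp(e2[["lv"]]) else 0), numeric(1L))
        lrat <- sum(ll2) + pr2 - sum(geneLL[, j]) - genePr[j]
        if (log(runif(1L)) < lrat) {
          eta[[j]] <- e2; geneLL[, j] <- ll2; genePr[j] <- pr2
          .syncPars(j, e2)
          okAcc <- TRUE
        }
      }
      sGene[j] <- .adapt(sGene[j], okAcc, it)
      acc["gene"] <- acc["gene"] + okAcc; try_["gene"] <- try_["gene"] + 1
    }

    ## (2) latent TF mRNA functions: elliptical slice sampling
    for (s in seq_len(nS)) for (i in seq_len(I)) {
      gu <- genesUsing[[i]]
      curLL <- tfLL[s, i] + sum(geneLL[s, gu])
      fcur <- f[[s]][, i]
      nu <- drop(crossprod(cholK[[i]], rnorm(nG)))
      logy <- curLL + log(runif(1L))
      th <- runif(1L, 0, 2 * pi); thLo <- th - 2 * pi; thHi <- th
      for (step in seq_len(config$essMaxSteps)) {
        fprop <- mf[s, i] + (fcur - mf[s, i]) * cos(th) + nu * sin(th)
        pprop <- .tr(fprop, delta[i], p0[s, i])
        lp2 <- logP[[s]]; lp2[, i] <- log(pmax(pprop, .P_FLOOR))
        ll2 <- .gLLvec(s, gu, lp2)
        tll2 <- .tLL(s, i, fprop)
        if (tll2 + sum(ll2) > logy) {
          f[[s]][, i] <- fprop; p[[s]][, i] <- pprop; logP[[s]] <- lp2
          tfLL[s, i] <- tll2; geneLL[s, gu] <- ll2
          break
        }
        if (th < 0) thLo <- th else thHi <- th
        th <- runif(1L, thLo, thHi)
      }
    }

    ## (3) protein degradation rates (shared across series)
    for (i in seq_len(I)) {
      d2 <- delta[i] * exp(rnorm(1L) * sDelta[i])
      gu <- genesUsing[[i]]
      lp2 <- vector("list", nS); ll2 <- matrix(0, nS, length(gu))
      pp2 <- vector("list", nS)
      for (s in seq_len(nS)) {
        pp2[[s]] <- .tr(f[[s]][, i], d2, p0[s, i])
        lp2[[s]] <- logP[[s]]; lp2[[s]][, i] <- log(pmax(pp2[[s]], .P_FLOOR))
        ll2[s, ] <- .gLLvec(s, gu, lp2[[s]])
      }
      lrat <- sum(ll2) - sum(geneLL[, gu]) +
        dnorm(log(d2), 0, .PR_LKIN_SD, log = TRUE) -
        dnorm(log(delta[i]), 0, .PR_LKIN_SD, log = TRUE)
      okAcc <- log(runif(1L)) < lrat
      if (okAcc) {
        delta[i] <- d2
        for (s in seq_len(nS)) {
          p[[s]][, i] <- pp2[[s]]; logP[[s]] <- lp2[[s]]
          geneLL[s, gu] <- ll2[s, ]
        }
      }
      sDelta[i] <- .adapt(sDelta[i], okAcc, it)
      acc["delta"] <- acc["delta"] + okAcc; try_["delta"] <- try_["delta"] + 1
    }

    ## (3b) ridge move: rescale delta_i jointly with the initial protein
    ## level and the biases of its target genes. Protein amplitude scales
    ## roughly as 1/delta and a shift of log p is absorbed by the bias
    ## (G depends on w0 + sum w log p), so (log delta + log c,
    ## log p0 - log c, w0 + w log c) is a near-invariant shear (unit
    ## Jacobian) along which the posterior is hard to traverse by
    ## single-parameter walks.
    for (i in seq_len(I)) {
      lc <- rnorm(1L) * sResc[i]
      c2 <- exp(lc)
      d2 <- delta[i] * c2
      gu <- genesUsing[[i]]
      w0new <- w0v; w0new[gu] <- w0v[gu] + Wfull[i, gu] * lc
      lp2 <- vector("list", nS); pp2 <- vector("list", nS)
      llGu <- matrix(0, nS, length(gu))
      for (s in seq_len(nS)) {
        pp2[[s]] <- .tr(f[[s]][, i], d2, p0[s, i] / c2)
        lp2[[s]] <- logP[[s]]; lp2[[s]][, i] <- log(pmax(pp2[[s]], .P_FLOOR))
        llGu[s, ] <- .gLLvec(s, gu, lp2[[s]], w0 = w0new[gu])
      }
      lrat <- sum(llGu) - sum(geneLL[, gu]) +
        dnorm(log(d2), 0, .PR_LKIN_SD, log = TRUE) -
        dnorm(log(delta[i]), 0, .PR_LKIN_SD, log = TRUE) +
        sum(dnorm(log(p0[, i]) - lc, 0, .PR_LKIN_SD, log = TRUE) -
            dnorm(log(p0[, i]), 0, .PR_LKIN_SD, log = TRUE)) +
        sum(dnorm(w0new[gu], 0, .PR_W_SD, log = TRUE) -
            dnorm(w0v[gu], 0, .PR_W_SD, log = TRUE))
      okAcc <- is.finite(lrat) && log(runif(1L)) < lrat
      if (okAcc) {
        delta[i] <- d2
        p0[, i] <- p0[, i] / c2
        for (j in gu) {
          eta[[j]][["w0"]] <- w0new[j]
          genePr[j] <- .gPrior(j, eta[[j]])
        }
        w0v <- w0new
        for (s in seq_len(nS)) {
          p[[s]][, i] <- pp2[[s]]; logP[[s]] <- lp2[[s]]
          geneLL[s, gu] <- llGu[s, ]
        }
      }
      sResc[i] <- .adapt(sResc[i], okAcc, it)
      acc["rescale"] <- acc["rescale"] + okAcc
      try_["rescale"] <- try_["rescale"] + 1
    }

    ## (4) initial protein levels per series
    for (s in seq_len(nS)) for (i in seq_len(I)) {
      q2 <- p0[s, i] * exp(rnorm(1L) * sP0[s, i])
      gu <- genesUsing[[i]]
      pp2 <- .tr(f[[s]][, i], delta[i], q2)
      lp2 <- logP[[s]]; lp2[, i] <- log(pmax(pp2, .P_FLOOR))
      ll2 <- .gLLvec(s, gu, lp2)
      lrat <- sum(ll2) - sum(geneLL[s, gu]) +
        dnorm(log(q2), 0, .PR_LKIN_SD, log = TRUE) -
        dnorm(log(p0[s, i]), 0, .PR_LKIN_SD, log = TRUE)
      okAcc <- log(runif(1L)) < lrat
      if (okAcc) {
        p0[s, i] <- q2; p[[s]][, i] <- pp2; logP[[s]] <- lp2
        geneLL[s, gu] <- ll2
      }
      sP0[s, i] <- .adapt(sP0[s, i], okAcc, it)
      acc["p0"] <- acc["p0"] + okAcc; try_["p0"] <- try_["p0"] + 1
    }

    ## (5) GP hyperparameters per TF (shared across series)
    for (i in seq_len(I)) {
      h2 <- hyper[i, ] * exp(stats::rnorm(2L) * sHyp[i])
      ck2 <- try(chol(gpCov(grid, gpHyperparams(h2[1L], h2[2L]))),
                 silent = TRUE)
      okAcc <- FALSE
      if (!inherits(ck2, "try-error")) {
        lpOld <- lpNew <- 0
        for (s in seq_len(nS)) {
          lpOld <- lpOld + .gpLogPrior(f[[s]][, i], cholK[[i]], mf[s, i])
          lpNew <- lpNew + .gpLogPrior(f[[s]][, i], ck2, mf[s, i])
        }
        ## hyperpriors: broad log-normals (variance median = initial data
        ## variance, lengthscale median = span/4), sd 1 and 0.5 in log space
        hp <- function(h) stats::dnorm(log(h[1L]), log(hyper0[i, 1L]), 1,
                                       log = TRUE) +
          stats::dnorm(log(h[2L]), log(span / 4), 0.5, log = TRUE)
        lrat <- lpNew + hp(h2) - lpOld - hp(hyper[i, ])
        if (is.finite(lrat) && log(stats::runif(1L)) < lrat) {
          hyper[i, ] <- h2; cholK[[i]] <- ck2; okAcc <- TRUE
        }
      }
      sHyp[i] <- .adapt(sHyp[i], okAcc, it)
      acc["hyper"] <- acc["hyper"] + okAcc; try_["hyper"] <- try_["hyper"] + 1
    }

    if (config$logEvery > 0 && it %% config$logEvery == 0L)
      message(sprintf("iter %d | acc gene %.2f delta %.2f p0 %.2f hyper %.2f",
                      it, acc["gene"] / try_["gene"],
                      acc["delta"] / try_["delta"], acc["p0"] / try_["p0"],
                      acc["hyper"] / try_["hyper"]))

    if (keep < S && it == keepIts[keep + 1L]) {
      keep <- keep + 1L
      for (s in seq_len(nS)) for (i in seq_len(I)) {
        out$activity[[s]][[i]][keep, ] <- p[[s]][, i]
        out$fmrna[[s]][[i]][keep, ] <- f[[s]][, i]
      }
      out$delta[keep, ] <- delta
      for (s in seq_len(nS)) out$p0[[s]][keep, ] <- p0[s, ]
      for (j in seq_len(J)) {
        e <- eta[[j]]; a <- active[[j]]
        w <- numeric(I); w[a] <- e[seq_along(a)]
        out$geneParams[[j]][keep, ] <- c(w, e[["w0"]],
                                         exp(e[c("lb", "ld", "ls", "la")]),
                                         if (useAd) exp(e[["lv"]]))
        out$adaptiveVar[keep, j] <- if (useAd) exp(e[["lv"]]) else 0
      }
      out$hyper[keep, ] <- c(hyper[, 1L], hyper[, 2L])
    }
  }
  out$gridTimes <- grid
  out$acceptance <- acc / pmax(try_, 1)
  out
}

#' Run the training-phase MCMC
#'
#' Given expression time series for the training genes and the TF mRNAs,
#' plus a binary training network (weights are fixed to zero where the
#' network has no link), samples the joint posterior over latent TF
#' activities, protein degradation rates, gene kinetics/weights, GP
#' hyperparameters and (optionally) adaptive noise variances. Multiple
#' conditions/replicates are handled with series-specific TF activities and
#' shared kinetics and weights.
#'
#' @param data an \linkS4class{ExpressionTimeSeries} containing the TF mRNA
#'   rows and the training genes.
#' @param X binary training network, genes x TFs; rownames select the
#'   training genes, colnames must equal \code{tfNames(data)}.
#' @param config a \code{\link{trainingConfig}}.
#' @return a \linkS4class{TrainingPosterior}.
#' @export
runTraining <- function(data, X, config = trainingConfig()) {
  tfn <- tfNames(data)
  if (length(tfn) == 0L) stop("data has no TF mRNA rows", call. = FALSE)
  if (is.null(colnames(X)) || !setequal(colnames(X), tfn))
    stop("training network columns must match tfNames(data)", call. = FALSE)
  X <- X[, tfn, drop = FALSE]
  if (!all(X %in% c(0L, 1L))) stop("training network must be binary",
                                   call. = FALSE)
  if (nrow(X) == 0L) stop("empty training set", call. = FALSE)
  if (!all(rownames(X) %in% rownames(data)))
    stop("training genes missing from the expression data", call. = FALSE)
  sub <- data[c(rownames(X), tfn), ]
  ser <- .seriesList(sub)
  if (any(vapply(ser, function(s) length(s$times), integer(1L)) < 3L))
    stop("every series needs at least 3 time points", call. = FALSE)

  out <- .mcmcTrain(ser, X, config)
  sinfo <- data.frame(
    condition = vapply(ser, `[[`, numeric(1L), "condition"),
    replicate = vapply(ser, function(s) as.character(s$replicate),
                       character(1L)))
  new("TrainingPosterior", tfNames = tfn, geneIds = rownames(X),
      gridTimes = out$gridTimes, series = sinfo, activity = out$activity,
      fmrna = out$fmrna, delta = out$delta, p0 = out$p0,
      geneParams = stats::setNames(out$geneParams, rownames(X)),
      adaptiveVar = out$adaptiveVar, hyper = out$hyper,
      network = X, acceptance = out$acceptance, config = unclass(config))
}

#' Filter training genes by posterior adaptive variance
#'
#' Robustified training: genes whose posterior-mean adaptive variance
#' exceeds the threshold are judged not explained by the modelled TFs (for
#' example because an unmodelled regulator drives them) and are excluded;
#' the remainder is returned for a second, non-adaptive training run.
#'
#' @param tp a \linkS4class{TrainingPosterior} fit with
#'   \code{useAdaptive = TRUE}.
#' @param threshold adaptive-variance threshold (default 0.01, chosen to be
#'   below typical preprocessing noise variances).
#' @return character vector of retained gene ids.
#' @export
robustFilter <- function(tp, threshold = 0.01) {
  if (threshold < 0) stop("threshold must be non-negative", call. = FALSE)
  if (!isTRUE(tp@config$useAdaptive))
    stop("posterior was not trained with useAdaptive = TRUE", call. = FALSE)
  av <- adaptiveVariances(tp)
  tp@geneIds[av <= threshold]
}
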