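## Comparison methods: a maximum-likelihood analogue of the Bayesian
## pipeline (point estimates everywhere, maximized likelihood in place of
## evidence, TF activities driven by piecewise-linear interpolation of the
## TF mRNA observations), exhaustive linear-regression model selection by
## cross-validation, and the Inferelator weight-combination ranking rule.

#' ML-baseline configuration
#'
#' @param gridN dense-grid size for the ODE quadrature.
#' @param restarts random optimizer restarts (first start is deterministic).
#' @param seed seed for the random restarts.
#' @param activationOnly constrain weights to be non-negative.
#' @param varFloor floor on per-observation noise variances.
#' @param maxit iteration cap per \code{nlminb} call.
#' @return a list of class \code{MLConfig}.
#' @export
mlConfig <- function(gridN = 100L, restarts = 2L, seed = 1L,
                     activationOnly = FALSE, varFloor = 1e-3,
                     maxit = 200L) {
  structure(as.list(environment()), class = "MLConfig")
}

## piecewise-linear TF mRNA interpolants on the dense grid, per series
.plinF <- function(ser, tfn, grid) {
  lapply(ser, function(s)
    vapply(tfn, function(tf)
      stats::approx(s$times, pmax(s$values[tf, ], 0), xout = grid,
                    rule = 2)$y, numeric(length(grid))))
}

#' Maximum-likelihood training of TF activities
#'
#' The deterministic counterpart of the training phase: TF mRNA functions
#' are piecewise-linear interpolants of the observations, protein
#' activities follow from the translation ODE, and the protein degradation
#' rates, initial protein levels and all per-gene parameters are fitted
#' jointly by bounded quasi-Newton optimization with random restarts,
#' maximizing the likelihood of the training genes.
#'
#' @param data an \linkS4class{ExpressionTimeSeries} with TF rows and
#'   training genes.
#' @param X binary training network (genes x TFs).
#' @param config an \code{\link{mlConfig}}.
#' @return list of class \code{MLTrainedActivities}: per-series activity
#'   matrices \code{p} on the grid, \code{delta}, \code{logLik},
#'   \code{converged}.
#' @export
mlTrainActivities <- function(data, X, config = mlConfig()) {
  tfn <- tfNames(data)
  X <- X[, tfn, drop = FALSE]
  sub <- data[c(rownames(X), tfn), ]
  ser <- .seriesList(sub)
  tAll <- unlist(lapply(ser, `[[`, "times"))
  grid <- denseGrid(min(tAll), max(tAll), config$gridN)
  fList <- .plinF(ser, tfn, grid)
  iwList <- lapply(ser, function(s) .lininterpWeights(grid, s$times))
  I <- length(tfn); J <- nrow(X); nS <- length(ser)
  active <- lapply(seq_len(J), function(j) which(X[j, ] == 1L))
  vals <- lapply(seq_len(J), function(j)
    lapply(ser, function(s) s$values[rownames(X)[j], ]))
  vars <- lapply(seq_len(J), function(j)
    lapply(ser, function(s) pmax(s$vars[rownames(X)[j], ], config$varFloor)))

  nGeneParBase <- vapply(active, length, integer(1L)) + 5L
  offs <- c(0L, cumsum(nGeneParBase))
  nPar <- I + nS * I + offs[J + 1L]

  unpack <- function(th) {
    list(ldelta = th[seq_len(I)],
         lp0 = matrix(th[I + seq_len(nS * I)], nS, I),
         genes = lapply(seq_len(J), function(j)
           th[I + nS * I + offs[j] + seq_len(nGeneParBase[j])]))
  }
  negll <- function(th) {
    u <- unpack(th)
    lpList <- lapply(seq_len(nS), function(s) {
      p <- vapply(seq_len(I), function(i)
        solveTranslation(fList[[s]][, i], grid,
                         proteinParams(exp(u$ldelta[i]),
                                       exp(u$lp0[s, i]))),
        numeric(length(grid)))
      log(pmax(p, .P_FLOOR))
    })
    ll <- 0
    for (j in seq_len(J))
      ll <- ll + .predGeneLL(u$genes[[j]], active[[j]], lpList, grid,
                             iwList, vals[[j]], vars[[j]], useAd = FALSE)
    if (!is.finite(ll)) 1e10 else -ll
  }
  start0 <- c(rep(0, I), rep(0, nS * I),
              unlist(lapply(seq_len(J), function(j)
                c(rep(0.5, length(active[[j]])), 0, log(0.1), log(0.6), 0,
                  log(max(vals[[j]][[1L]][1L], 0.05))))))
  lower <- rep(-10, nPar); upper <- rep(10, nPar)
  if (config$activationOnly) {
    wpos <- I + nS * I + unlist(lapply(seq_len(J), function(j)
      if (length(active[[j]])) offs[j] + seq_along(active[[j]])))
    lower[wpos] <- 0
  }
  set.seed(config$seed)
  starts <- c(list(start0), lapply(seq_len(config$restarts - 1L), function(k)
    start0 + stats::rnorm(nPar, 0, 0.3)))
  fits <- lapply(starts, function(st)
    stats::nlminb(pmin(pmax(st, lower), upper), negll, lower = lower,
                  upper = upper,
                  control = list(iter.max = config$maxit,
                                 eval.max = 4L * config$maxit)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1L), "objective"))]]
  u <- unpack(best$par)
  pList <- lapply(seq_len(nS), function(s)
    vapply(seq_len(I), function(i)
      solveTranslation(fList[[s]][, i], grid,
                       proteinParams(exp(u$ldelta[i]), exp(u$lp0[s, i]))),
      numeric(length(grid))))
  for (s in seq_len(nS)) colnames(pList[[s]]) <- tfn
  geneEstimates <- lapply(seq_len(J), function(j) {
    e <- u$genes[[j]]
    w <- stats::setNames(numeric(I), tfn)
    if (length(active[[j]])) w[active[[j]]] <- e[seq_along(active[[j]])]
    c(w, w0 = e[[length(active[[j]]) + 1L]],
      b = exp(e[[length(active[[j]]) + 2L]]),
      d = exp(e[[length(active[[j]]) + 3L]]),
      s = exp(e[[length(active[[j]]) + 4L]]),
      a = exp(e[[length(active[[j]]) + 5L]]))
  })
  names(geneEstimates) <- rownames(X)
  series <- data.frame(
    condition = vapply(ser, `[[`, numeric(1L), "condition"),
    replicate = vapply(ser, function(s) as.character(s$replicate),
                       character(1L)))
  structure(list(tfNames = tfn, gridTimes = grid, p = pList,
                 delta = stats::setNames(exp(u$ldelta), tfn),
                 geneEstimates = geneEstimates,
                 series = series, logLik = -best$objective,
                 converged = best$convergence == 0L,
                 config = unclass(config)),
            class = "MLTrainedActivities")
}

#' Maximum-likelihood structure scoring
#'
#' For each gene and each candidate structure, maximizes the likelihood
#' over the gene parameters (multi-start bounded optimization) and uses the
#' maximized log-likelihood in place of the Bayesian evidence; posteriors,
#' MAP structures and link marginals are then formed exactly as in the
#' Bayesian case.
#'
#' @param data an \linkS4class{ExpressionTimeSeries} with the test genes.
#' @param fit an \code{MLTrainedActivities} from
#'   \code{\link{mlTrainActivities}}.
#' @param genes gene ids to score.
#' @param config an \code{\link{mlConfig}}.
#' @return a \linkS4class{ModelScoreTable} with \code{method = "ml"}.
#' @export
mlScoreStructures <- function(data, fit, genes = targetIds(data),
                              config = mlConfig()) {
  tfn <- fit$tfNames
  grid <- fit$gridTimes
  ser <- .seriesList(data[genes, , drop = FALSE])
  key <- function(cond, rep) paste(cond, rep, sep = "\r")
  idx <- match(key(fit$series$condition, fit$series$replicate),
               vapply(ser, function(s) key(s$condition, s$replicate),
                      character(1L)))
  if (anyNA(idx)) stop("series mismatch between fit and data", call. = FALSE)
  ser <- ser[idx]
  iwList <- lapply(ser, function(s) .lininterpWeights(grid, s$times))
  lpList <- lapply(fit$p, function(pm) log(pmax(pm, .P_FLOOR)))
  S <- allStructures(tfn)
  set.seed(config$seed)
  restartNoise <- matrix(stats::rnorm(config$restarts * 32L, 0, 0.5),
                         config$restarts)
  logEv <- t(vapply(genes, function(g) {
    vals <- lapply(ser, function(s) s$values[g, ])
    vars <- lapply(ser, function(s) pmax(s$vars[g, ], config$varFloor))
    a0 <- log(max(vals[[1L]][1L], 0.05))
    vapply(seq_len(nrow(S)), function(k) {
      act <- which(S[k, ] == 1L); nA <- length(act)
      npar <- nA + 5L
      st0 <- c(rep(0.5, nA), 0, log(0.1), log(0.6), 0, a0)
      lower <- rep(-10, npar); upper <- rep(10, npar)
      if (config$activationOnly && nA) lower[seq_len(nA)] <- 0
      obj <- function(e) {
        v <- .predGeneLL(e, act, lpList, grid, iwList, vals, vars, FALSE)
        if (is.finite(v)) -v else 1e10
      }
      best <- Inf
      for (r in seq_len(config$restarts)) {
        st <- if (r == 1L) st0 else st0 + restartNoise[r, seq_len(npar)]
        ft <- stats::nlminb(pmin(pmax(st, lower), upper), obj,
                            lower = lower, upper = upper,
                            control = list(iter.max = config$maxit,
                                           eval.max = 4L * config$maxit))
        best <- min(best, ft$objective)
      }
      -best
    }, numeric(1L))
  }, numeric(nrow(S))))
  .buildScoreTable(genes, tfn, logEv, method = "ml")
}

#' Exhaustive linear-regression model selection by cross-validation
#'
#' Regresses the gene's observed mRNA on the observed TF mRNAs
#' (\code{m = sum_i w_i f_i + w0 + noise}), enumerating all 2^I subsets of
#' TFs and selecting the subset with the smallest cross-validated MSE.
#' Folds are time points: fold n holds out the n-th time point in every
#' series (leave-one-time-point-out).
#'
#' @param data an \linkS4class{ExpressionTimeSeries}.
#' @param genes gene ids to analyse.
#' @return data.frame, one row per gene: the selected active set (structure
#'   string), cross-validated MSE (\code{cvMSE}, the gene ranking score:
#'   smaller = better explained), and refitted weights/bias columns.
#' @export
regressionSelect <- function(data, genes = targetIds(data)) {
  tfn <- tfNames(data)
  ser <- .seriesList(data[c(genes, tfn), ])
  nT <- vapply(ser, function(s) length(s$times), integer(1L))
  if (any(nT < 3L)) stop("at least 3 time points required", call. = FALSE)
  Fobs <- do.call(rbind, lapply(ser, function(s) t(s$values[tfn, , drop = FALSE])))
  foldId <- unlist(lapply(ser, function(s) seq_along(s$times)))
  S <- allStructures(tfn)
  res <- lapply(genes, function(g) {
    y <- unlist(lapply(ser, function(s) s$values[g, ]))
    cv <- vapply(seq_len(nrow(S)), function(k) {
      act <- which(S[k, ] == 1L)
      Xd <- cbind(1, Fobs[, act, drop = FALSE])
      errs <- vapply(sort(unique(foldId)), function(fold) {
        tr <- foldId != fold
        ft <- stats::lm.fit(Xd[tr, , drop = FALSE], y[tr])
        cf <- ifelse(is.na(ft$coefficients), 0, ft$coefficients)
        mean((y[!tr] - drop(Xd[!tr, , drop = FALSE] %*% cf))^2)
      }, numeric(1L))
      mean(errs)
    }, numeric(1L))
    k <- which.min(cv)
    act <- which(S[k, ] == 1L)
    ft <- stats::lm.fit(cbind(1, Fobs[, act, drop = FALSE]), y)
    w <- stats::setNames(numeric(length(tfn)), tfn)
    w[act] <- ft$coefficients[-1L]
    c(list(gene = g, structure = rownames(S)[k], cvMSE = cv[k],
           w0 = unname(ft$coefficients[1L])), as.list(w))
  })
  out <- do.call(rbind.data.frame, res)
  out[order(out$cvMSE, out$gene), ]
}

#' Inferelator weight-combination score for a TF pair
#'
#' Combines the absolute regression weights of two single-TF terms
#' (\code{beta1}, \code{beta2}) and their interaction term (\code{beta3})
#' into one pair confidence: \code{max(|beta3|, min(|beta1|, |beta2|))}.
#'
#' @param beta1,beta2,beta3 finite regression weights.
#' @return scalar pair score.
#' @export
inferelatorCombine <- function(beta1, beta2, beta3) {
  .assertFinite(c(beta1, beta2, beta3), "betas")
  pmax(abs(beta3), pmin(abs(beta1), abs(beta2)))
}

#' Rank links from an Inferelator weight table
#'
#' Re-ranks user-supplied Inferelator output. The table has columns
#' \code{gene}, \code{term}, \code{beta} where a term is either a single TF
#' name or \code{"TF1:TF2"} for an interaction. The single-TF score is the
#' maximum |beta| over all terms containing that TF; the pair score follows
#' \code{\link{inferelatorCombine}}.
#'
#' @param tbl data.frame with columns gene, term, beta.
#' @param tfn TF names.
#' @return list with ranked \code{single} and \code{pair} data.frames.
#' @export
inferelatorRank <- function(tbl, tfn) {
  stopifnot(all(c("gene", "term", "beta") %in% names(tbl)))
  .assertFinite(tbl$beta, "betas")
  parts <- strsplit(as.character(tbl$term), ":", fixed = TRUE)
  genes <- unique(tbl$gene)
  getBeta <- function(g, term) {
    hit <- tbl$gene == g &
      vapply(parts, function(p) setequal(p, term), logical(1L))
    if (any(hit)) max(abs(tbl$beta[hit])) else 0
  }
  single <- do.call(rbind, lapply(genes, function(g) {
    sc <- vapply(tfn, function(tf) {
      hit <- tbl$gene == g & vapply(parts, function(p) tf %in% p, logical(1L))
      if (any(hit)) max(abs(tbl$beta[hit])) else 0
    }, numeric(1L))
    data.frame(gene = g, tf = tfn, score = unname(sc))
  }))
  prs <- utils::combn(tfn, 2L)
  pair <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene = g, tf1 = prs[1L, ], tf2 = prs[2L, ],
               score = vapply(seq_len(ncol(prs)), function(q)
                 inferelatorCombine(getBeta(g, prs[1L, q]),
                                    getBeta(g, prs[2L, q]),
                                    getBeta(g, prs[, q])), numeric(1L)))))
  single <- single[order(-single$score, single$gene), ]
  pair <- pair[order(-pair$score, pair$gene), ]
  rownames(single) <- rownames(pair) <- NULL
  list(single = single, pair = pair)
}
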