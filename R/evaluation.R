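## Evaluation: ROC curves against a ground-truth link matrix, enrichment of
## top-ranked predictions against an independent binary validation matrix
## with hypergeometric significance, and bootstrap comparison of ranking
## methods.

#' ROC curve and AUC for link predictions
#'
#' Standard threshold-sweep ROC with tied scores grouped; AUC by the
#' trapezoid rule.
#'
#' @param scores numeric prediction scores (higher = more confident link).
#' @param truth binary ground-truth labels (1 = true link).
#' @return list with \code{points} (data.frame fpr, tpr) and \code{auc}.
#' @export
rocCurve <- function(scores, truth) {
  truth <- as.integer(truth)
  if (length(unique(truth)) < 2L)
    stop("truth must contain at least one positive and one negative",
         call. = FALSE)
  r <- pROC::roc(response = truth, predictor = scores, quiet = TRUE,
                 levels = c(0L, 1L), direction = "<")
  pts <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), ]
  rownames(pts) <- NULL
  list(points = pts, auc = as.numeric(r$auc))
}

## correctness of ranked prediction rows against a validation matrix
.rankedCorrect <- function(ranked, V, rule) {
  gi <- match(ranked$gene, rownames(V))
  if (anyNA(gi)) stop("ranked genes missing from the validation matrix",
                      call. = FALSE)
  switch(rule,
    single = V[cbind(gi, match(ranked$tf, colnames(V)))] == 1L,
    pair = V[cbind(gi, match(ranked$tf1, colnames(V)))] == 1L &
           V[cbind(gi, match(ranked$tf2, colnames(V)))] == 1L,
    `map-exact` = vapply(seq_len(nrow(ranked)), function(r) {
      prof <- as.integer(strsplit(ranked$structure[r], "")[[1L]])
      all(V[gi[r], ] == prof)
    }, logical(1L)),
    `map-positive` = vapply(seq_len(nrow(ranked)), function(r) {
      prof <- as.integer(strsplit(ranked$structure[r], "")[[1L]])
      all(V[gi[r], prof == 1L] == 1L)
    }, logical(1L)),
    stop("unknown correctness rule: ", rule, call. = FALSE))
}

#' Enrichment of top-ranked predictions with hypergeometric significance
#'
#' For each cutoff n, reports the fraction of the n top-ranked predictions
#' that are supported by the validation matrix, together with the
#' upper-tail hypergeometric p-value of drawing that many supported
#' predictions among n from the full ranked population.
#'
#' @param ranked ranked predictions (data.frame from
#'   \code{\link{linkRanking}}, or with a \code{structure} column for the
#'   MAP-based rules), best first.
#' @param V binary validation matrix (genes x TFs), e.g. ChIP-derived.
#' @param cutoffs vector of list-prefix sizes to evaluate.
#' @param rule correctness rule: \code{"single"} (the predicted TF is
#'   supported), \code{"pair"} (both TFs supported), \code{"map-exact"}
#'   (the predicted binding profile matches exactly), or
#'   \code{"map-positive"} (all predicted regulators are supported).
#' @param excludeUnvalidated drop genes with an all-zero validation row
#'   before evaluating.
#' @return data.frame with columns cutoff, nCorrect, enrichment, pValue.
#' @export
enrichmentAtCutoffs <- function(ranked, V, cutoffs,
                                rule = c("single", "pair", "map-exact",
                                         "map-positive"),
                                excludeUnvalidated = FALSE) {
  rule <- match.arg(rule)
  if (length(V) == 0L || is.null(rownames(V)))
    stop("empty validation matrix", call. = FALSE)
  if (excludeUnvalidated) {
    keep <- rownames(V)[rowSums(V) > 0L]
    ranked <- ranked[ranked$gene %in% keep, , drop = FALSE]
  }
  if (any(cutoffs > nrow(ranked)))
    stop("cutoff exceeds the ranked list length", call. = FALSE)
  ok <- .rankedCorrect(ranked, V, rule)
  N <- length(ok); K <- sum(ok)
  out <- lapply(cutoffs, function(n) {
    k <- sum(ok[seq_len(n)])
    data.frame(cutoff = n, nCorrect = k, enrichment = k / n,
               pValue = stats::phyper(k - 1L, K, N - K, n,
                                      lower.tail = FALSE))
  })
  do.call(rbind, out)
}

#' Bootstrap comparison of two ranking methods
#'
#' Resamples the validated gene set with replacement; in each fold the two
#' ranked lists are restricted to the resampled genes (with multiplicity,
#' preserving rank order), top-k enrichment is recomputed for both, and the
#' fraction of folds in which method A beats method B is tabulated (ties
#' count 0.5 to each).
#'
#' @param rankedA,rankedB ranked predictions of the two methods.
#' @param V binary validation matrix.
#' @param cutoffs top-k sizes to compare at.
#' @param nBoot number of bootstrap folds (default 10000).
#' @param seed integer seed; folds are reproducible.
#' @param rule correctness rule, as in \code{\link{enrichmentAtCutoffs}}.
#' @return data.frame with columns cutoff and winFracA.
#' @export
bootstrapCompare <- function(rankedA, rankedB, V, cutoffs, nBoot = 10000L,
                             seed = 1L,
                             rule = c("single", "pair", "map-exact",
                                      "map-positive")) {
  rule <- match.arg(rule)
  stopifnot(nBoot >= 1L)
  genes <- rownames(V)
  okA <- .rankedCorrect(rankedA, V, rule)
  okB <- .rankedCorrect(rankedB, V, rule)
  giA <- match(rankedA$gene, genes)
  giB <- match(rankedB$gene, genes)
  set.seed(seed)
  wins <- matrix(0, nBoot, length(cutoffs))
  for (b in seq_len(nBoot)) {
    cnt <- tabulate(sample.int(length(genes), replace = TRUE),
                    nbins = length(genes))
    topEnr <- function(gi, ok) {
      keep <- rep.int(seq_along(gi), cnt[gi])
      vapply(cutoffs, function(k)
        if (length(keep) >= k) mean(ok[keep[seq_len(k)]]) else NA_real_,
        numeric(1L))
    }
    eA <- topEnr(giA, okA); eB <- topEnr(giB, okB)
    wins[b, ] <- ifelse(is.na(eA) | is.na(eB), NA,
                        (eA > eB) + 0.5 * (eA == eB))
  }
  data.frame(cutoff = cutoffs, winFracA = colMeans(wins, na.rm = TRUE))
}
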