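## ExpressionTimeSeries: container for observed mRNA time series. Rows are
## genes (including the TF mRNA rows), columns are individual observations
## (condition x replicate x time), with a matching per-observation noise
## variance assay from upstream preprocessing.

#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

#' ExpressionTimeSeries class
#'
#' A \linkS4class{SummarizedExperiment} holding gene expression time-series
#' observations: an \code{exprs} assay of measured values and a \code{var}
#' assay of per-observation noise variances, with \code{condition},
#' \code{replicate} and \code{time} (hours) in the column data. Rows
#' corresponding to TF mRNA measurements are named in
#' \code{metadata(x)$tfNames}.
#'
#' @aliases ExpressionTimeSeries-class
#' @exportClass ExpressionTimeSeries
setClass("ExpressionTimeSeries", contains = "SummarizedExperiment")

setValidity("ExpressionTimeSeries", function(object) {
  msg <- NULL
  if (!all(c("exprs", "var") %in% names(assays(object))))
    msg <- c(msg, "assays 'exprs' and 'var' are required")
  cd <- colData(object)
  need <- c("condition", "replicate", "time")
  if (!all(need %in% names(cd)))
    msg <- c(msg, "colData must contain condition, replicate and time")
  else if (!is.numeric(cd$time) || any(!is.finite(cd$time)))
    msg <- c(msg, "time must be finite numeric hours")
  if ("var" %in% names(assays(object)) &&
      any(assay(object, "var") < 0, na.rm = TRUE))
    msg <- c(msg, "noise variances must be non-negative")
  if (is.null(rownames(object)))
    msg <- c(msg, "rows (genes) must be named")
  tf <- metadata(object)$tfNames
  if (!is.null(tf) && !all(tf %in% rownames(object)))
    msg <- c(msg, "tfNames must name rows of the object")
  if (is.null(msg)) TRUE else msg
})

#' Construct an ExpressionTimeSeries
#'
#' @param values genes x observations matrix of expression values (rownames
#'   are gene ids).
#' @param variances matching matrix of per-observation noise variances; if
#'   \code{NULL}, a constant \code{varFloor} is used.
#' @param time,condition,replicate per-column observation annotations.
#' @param tfNames character vector of row names holding TF mRNA series.
#' @param varFloor variance used when \code{variances} is missing.
#' @return an \linkS4class{ExpressionTimeSeries}.
#' @export
expressionTimeSeries <- function(values, variances = NULL, time,
                                 condition = 1L, replicate = 1L,
                                 tfNames = character(), varFloor = 1e-3) {
  values <- as.matrix(values)
  if (is.null(variances)) variances <- matrix(varFloor, nrow(values), ncol(values))
  cd <- S4Vectors::DataFrame(
    condition = rep_len(condition, ncol(values)),
    replicate = rep_len(replicate, ncol(values)),
    time = rep_len(time, ncol(values)))
  se <- SummarizedExperiment(
    assays = list(exprs = values, var = as.matrix(variances)), colData = cd)
  obj <- new("ExpressionTimeSeries", se)
  metadata(obj)$tfNames <- tfNames
  validObject(obj)
  obj
}

#' @describeIn expressionTimeSeries names of the TF mRNA rows.
#' @param x an \code{ExpressionTimeSeries}.
#' @export
tfNames <- function(x) metadata(x)$tfNames

#' @describeIn expressionTimeSeries ids of target-gene rows (non-TF rows).
#' @export
targetIds <- function(x) setdiff(rownames(x), tfNames(x))

setMethod("show", "ExpressionTimeSeries", function(object) {
  cd <- colData(object)
  cat("ExpressionTimeSeries:", nrow(object), "genes (",
      length(tfNames(object)), "TF mRNA rows ),",
      length(unique(paste(cd$condition, cd$replicate))), "series,",
      length(unique(cd$time)), "time points\n")
})

## Split an ExpressionTimeSeries into per-(condition, replicate) series:
## a list with per-series sorted times and genes x time value/variance
## matrices. The internal working representation of training and prediction.
.seriesList <- function(x) {
  cd <- colData(x)
  key <- paste(cd$condition, cd$replicate, sep = "\r")
  lapply(split(seq_len(ncol(x)), key)[unique(key)], function(idx) {
    ord <- idx[order(cd$time[idx])]
    tt <- cd$time[ord]
    if (anyDuplicated(tt))
      stop("duplicate time points within a series", call. = FALSE)
    list(condition = cd$condition[ord[1L]], replicate = cd$replicate[ord[1L]],
         times = tt,
         values = assay(x, "exprs")[, ord, drop = FALSE],
         vars = assay(x, "var")[, ord, drop = FALSE])
  })
}

#' Read an expression time-series table
#'
#' Expects a tab- or comma-separated file with columns \code{gene},
#' \code{condition}, \code{replicate}, \code{time}, \code{value} and
#' optionally \code{variance} (when absent, \code{varFloor} is used).
#'
#' @param path file path.
#' @param tfNames gene ids to mark as TF mRNA rows.
#' @param varFloor variance assigned when the variance column is missing.
#' @return an \linkS4class{ExpressionTimeSeries}.
#' @export
readExpression <- function(path, tfNames = character(), varFloor = 1e-3) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("gene", "condition", "replicate", "time", "value")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  if (!"variance" %in% names(df)) df$variance <- varFloor
  if (any(df$variance < 0)) stop("negative noise variance", call. = FALSE)
  keyobs <- paste(df$gene, df$condition, df$replicate, df$time)
  if (anyDuplicated(keyobs))
    stop("duplicate (gene, condition, replicate, time) rows", call. = FALSE)
  samp <- unique(df[order(df$condition, df$replicate, df$time),
                    c("condition", "replicate", "time")])
  skey <- do.call(paste, samp)
  genes <- unique(df$gene)
  val <- matrix(NA_real_, length(genes), nrow(samp),
                dimnames = list(genes, NULL))
  vv <- val
  idx <- cbind(match(df$gene, genes),
               match(paste(df$condition, df$replicate, df$time), skey))
  val[idx] <- df$value
  vv[idx] <- df$variance
  if (anyNA(val))
    stop("every gene must be observed at every (condition, replicate, time)",
         call. = FALSE)
  expressionTimeSeries(val, vv, time = samp$time, condition = samp$condition,
                       replicate = samp$replicate, tfNames = tfNames,
                       varFloor = varFloor)
}

#' Write an expression time-series table
#'
#' Inverse of \code{\link{readExpression}}; values round-trip exactly.
#'
#' @param x an \linkS4class{ExpressionTimeSeries}.
#' @param path output TSV path.
#' @export
writeExpression <- function(x, path) {
  cd <- colData(x)
  df <- data.frame(
    gene = rep(rownames(x), times = ncol(x)),
    condition = rep(cd$condition, each = nrow(x)),
    replicate = rep(cd$replicate, each = nrow(x)),
    time = rep(cd$time, each = nrow(x)),
    value = as.vector(assay(x, "exprs")),
    variance = as.vector(assay(x, "var")))
  utils::write.table(format(df, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binary gene-by-TF network matrix
#'
#' A TSV with a \code{gene} column followed by one 0/1 column per TF. Used
#' both for the training network and for validation (e.g. ChIP-derived
#' binding) matrices.
#'
#' @param path file path.
#' @param tfNames expected TF column names; if supplied, the file must
#'   contain exactly these columns.
#' @return binary matrix with gene rownames and TF colnames.
#' @export
readNetwork <- function(path, tfNames = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L || !"gene" %in% names(df))
    stop("empty or malformed network file", call. = FALSE)
  X <- as.matrix(df[setdiff(names(df), "gene")])
  rownames(X) <- df$gene
  if (!all(X %in% c(0, 1)))
    stop("network entries must be 0 or 1", call. = FALSE)
  if (!is.null(tfNames) && !setequal(colnames(X), tfNames))
    stop("unexpected TF columns; expected: ",
         paste(tfNames, collapse = ", "), call. = FALSE)
  storage.mode(X) <- "integer"
  if (!is.null(tfNames)) X <- X[, tfNames, drop = FALSE]
  X
}

#' @rdname readNetwork
#' @param X binary matrix with gene rownames.
#' @export
writeNetwork <- function(X, path) {
  df <- data.frame(gene = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
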