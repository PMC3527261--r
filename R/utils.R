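## Internal numeric helpers shared across modules.

#' @importFrom stats approx rnorm runif dnorm qnorm plogis setNames
#' @importFrom methods new validObject is slot
NULL

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log-scale values.
#' @return \code{log(sum(exp(x)))} computed without overflow.
#' @keywords internal
logSumExp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logMeanExp <- function(x) logSumExp(x) - log(length(x))

## elementwise log(exp(a) + exp(b))
.lse2 <- function(a, b) {
  m <- pmax(a, b)
  m + log1p(exp(pmin(a, b) - m))
}

## Positivity floor applied to protein activities before taking logs in the
## response function; GP-derived activities can numerically touch zero.
.P_FLOOR <- 1e-8

.assertFinite <- function(x, what) {
  if (!all(is.finite(x)))
    stop("non-finite values in ", what, call. = FALSE)
  invisible(x)
}

## Linear interpolation of a function on a grid, erroring outside the span.
.interpGrid <- function(times, values, at) {
  if (min(at) < times[1L] - 1e-9 || max(at) > times[length(times)] + 1e-9)
    stop("requested times fall outside the evaluation grid", call. = FALSE)
  stats::approx(times, values, xout = at, rule = 2)$y
}

## Derive a stream of sub-seeds from one master seed (keeps values < 2^31).
.subSeeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
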