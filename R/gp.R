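## Gaussian-process prior over each TF mRNA function f_i(t). A smooth
## squared-exponential kernel encodes the assumption that TF mRNA (and hence,
## through the linear translation ODE, protein activity) varies smoothly over
## the time course.

#' Gaussian-process hyperparameters
#'
#' @param variance marginal variance of the kernel (squared expression units).
#' @param lengthscale correlation length of the kernel (h).
#' @return a validated list of class \code{GPHyperparams}.
#' @export
gpHyperparams <- function(variance, lengthscale) {
  .assertFinite(c(variance, lengthscale), "GP hyperparameters")
  if (variance < 0) stop("kernel variance must be non-negative", call. = FALSE)
  if (lengthscale <= 0) stop("kernel lengthscale must be positive", call. = FALSE)
  structure(list(variance = variance, lengthscale = lengthscale),
            class = "GPHyperparams")
}

#' Squared-exponential covariance matrix with jitter
#'
#' \code{K(t, t') = v exp(-(t - t')^2 / (2 l^2))} plus diagonal jitter
#' \code{1e-6 v} for numerical positive-definiteness.
#'
#' @param times numeric vector of input times (h).
#' @param hyper a \code{\link{gpHyperparams}} object.
#' @return symmetric positive-semidefinite matrix.
#' @export
gpCov <- function(times, hyper) {
  stopifnot(inherits(hyper, "GPHyperparams"))
  .assertFinite(times, "times")
  D <- outer(times, times, "-")
  K <- hyper$variance * exp(-0.5 * (D / hyper$lengthscale)^2)
  K + diag(1e-6 * hyper$variance, length(times))
}

#' Gaussian log-likelihood of TF mRNA observations
#'
#' Observations are compared to the latent function (clamped at zero, since
#' measured mRNA is non-negative) linearly interpolated at the observation
#' times, under independent Gaussian noise with the supplied per-point
#' variances.
#'
#' @param obsValues,obsTimes,obsVar observed TF mRNA values, their times, and
#'   per-observation noise variances (all same length).
#' @param f latent function values on \code{times}.
#' @param times evaluation grid carrying \code{f}.
#' @param varFloor variance floor applied to the supplied variances; zero or
#'   negative variances without a positive floor are an error.
#' @return scalar Gaussian log-density.
#' @export
gpLogLikF <- function(obsValues, obsTimes, obsVar, f, times,
                      varFloor = 1e-3) {
  v <- pmax(obsVar, varFloor)
  if (any(v <= 0))
    stop("non-positive noise variance and no positive variance floor",
         call. = FALSE)
  mu <- .interpGrid(times, pmax(f, 0), obsTimes)
  sum(stats::dnorm(obsValues, mu, sqrt(v), log = TRUE))
}

#' Draw a TF mRNA function from the GP prior
#'
#' @param times evaluation grid.
#' @param hyper a \code{\link{gpHyperparams}} object.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @param mean optional prior mean vector (default 0).
#' @return numeric vector of function values on \code{times}.
#' @export
sampleFPrior <- function(times, hyper, seed = NULL, mean = 0) {
  if (!is.null(seed)) set.seed(seed)
  if (hyper$variance == 0) return(rep(mean, length.out = length(times)) * 1)
  L <- chol(gpCov(times, hyper))
  drop(crossprod(L, stats::rnorm(length(times)))) + mean
}

## Log-density of f under the GP prior given a precomputed Cholesky factor
## (upper triangular) of the covariance.
.gpLogPrior <- function(f, cholK, mean = 0) {
  r <- f - mean
  z <- backsolve(cholK, r, transpose = TRUE)
  -0.5 * sum(z^2) - sum(log(diag(cholK))) - 0.5 * length(f) * log(2 * pi)
}
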