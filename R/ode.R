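## Deterministic mathematical core: the sigmoidal response function and
## explicit solutions of the transcription / translation ODEs evaluated by
## exponentially-weighted trapezoidal quadrature on a dense time grid.
##
## Transcription:  dm/dt = b + s * G(p_1(t), ..., p_I(t)) - d * m(t)
## Translation:    dp/dt = f(t) - delta * p(t)
##
## Both are linear in the state, so the solution is a decaying initial
## condition plus a convolution of the drive with an exponential kernel; the
## convolution is evaluated by trapezoidal quadrature on the grid with the
## exponential kernel handled exactly on each sub-interval.

#' Construct response weights
#'
#' Interaction weights between one target gene and the I transcription
#' factors, plus a bias. A weight of zero means the corresponding link is
#' absent; positive weights are activating, negative repressing.
#'
#' @param w numeric vector of interaction weights (length I).
#' @param w0 scalar bias.
#' @return a validated list of class \code{ResponseWeights}.
#' @export
responseWeights <- function(w, w0 = 0) {
  w <- as.numeric(w); w0 <- as.numeric(w0)
  .assertFinite(c(w, w0), "response weights")
  structure(list(w = w, w0 = w0), class = "ResponseWeights")
}

#' Construct kinetic parameters of the transcription ODE
#'
#' @param b basal transcription rate (expression units / h), >= 0.
#' @param d mRNA degradation rate (1/h), > 0.
#' @param s sensitivity to the TF response (expression units / h), >= 0.
#' @param a initial mRNA level (expression units), >= 0.
#' @return a validated list of class \code{KineticParams}.
#' @export
kineticParams <- function(b, d, s, a) {
  p <- c(b = b, d = d, s = s, a = a)
  .assertFinite(p, "kinetic parameters")
  if (any(p < 0) || d <= 0)
    stop("kinetic parameters must be non-negative with d > 0", call. = FALSE)
  structure(as.list(p), class = "KineticParams")
}

#' Construct translation-ODE parameters for one TF protein
#'
#' @param delta protein degradation rate (1/h), > 0.
#' @param p0 initial protein level, >= 0.
#' @return a validated list of class \code{ProteinParams}.
#' @export
proteinParams <- function(delta, p0 = 0) {
  .assertFinite(c(delta, p0), "protein parameters")
  if (delta <= 0) stop("protein degradation rate must be positive", call. = FALSE)
  if (p0 < 0) stop("initial protein level must be non-negative", call. = FALSE)
  structure(list(delta = delta, p0 = p0), class = "ProteinParams")
}

#' Uniform dense evaluation grid spanning the observation interval
#'
#' @param from,to interval end points (h).
#' @param n number of grid points (default 100).
#' @return numeric vector of strictly increasing times.
#' @export
denseGrid <- function(from, to, n = 100L) {
  if (!(to > from)) stop("grid interval must have positive length", call. = FALSE)
  seq(from, to, length.out = n)
}

#' Sigmoidal response of transcription to TF protein activities
#'
#' \code{G(p; w, w0) = 1 / (1 + exp(-w0 - sum_i w_i log p_i))}, the
#' multiplicative modulation (in (0,1)) of the sensitivity term of the
#' transcription ODE. Activities are clamped below at a small positivity
#' floor before the log is taken.
#'
#' @param p activities: numeric vector (length I) or matrix (times x I).
#' @param rw a \code{\link{responseWeights}} object.
#' @return response values in (0, 1), one per row of \code{p}.
#' @export
responseG <- function(p, rw) {
  stopifnot(inherits(rw, "ResponseWeights"))
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  .assertFinite(p, "TF activities")
  if (ncol(p) != length(rw$w))
    stop("activity / weight dimension mismatch", call. = FALSE)
  z <- drop(log(pmax(p, .P_FLOOR)) %*% rw$w) + rw$w0
  stats::plogis(z)
}

## Solve y' = basal + drive(t) - decay * y on a grid, with the decay handled
## exactly and the drive trapezoidally on each sub-interval:
##   y[k+1] = e^{-decay h} y[k] + basal/decay (1 - e^{-decay h})
##            + h/2 (e^{-decay h} drive[k] + drive[k+1]).
## On a uniform grid the recurrence is a first-order recursive filter.
.odeStep <- function(drive, hh, decay, init, basal = 0) {
  n <- length(drive)
  al <- exp(-decay * hh)
  z <- c(init, -basal / decay * expm1(-decay * hh) +
           (hh / 2) * (al * drive[-n] + drive[-1L]))
  .Call(tfode_lin_recurse, z, al)
}

.lin1ode <- function(drive, times, decay, init, basal = 0) {
  n <- length(times)
  if (n < 2L) return(rep(init, n))
  h <- diff(times)
  uniform <- diff(range(h)) < 1e-9 * mean(h)
  if (uniform) {
    .odeStep(drive, h[1L], decay, init, basal)
  } else {
    y <- numeric(n)
    y[1L] <- init
    for (k in seq_len(n - 1L)) {
      al <- exp(-decay * h[k])
      y[k + 1L] <- al * y[k] - basal / decay * expm1(-decay * h[k]) +
        (h[k] / 2) * (al * drive[k] + drive[k + 1L])
    }
    y
  }
}

#' Solve the translation ODE for protein activity
#'
#' Evaluates \code{p(t) = p0 e^{-delta t} + int_0^t e^{-delta (t-u)} f(u) du}
#' by quadrature on the grid carrying \code{f}. The driving mRNA function is
#' clamped at zero from below (the GP prior on f does not enforce
#' positivity).
#'
#' @param f numeric vector, TF mRNA values on \code{times}.
#' @param times strictly increasing grid (h).
#' @param pp a \code{\link{proteinParams}} object.
#' @return protein activity values on \code{times} (non-negative).
#' @export
solveTranslation <- function(f, times, pp) {
  stopifnot(inherits(pp, "ProteinParams"))
  if (length(f) != length(times))
    stop("f and times lengths differ", call. = FALSE)
  pmax(.lin1ode(pmax(f, 0), times, pp$delta, pp$p0), 0)
}

#' Solve the transcription ODE for target-gene mRNA
#'
#' Evaluates
#' \code{m(t) = a e^{-d t} + b/d (1 - e^{-d t}) +
#'   s int_0^t e^{-d (t-u)} G(p(u)) du}
#' on the common grid of the TF activities, then linearly interpolates at the
#' requested output times.
#'
#' @param pAll matrix (grid x I) of TF protein activities on \code{times},
#'   or a list of equal-length numeric vectors.
#' @param times strictly increasing common grid (h).
#' @param rw a \code{\link{responseWeights}} object.
#' @param kp a \code{\link{kineticParams}} object.
#' @param outTimes times at which to return m(t); defaults to the grid.
#' @return predicted mRNA values at \code{outTimes}.
#' @export
solveTranscription <- function(pAll, times, rw, kp, outTimes = times) {
  if (is.list(pAll)) {
    len <- lengths(pAll)
    if (length(unique(len)) != 1L)
      stop("TF activity grids differ in length", call. = FALSE)
    pAll <- do.call(cbind, pAll)
  }
  if (nrow(pAll) != length(times))
    stop("activity grid does not match times", call. = FALSE)
  G <- responseG(pAll, rw)
  m <- .lin1ode(G * kp$s, times, kp$d, kp$a, basal = kp$b)
  .interpGrid(times, m, outTimes)
}
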