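test_that("response function matches its closed form and limits", {
  expect_equal(responseG(c(1, 1, 1), responseWeights(c(0, 0, 0), 0)), 0.5)
  expect_equal(responseG(c(exp(1), 1), responseWeights(c(1, 0), 0)),
               1 / (1 + exp(-1)))
  ## strongly negative bias drives the response to 0, never reaching it
  g <- responseG(c(1, 1, 1), responseWeights(c(1, 2, 3), -50))
  expect_gt(g, 0)
  expect_lt(g, 1e-15)
  expect_error(responseG(c(NA, 1), responseWeights(c(1, 1), 0)),
               "non-finite")
  expect_error(responseG(c(1, 1, 1), responseWeights(c(1, 1), 0)),
               "mismatch")
})

test_that("response function is monotone in each activity", {
  set.seed(11)
  for (rep in 1:20) {
    w <- rnorm(3)
    rw <- responseWeights(w, rnorm(1))
    i <- sample(3, 1)
    p <- matrix(rep(runif(3, 0.1, 5), each = 50), 50, 3)
    p[, i] <- sort(runif(50, 0.1, 5))
    g <- responseG(p, rw)
    d <- diff(g)
    if (w[i] > 0) expect_true(all(d >= 0)) else
      if (w[i] < 0) expect_true(all(d <= 0))
  }
})

test_that("translation ODE reproduces closed-form solutions", {
  g <- denseGrid(0, 5, 501)
  ## pure decay
  p <- solveTranslation(rep(0, 501), g, proteinParams(1, 1))
  expect_equal(p, exp(-g), tolerance = 1e-10)
  ## steady state: f = c, p0 = c / delta (trapezoid error is O(h^2))
  p <- solveTranslation(rep(3, 501), g, proteinParams(1.5, 2))
  expect_equal(p, rep(2, 501), tolerance = 1e-4)
  ## ramp drive: closed form t - 1 + e^-t
  p <- solveTranslation(g, g, proteinParams(1, 0))
  expect_equal(p, g - 1 + exp(-g), tolerance = 1e-4)
  expect_error(proteinParams(-1, 0), "positive")
})

test_that("translation is linear in the drive", {
  g <- denseGrid(0, 8, 200)
  f1 <- sin(g) + 1.2; f2 <- exp(-g / 3)
  p12 <- solveTranslation(f1 + f2, g, proteinParams(0.7, 1.0))
  p1 <- solveTranslation(f1, g, proteinParams(0.7, 0.4))
  p2 <- solveTranslation(f2, g, proteinParams(0.7, 0.6))
  expect_equal(p12, p1 + p2, tolerance = 1e-10)
})

test_that("transcription ODE handles decoupled and constant-response cases", {
  g <- denseGrid(0, 6, 601)
  pmat <- matrix(1, 601, 2)
  ## s = 0: m(t) = a e^-dt + b/d (1 - e^-dt)
  m <- solveTranscription(pmat, g, responseWeights(c(0, 0), 0),
                          kineticParams(b = 1, d = 1, s = 0, a = 2))
  expect_equal(m, 2 * exp(-g) + (1 - exp(-g)), tolerance = 1e-8)
  ## zero weights: G = 1/2, equilibrium (b + s/2) / d
  m <- solveTranscription(pmat, g, responseWeights(c(0, 0), 0),
                          kineticParams(b = 1, d = 2, s = 3, a = 0))
  expect_equal(m[length(m)], (1 + 1.5) / 2, tolerance = 1e-3)
  expect_error(solveTranscription(list(rep(1, 5), rep(1, 4)), g,
                                  responseWeights(c(0, 0), 0),
                                  kineticParams(1, 1, 1, 1)),
               "grids")
})

test_that("quadrature solution matches an adaptive ODE integrator", {
  skip_if_not_installed("deSolve")
  set.seed(21)
  g <- denseGrid(0, 18, 1441)
  for (draw in 1:5) {
    f <- abs(sampleFPrior(g, gpHyperparams(4, 4), seed = draw)) + 0.3
    pp <- proteinParams(delta = runif(1, 0.3, 2), p0 = runif(1, 0, 2))
    rw <- responseWeights(rnorm(1), rnorm(1))
    kp <- kineticParams(b = runif(1, 0, 1), d = runif(1, 0.2, 2.5),
                        s = runif(1, 0.5, 3), a = runif(1, 0, 2))
    p <- solveTranslation(f, g, pp)
    m <- solveTranscription(matrix(p, ncol = 1), g, rw, kp)
    fFun <- approxfun(g, pmax(f, 0), rule = 2)
    ode <- deSolve::ode(
      y = c(p = pp$p0, m = kp$a), times = g,
      func = function(t, y, parms) {
        G <- responseG(max(y[1], 1e-8), rw)
        list(c(fFun(t) - pp$delta * y[1],
               kp$b + kp$s * G - kp$d * y[2]))
      }, parms = NULL, rtol = 1e-9, atol = 1e-10)
    expect_lt(max(abs(p - ode[, "p"])) / max(abs(ode[, "p"])), 1e-4)
    expect_lt(max(abs(m - ode[, "m"])) / max(abs(ode[, "m"])), 1e-4)
  }
})

test_that("grid refinement converges at second order", {
  gRef <- denseGrid(0, 10, 6401)
  ref <- solveTranslation(sin(gRef / 2) + 1.5, gRef, proteinParams(0.9, 1))
  err <- vapply(c(200L, 400L, 800L), function(n) {
    g <- denseGrid(0, 10, n)
    p <- solveTranslation(sin(g / 2) + 1.5, g, proteinParams(0.9, 1))
    max(abs(p - approx(gRef, ref, xout = g)$y))
  }, numeric(1))
  ## each doubling divides the error by ~4
  expect_lt(err[2], err[1] / 3)
  expect_lt(err[3], err[2] / 3)
  expect_lt(err[3], 1e-4)
})
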