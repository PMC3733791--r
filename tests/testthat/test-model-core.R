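test_that("model construction validates names, dimensions and positivity", {
  m <- goodwinModel()
  expect_s3_class(m, "oscillator_model")
  expect_equal(m$neq, 3)
  expect_equal(m$np, 6)
  expect_error(oscillatorModel(c("x", "x"), "a", function(x, p) x, 1),
               "unique")
  expect_error(oscillatorModel("x", "a", function(x, p) x, -1), "positive")
  expect_error(oscillatorModel("x", "a", function(x, p) x, c(1, 2)), "length")
})

test_that("rhs evaluation honours its contracts on the Goodwin fixture", {
  m <- goodwinModel()
  p <- m$nominal_params
  # at the origin only Hill-repressed production of x1 survives: (a, 0, 0)
  expect_identical(evaluateRhs(m, c(0, 0, 0), p),
                   c(p[["a"]], 0, 0))
  # deterministic / autonomous: repeated evaluation is bit-identical
  x <- c(0.3, 0.7, 1.1)
  expect_identical(evaluateRhs(m, x, p), evaluateRhs(m, x, p))
  expect_error(evaluateRhs(m, c(1, 2), p), "NEQ")
  expect_error(evaluateRhs(m, x, p[-1]), "NP")
  expect_error(evaluateRhs(m, x, -p), "positive")
})

test_that("derivative vanishes at a root-found fixed point", {
  m <- dampedFixture()
  p <- m$nominal_params
  # independent multivariate Newton with numerically differenced Jacobian
  x <- c(0.5, 0.5, 0.5)
  for (it in 1:60) {
    f <- m$rhs(x, p)
    J <- vapply(1:3, function(k) {
      h <- 1e-7 * max(abs(x[k]), 1)
      xp <- x; xm <- x; xp[k] <- xp[k] + h; xm[k] <- xm[k] - h
      (m$rhs(xp, p) - m$rhs(xm, p)) / (2 * h)
    }, numeric(3))
    x <- x - solve(J, f)
  }
  expect_lt(max(abs(evaluateRhs(m, x, p))), 1e-10)
})

test_that("time-rescaling symmetry holds to machine precision", {
  m <- goodwinModel()
  set.seed(11)
  for (rep in 1:10) {
    x <- runif(3, 0.05, 2)
    lam <- runif(1, 0.2, 5)
    expect_equal(evaluateRhs(m, x, lam * m$nominal_params),
                 lam * evaluateRhs(m, x, m$nominal_params),
                 tolerance = 1e-12)
  }
})

test_that("the Goodwin fixture sustains oscillation and its low-Hill variant damps out", {
  m <- goodwinModel()
  # 50 nominal periods from a perturbed state: successive cycles stay alike
  tr <- simulateModel(m, x0 = c(0.9, 0.1, 0.4),
                      times = seq(0, 50 * 24, length.out = 4001))
  late <- tr$values[1, tr$times > 40 * 24]
  expect_gt(diff(range(late)), 1e-2)
  # peak-to-peak amplitude of the last two cycles agrees (settled cycle)
  last <- tr$values[1, tr$times > 48 * 24]
  prev <- tr$values[1, tr$times > 46 * 24 & tr$times <= 48 * 24]
  expect_equal(diff(range(last)), diff(range(prev)), tolerance = 1e-3)

  d <- dampedFixture(hill = 2)
  trd <- simulateModel(d, x0 = c(0.9, 0.1, 0.4),
                       times = seq(0, 50 * 24, length.out = 2001))
  xe <- trd$values[, ncol(trd$values)]
  fin <- trd$values[, trd$times >= 49 * 24]
  expect_lt(max(abs(fin - xe)), 1e-6 * max(abs(xe)))
})
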