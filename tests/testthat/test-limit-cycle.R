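test_that("integration keeps an equilibrium fixed and is self-convergent", {
  d <- dampedFixture()
  # settle to the fixed point first
  xe <- simulateModel(d, x0 = c(0.5, 0.5, 0.5),
                      times = c(0, 2000))$values[, 2]
  tr <- simulateModel(d, x0 = xe, times = seq(0, 48, length.out = 49))
  expect_lt(max(abs(tr$values - xe)), 1e-6)

  m <- goodwinModel()
  grid <- seq(0, 120, length.out = 121)
  e1 <- simulateModel(m, x0 = c(0.3, 0.4, 0.5), times = grid)$values[, 121]
  e2 <- simulateModel(m, x0 = c(0.3, 0.4, 0.5), times = grid,
                      rtol = 1e-9, atol = 1e-11)$values[, 121]
  expect_lt(max(abs(e1 - e2)), 10 * 1e-8 * (1 + max(abs(e1))))

  # long-horizon positivity and boundedness
  trl <- simulateModel(m, x0 = c(0.3, 0.4, 0.5),
                       times = seq(0, 100 * 24, length.out = 2001))
  expect_true(all(trl$values > 0))
  expect_true(all(trl$values < 10))
})

test_that("shooting period matches the peak-timing of a long simulation", {
  m <- goodwinModel()
  cyc <- goodwinCycle()
  tr <- simulateModel(m, x0 = c(0.1, 0.2, 0.3),
                      times = seq(0, 40 * 24, length.out = 40 * 400 + 1))
  sel <- tr$times > 20 * 24
  t <- tr$times[sel]; x1 <- tr$values[1, sel]
  pk <- which(diff(sign(diff(x1))) == -2) + 1
  # quadratic refinement of each peak time
  tpk <- vapply(pk, function(i) {
    a <- x1[i - 1]; b <- x1[i]; c <- x1[i + 1]
    t[i] + 0.5 * (a - c) / (a - 2 * b + c) * (t[2] - t[1])
  }, numeric(1))
  T_oracle <- mean(diff(tpk))
  expect_lt(abs(cyc$period - T_oracle) / T_oracle, 1e-3)
})

test_that("the converged orbit is a fixed point of the solver", {
  m <- goodwinModel()
  cyc <- goodwinCycle()
  again <- findLimitCycle(m, x0_guess = cyc$anchor_state,
                          T_guess = cyc$period, refine = FALSE)
  expect_lte(again$n_iterations, 2)
  expect_equal(again$period, cyc$period, tolerance = 1e-8)
  expect_lt(max(abs(again$anchor_state - cyc$anchor_state)), 1e-8)
})

test_that("the damped fixture raises a steady-state error", {
  expect_error(findLimitCycle(dampedFixture(), x0_guess = c(0.1, 0.2, 0.3),
                              T_guess = 24),
               class = "cyclefit_steady_state_error")
})

test_that("any anchor on the orbit yields the same period (phase invariance)", {
  m <- goodwinModel()
  cyc <- goodwinCycle()
  for (frac in c(0.17, 0.42, 0.77)) {
    x0 <- cyc$sampler(frac * cyc$period)[, 1]
    c2 <- findLimitCycle(m, x0_guess = x0, T_guess = cyc$period,
                         refine = FALSE)
    expect_equal(c2$period, cyc$period, tolerance = 1e-7)
  }
})

test_that("rescaling all rates by lambda rescales the period by 1/lambda", {
  m <- goodwinModel()
  cyc <- goodwinCycle()
  for (lam in c(0.5, 2)) {
    cl <- findLimitCycle(m, p = lam * m$nominal_params,
                         x0_guess = cyc$anchor_state,
                         T_guess = cyc$period / lam)
    expect_lt(abs(cl$period - cyc$period / lam) / (cyc$period / lam), 1e-3)
  }
})

test_that("steady-state detection separates cycles from relaxed trajectories", {
  m <- goodwinModel()
  const <- trajectory(seq(0, 96, by = 1), matrix(1.3, 3, 97))
  expect_true(detectSteadyState(const, period = 24))
  cyc_tr <- simulateModel(m, x0 = goodwinCycle()$anchor_state,
                          times = seq(0, 96, length.out = 400))
  expect_false(detectSteadyState(cyc_tr, period = 24))
  d <- dampedFixture()
  damp_tr <- simulateModel(d, x0 = c(0.9, 0.1, 0.4),
                           times = seq(0, 2000, length.out = 2001))
  expect_true(detectSteadyState(damp_tr, period = 24))
  short <- trajectory(seq(0, 30, by = 1), matrix(1, 3, 31))
  expect_error(detectSteadyState(short, period = 24), class = "cyclefit_argument_error")
})

test_that("period estimation applies the one-cycle span rule and rejects flat data", {
  t <- 0:23
  y <- sin(2 * pi * t / 24)
  ds <- timeSeriesDataset(t, rbind(y), rbind(rep(0.1, 24)))
  expect_equal(estimatePeriod(ds), 24, tolerance = 0.5)
  set.seed(3)
  for (rep in 1:5) {
    yn <- y + rnorm(24, 0, 0.1)
    dsn <- timeSeriesDataset(t, rbind(yn), rbind(rep(0.1, 24)))
    expect_lt(abs(estimatePeriod(dsn) - 24) / 24, 0.05)
  }
  flat <- timeSeriesDataset(t, rbind(rep(2, 24)), rbind(rep(0.1, 24)))
  expect_error(estimatePeriod(flat), class = "cyclefit_estimation_error")
})
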