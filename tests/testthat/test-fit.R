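test_that("the weighted cost matches a direct double-loop summation", {
  set.seed(21)
  means <- matrix(runif(12), 3, 4)
  stds <- matrix(runif(12, 0.1, 0.5), 3, 4)
  ds <- timeSeriesDataset(1:4, means, stds)
  expect_identical(datasetCost(ds, means), 0)
  # a single residual equal to its sigma contributes exactly 1
  pred <- means; pred[2, 3] <- means[2, 3] + stds[2, 3]
  expect_equal(datasetCost(ds, pred), 1, tolerance = 1e-14)
  pred <- matrix(runif(12), 3, 4)
  brute <- 0
  for (i in 1:3) for (j in 1:4)
    brute <- brute + (means[i, j] - pred[i, j])^2 / stds[i, j]^2
  expect_equal(datasetCost(ds, pred), brute, tolerance = 1e-12)
  expect_error(timeSeriesDataset(1:4, means, stds * 0),
               class = "cyclefit_argument_error")
})

test_that("data-driven initial guesses start close in cost and have the right size", {
  m <- goodwinModel()
  truth <- goodwinTruth(30)
  ds <- generateBootstrapDataset(truth, noiseModel(0.05, 0.001), seed = 5)
  cfg <- collocationConfig(n_elements = 10, degree = 4)
  g <- buildInitialGuess(ds, m, cfg)
  expect_length(g, countDecisionVariables(10, 4, 3, 6) + 1)

  # noise-free data: the interpolated guess nearly zeroes the cost
  ds0 <- timeSeriesDataset(truth$times, truth$means,
                           matrix(0.05, 3, 30))
  g0 <- buildInitialGuess(ds0, m, cfg)
  tr <- cyclefit:::transcription(m, ds0, cfg)
  r0 <- cyclefit:::trResiduals(tr, g0)
  expect_lt(sum(r0$data^2), 1e-2 * 30 * 3)
  # the guess interpolant reproduces the smooth data to < 1%
  X <- cyclefit:::trStates(tr, g0)
  pred <- cyclefit:::collocEval(tr, X, (ds0$times - ds0$times[1]) / exp(g0[tr$idx_logT]))
  expect_lt(max(abs(pred - truth$means)) / max(abs(truth$means)), 0.01)

  miss <- truth$means; miss[2, ] <- NA
  dsm <- timeSeriesDataset(truth$times, miss, matrix(0.05, 3, 30))
  expect_error(buildInitialGuess(dsm, m, cfg),
               class = "cyclefit_unsupported_error")
})

test_that("noise-free recovery from a 1.3x-perturbed start is sharp", {
  m <- goodwinModel()
  truth <- goodwinTruth(30)
  ds0 <- timeSeriesDataset(truth$times, truth$means, matrix(0.05, 3, 30))
  res <- estimateParameters(m, ds0, params = 1.3 * m$nominal_params)
  expect_identical(res$status, "converged")
  expect_lt(max(abs(res$p_star - m$nominal_params) / m$nominal_params), 0.01)
  expect_lt(abs(res$period - goodwinCycle()$period) / goodwinCycle()$period, 1e-3)
  expect_lte(res$cost, res$initial_objective)
  expect_lt(res$constraint_violation, 1e-6)
  # converged collocation trajectory agrees with an IVP re-integration
  expect_lt(res$consistency, 1e-4)
})

test_that("mesh refinement leaves the optimum essentially unchanged", {
  m <- goodwinModel()
  truth <- goodwinTruth(30)
  ds0 <- timeSeriesDataset(truth$times, truth$means, matrix(0.05, 3, 30))
  r1 <- estimateParameters(m, ds0, collocationConfig(n_elements = 8, degree = 4),
                           params = 1.2 * m$nominal_params)
  r2 <- estimateParameters(m, ds0, collocationConfig(n_elements = 16, degree = 4),
                           params = 1.2 * m$nominal_params)
  expect_lt(max(abs(r1$p_star - r2$p_star) / r2$p_star), 1e-3)
})

test_that("rescaling all sigmas rescales the cost and leaves p* unchanged", {
  m <- goodwinModel()
  truth <- goodwinTruth(20)
  ds <- generateBootstrapDataset(truth, noiseModel(0.05, 0.001), seed = 9)
  r1 <- estimateParameters(m, ds)
  ds2 <- timeSeriesDataset(ds$times, ds$means, 2 * ds$stds)
  r2 <- estimateParameters(m, ds2)
  expect_identical(r1$status, "converged")
  expect_identical(r2$status, "converged")
  expect_equal(r2$cost, r1$cost / 4, tolerance = 1e-4)
  expect_lt(max(abs(r2$p_star - r1$p_star) / r1$p_star), 1e-4)
})

test_that("optimal cost scales like the residual count for noisy data", {
  m <- goodwinModel()
  truth <- goodwinTruth(30)
  nm <- noiseModel(0.05, 0.001)
  set.seed(31)
  costs <- vapply(1:12, function(s) {
    ds <- generateBootstrapDataset(truth, nm, seed = 1000 + s)
    r <- estimateParameters(m, ds)
    expect_identical(r$status, "converged")
    r$cost
  }, numeric(1))
  expect_true(all(costs > 0.2 * 30 * 3))
  expect_true(all(costs < 5 * 30 * 3))
})

test_that("individually missing points are dropped from the fit", {
  m <- goodwinModel()
  truth <- goodwinTruth(20)
  ds <- generateBootstrapDataset(truth, noiseModel(0.05, 0.001), seed = 13)
  means <- ds$means
  means[1, 3] <- NA; means[3, 17] <- NA
  dsm <- timeSeriesDataset(ds$times, means, ds$stds)
  res <- estimateParameters(m, dsm)
  expect_identical(res$status, "converged")
  expect_lt(max(abs(res$p_star - m$nominal_params) / m$nominal_params), 0.25)
})
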