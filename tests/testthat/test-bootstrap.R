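test_that("noise model validation rejects degenerate errors", {
  expect_error(noiseModel(0, 0), class = "cyclefit_invalid_noise_error")
  expect_error(noiseModel(-0.1, 0.1), class = "cyclefit_argument_error")
  lit <- noiseModel(preset = "literature")
  expect_equal(c(lit$xi, lit$eta), c(0.03, 0.005))
})

test_that("truth sampling reads the limit cycle at M equispaced phases", {
  m <- goodwinModel()
  cyc <- goodwinCycle()
  truth <- sampleTrueData(m, M = 20, cycle = cyc)
  expect_equal(truth$M, 20)
  expect_identical(truth$means, {
    x <- cyc$sampler(truth$times); rownames(x) <- m$state_names; x
  })
  # wrap-around: the virtual M+1-th point equals the first up to the
  # periodicity residual of the orbit
  expect_lt(max(abs(cyc$sampler(cyc$period) - cyc$sampler(0))), 1e-6)
  expect_error(sampleTrueData(dampedFixture(), M = 10),
               class = "cyclefit_steady_state_error")
})

test_that("noisy dataset generation is seeded and matches its stated moments", {
  truth <- goodwinTruth(10)
  nm <- noiseModel(0.1, 0)
  d1 <- generateBootstrapDataset(truth, nm, seed = 77)
  d2 <- generateBootstrapDataset(truth, nm, seed = 77)
  expect_identical(d1, d2)
  d3 <- generateBootstrapDataset(truth, nm, seed = 78)
  expect_false(identical(d1$means, d3$means))
  expect_identical(d1$stds, 0.1 * truth$means + 0)

  draws <- vapply(1:4000, function(s)
    generateBootstrapDataset(truth, nm, seed = s)$means[1, 1], numeric(1))
  mu <- truth$means[1, 1]; sig <- 0.1 * mu
  expect_lt(abs(mean(draws) - mu), 3 * sig / sqrt(4000))
  expect_lt(abs(sd(draws) - sig) / sig, 0.05)
})

test_that("the absolute error term is a fraction of each state's maximum", {
  means <- rbind(c(0, 1, 2, 0.5))
  truth <- timeSeriesDataset(1:4, means)
  d <- generateBootstrapDataset(truth, noiseModel(0, 0.001), seed = 1)
  expect_equal(unname(d$stds[1, 1]), 0.001 * 2.0)  # sigma at the zero-valued point
  # clipping flag clamps negative tails at zero
  big <- noiseModel(0.5, 0.5)
  dc <- generateBootstrapDataset(truth, big, seed = 4, clip_negative = TRUE)
  expect_true(all(dc$means >= 0))
})

test_that("bootstrap bookkeeping conserves counts and is seed-deterministic", {
  m <- goodwinModel()
  truth <- goodwinTruth(20)
  ens <- runBootstrap(m, truth, noiseModel(0.05, 0.001), B = 6,
                      master_seed = 4242)
  expect_identical(length(ens$results) + ens$n_failed + ens$n_steady,
                   ens$n_requested)
  expect_true(all(vapply(ens$results, `[[`, "", "status") == "converged"))
  ens2 <- runBootstrap(m, truth, noiseModel(0.05, 0.001), B = 6,
                       master_seed = 4242)
  expect_identical(ens$results, ens2$results)
})

test_that("per-trial seeds are a pure function of master seed and index", {
  s <- vapply(1:100, function(b) cyclefit:::trialSeed(17, b), integer(1))
  expect_identical(s, vapply(1:100, function(b) cyclefit:::trialSeed(17, b), integer(1)))
  expect_identical(anyDuplicated(s), 0L)
  expect_false(any(s == vapply(1:100, function(b) cyclefit:::trialSeed(18, b), integer(1))))
  expect_true(all(s > 0 & s < 2^31))
})

test_that("percentile bands match a brute-force order-statistic oracle", {
  # 5-member toy ensemble with constant-in-phase trajectories 1..5
  trajs <- lapply(c(3, 1, 5, 2, 4), function(v) matrix(v, 1, 11))
  ens <- fakeEnsemble(matrix(1, 5, 2), trajs = trajs)
  b <- percentileBand(ens, "x1", lo = 25, hi = 75)
  # independent sort-and-interpolate percentile (quantile type 7)
  brute <- function(v, p) {
    v <- sort(v); h <- (length(v) - 1) * p
    lo <- floor(h) + 1
    v[lo] + (h - floor(h)) * (v[min(lo + 1, length(v))] - v[lo])
  }
  expect_equal(unname(b$lower), rep(brute(1:5, 0.25), 11))
  expect_equal(unname(b$upper), rep(brute(1:5, 0.75), 11))
  full <- percentileBand(ens, "x1", lo = 0, hi = 100)
  expect_true(all(full$lower <= 1 & full$upper >= 5))
  # identical trajectories give a zero-width band
  same <- fakeEnsemble(matrix(1, 4, 2),
                       trajs = replicate(4, matrix(2.5, 1, 11), simplify = FALSE))
  bs <- percentileBand(same, 1)
  expect_equal(max(bs$upper - bs$lower), 0)
  expect_error(percentileBand(ens, "nope"), class = "cyclefit_argument_error")
})

test_that("sign-consistency classification follows the stated fractions", {
  allpos <- fakeEnsemble(cbind(s1 = rep(0.2, 40)))
  r <- classifyIdentifiability(allpos, level = 1)
  expect_true(r$table$identifiable)
  sym <- fakeEnsemble(cbind(s1 = rep(c(-1, 1), 20)))
  r2 <- classifyIdentifiability(sym, level = 0.95)
  expect_equal(r2$table$sign_consistent_fraction, 0.5)
  expect_false(r2$table$identifiable)
  mixed <- fakeEnsemble(cbind(s1 = c(rep(1, 96), rep(-1, 4))))
  expect_true(classifyIdentifiability(mixed, level = 0.95)$table$identifiable)
  expect_false(classifyIdentifiability(mixed, level = 0.97)$table$identifiable)
  # the interval rule is pinned at the 5th/95th percentiles (90% mass), so
  # at a 0.90 fraction level the two rules part ways: 10% opposite-sign
  # mass passes the fraction rule but drags the 5th percentile below zero
  r3 <- classifyIdentifiability(fakeEnsemble(cbind(s1 = c(rep(1, 90), rep(-1, 10)))),
                                level = 0.90)
  expect_true(r3$table$identifiable)
  expect_false(r3$table$identifiable_interval)
  small <- fakeEnsemble(cbind(s1 = rep(1, 5)))
  expect_true(classifyIdentifiability(small)$low_power)
})

test_that("cross-model comparison flags only sign-consistent identifiable pairs", {
  ra <- classifyIdentifiability(fakeEnsemble(cbind(u = rep(0.5, 30),
                                                   v = rep(-0.2, 30))))
  expect_true(all(compareModels(ra, ra)$robust))
  # one side unidentifiable
  rb <- classifyIdentifiability(fakeEnsemble(cbind(u = rep(c(0.5, -0.5), 15),
                                                   v = rep(-0.2, 30))))
  cmp <- compareModels(ra, rb)
  expect_false(cmp$robust[cmp$response_a == "u"])
  expect_true(cmp$robust[cmp$response_a == "v"])
  # identifiable but with clashing median signs
  rc <- classifyIdentifiability(fakeEnsemble(cbind(u = rep(0.5, 30),
                                                   v = rep(0.2, 30))))
  cmp2 <- compareModels(ra, rc)
  expect_false(cmp2$robust[cmp2$response_a == "v"])
  expect_error(compareModels(ra, rb, mapping = c(w = "u")),
               class = "cyclefit_argument_error")
})
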