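# Shared fixtures, built once per test run. The Goodwin cycle solve is
# cheap (~0.5 s) but used by most files, so it is memoized.

.fixture_cache <- new.env(parent = emptyenv())

goodwinModel <- function() {
  if (is.null(.fixture_cache$model)) .fixture_cache$model <- goodwinFixture()
  .fixture_cache$model
}

goodwinCycle <- function() {
  if (is.null(.fixture_cache$cycle)) {
    .fixture_cache$cycle <- findLimitCycle(
      goodwinModel(), x0_guess = c(0.1, 0.2, 0.3), T_guess = 24)
  }
  .fixture_cache$cycle
}

goodwinTruth <- function(M = 30) {
  key <- paste0("truth", M)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- sampleTrueData(goodwinModel(), M = M,
                                            cycle = goodwinCycle())
  .fixture_cache[[key]]
}

# A Goodwin model padded with an extra parameter that the dynamics ignore;
# its period sensitivity must be exactly zero.
paddedGoodwin <- function() {
  g <- goodwinFixture()
  oscillatorModel(
    state_names = g$state_names,
    param_names = c(g$param_names, "dummy"),
    rhs = function(x, p) g$rhs(x, p[1:6]),
    jac = function(x, p) g$jac(x, p[1:6]),
    pjac = function(x, p) cbind(g$pjac(x, p[1:6]), 0),
    nominal_params = c(g$nominal_params, dummy = 1),
    period_hint = 24, name = "goodwin+dummy")
}

# Minimal hand-built ensemble for percentile/identifiability logic tests.
fakeEnsemble <- function(sens_matrix, trajs = NULL, params = NULL) {
  n <- nrow(sens_matrix)
  pn <- colnames(sens_matrix)
  if (is.null(pn)) pn <- paste0("p", seq_len(ncol(sens_matrix)))
  phase <- seq(0, 1, length.out = 11)
  results <- lapply(seq_len(n), function(i) {
    list(status = "converged", seed = i,
         params = if (is.null(params)) stats::setNames(rep(1, ncol(sens_matrix)), pn)
                  else params[i, ],
         period = 24, cost = 1,
         sens = stats::setNames(sens_matrix[i, ], pn),
         traj = if (is.null(trajs)) matrix(1, 1, length(phase)) else trajs[[i]])
  })
  structure(list(results = results, n_requested = n, n_failed = 0L,
                 n_steady = 0L, master_seed = 1L, phase_grid = phase,
                 param_names = pn,
                 state_names = paste0("x", seq_len(nrow(results[[1]]$traj))),
                 model_name = "fake", noise = list(xi = 0.1, eta = 0),
                 M = 10), class = "bootstrap_ensemble")
}
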