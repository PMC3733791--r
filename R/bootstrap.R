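#' Measurement noise model
#'
#' Gaussian noise whose standard deviation mixes a relative and an
#' absolute component: for state i at time j,
#' \deqn{\sigma_{ij} = \xi\, \tilde x_i(t_j) + \eta\, \max_j \tilde x_i(t_j),}
#' where \eqn{\tilde x} is the noise-free truth. The same \eqn{\sigma_{ij}}
#' is used both to draw simulated measurements and as the weight of the
#' least-squares cost. The small absolute term (default
#' \eqn{\eta = 0.001}) keeps errors in near-zero values from dominating
#' the cost.
#'
#' @param xi relative error, >= 0.
#' @param eta absolute error (fraction of each state's maximum), >= 0.
#'   `xi + eta` must be positive so the stds are valid weights.
#' @param preset optional shortcut: `"literature"` selects the optimistic
#'   xi = 0.03, eta = 0.005 assumption used when published time courses
#'   come without error bars.
#' @return an object of class `noise_model`.
#' @export
noiseModel <- function(xi = 0.15, eta = 0.001, preset = NULL) {
  if (!is.null(preset)) {
    if (identical(preset, "literature")) { xi <- 0.03; eta <- 0.005 }
    else cfArgError("unknown noise preset '%s'", preset)
  }
  if (xi < 0 || eta < 0) cfArgError("xi and eta must be non-negative")
  if (xi + eta <= 0)
    cfStop("cyclefit_invalid_noise_error",
           "xi + eta must be > 0 (stds double as optimization weights)")
  structure(list(xi = xi, eta = eta), class = "noise_model")
}

#' Sample noise-free truth data from a model's limit cycle
#'
#' Evaluates the limit cycle at M equispaced times over one period
#' [0, T), producing the ground-truth table that the bootstrap noise model
#' perturbs. Standard deviations are left unset (NA) until a noise model
#' fills them.
#'
#' @param model an [oscillatorModel()].
#' @param p parameter vector; default nominal.
#' @param M number of sampling points (>= 4).
#' @param cycle optional pre-solved [findLimitCycle()] result.
#' @param x0_guess starting state for the cycle search when `cycle` is not
#'   given.
#' @return a [timeSeriesDataset()] with NA stds.
#' @export
sampleTrueData <- function(model, p = model$nominal_params, M = 20,
                           cycle = NULL, x0_guess = NULL) {
  stopifnot(inherits(model, "oscillator_model"))
  if (M < 4) cfArgError("M must be >= 4")
  if (is.null(cycle)) {
    if (is.null(x0_guess)) x0_guess <- rep(0.5, model$neq)
    cycle <- findLimitCycle(model, p, x0_guess,
                            T_guess = if (is.null(model$period_hint)) 24
                                      else model$period_hint)
  }
  tj <- seq(0, cycle$period, length.out = M + 1)[seq_len(M)]
  timeSeriesDataset(tj, cycle$sampler(tj), state_names = model$state_names)
}

## Counter-based per-trial seed: two Lehmer (minstd) steps over the
## 2^31 - 1 field keep master/trial streams decorrelated and identical
## under serial or parallel execution. Exact in double arithmetic.
trialSeed <- function(master_seed, trial) {
  m <- 2147483647
  h <- (abs(master_seed) %% m)
  h <- (h * 48271) %% m
  h <- (h + trial) %% m
  h <- (h * 48271) %% m
  as.integer(if (h == 0) 1 else h)
}

#' Generate one noisy bootstrap dataset
#'
#' Draws simulated measurements independently per state and time from
#' \eqn{N(\tilde x_i(t_j), \sigma_{ij})} with
#' \eqn{\sigma_{ij} = \xi \tilde x_i(t_j) + \eta \max_j \tilde x_i(t_j)},
#' and stores the same sigmas as the dataset's weights. Draws may be
#' negative (Gaussian tails at low concentrations are not truncated);
#' set `clip_negative = TRUE` to clamp at zero.
#'
#' @param truth noise-free [timeSeriesDataset()] (e.g. [sampleTrueData()]).
#' @param noise a [noiseModel()].
#' @param seed integer seed making the draw deterministic.
#' @param clip_negative clamp sampled means at 0 (default FALSE).
#' @return a [timeSeriesDataset()] with means resampled and stds set.
#' @export
generateBootstrapDataset <- function(truth, noise, seed, clip_negative = FALSE) {
  stopifnot(inherits(truth, "time_series_dataset"),
            inherits(noise, "noise_model"))
  if (!all(is.finite(truth$means)))
    cfArgError("truth means must be finite (no missing points)")
  rowmax <- apply(truth$means, 1, max)
  sig <- noise$xi * truth$means + noise$eta * rowmax
  if (any(sig <= 0))
    cfStop("cyclefit_invalid_noise_error",
           "noise model yields non-positive sigma; increase eta")
  set.seed(as.integer(seed))
  draws <- matrix(stats::rnorm(length(sig), mean = truth$means, sd = sig),
                  nrow = nrow(sig))
  if (clip_negative) draws[draws < 0] <- 0
  timeSeriesDataset(truth$times, draws, sig, truth$state_names)
}

#' Run the bootstrap: repeated estimation on regenerated datasets
#'
#' For each of B trials, a fresh noisy dataset is generated (per-trial
#' seeds derived deterministically from `master_seed`, so serial and
#' parallel execution give identical ensembles), parameters are
#' re-estimated by [estimateParameters()], and on success the relative
#' period sensitivities of the re-solved cycle are computed. Trials whose
#' estimation fails to converge are counted in `n_failed`; trials whose
#' fitted dynamics reach a steady state (where periodic sensitivities are
#' undefined) in `n_steady`; both are discarded from the ensemble.
#'
#' @param model an [oscillatorModel()].
#' @param truth noise-free [timeSeriesDataset()] from [sampleTrueData()].
#' @param noise a [noiseModel()].
#' @param B number of trials (>= 1); 200 is a reasonable desk-scale
#'   default, large runs are embarrassingly parallel via `map_fun`.
#' @param config a [collocationConfig()].
#' @param master_seed integer master seed.
#' @param params_init initial parameter vector for every trial (default
#'   the model's nominal values).
#' @param clip_negative forwarded to [generateBootstrapDataset()].
#' @param map_fun a `lapply`-like function; swap in a parallel map to
#'   distribute trials.
#' @param n_phase number of phase points at which each converged cycle is
#'   stored for percentile bands.
#' @return an object of class `bootstrap_ensemble`: `results` (list with
#'   per-trial `params`, `period`, `cost`, `sens`, `traj`, `seed`),
#'   `n_requested`, `n_failed`, `n_steady`, `master_seed`, `phase_grid`.
#' @export
runBootstrap <- function(model, truth, noise, B = 200,
                         config = collocationConfig(), master_seed = 1,
                         params_init = NULL, clip_negative = FALSE,
                         map_fun = lapply, n_phase = 101) {
  stopifnot(inherits(model, "oscillator_model"))
  B <- as.integer(B)
  if (B < 1) cfArgError("B must be >= 1")
  phase <- seq(0, 1, length.out = n_phase)
  trials <- map_fun(seq_len(B), function(b) {
    seed_b <- trialSeed(master_seed, b)
    ds <- generateBootstrapDataset(truth, noise, seed_b, clip_negative)
    res <- tryCatch(
      estimateParameters(model, ds, config, params = params_init),
      cyclefit_error = function(e) NULL, error = function(e) NULL)
    if (is.null(res) || res$status == "failed")
      return(list(status = "failed", seed = seed_b))
    if (res$status == "steady_state")
      return(list(status = "steady_state", seed = seed_b))
    sens <- tryCatch(
      variationalPeriodSensitivities(model, res$cycle),
      cyclefit_error = function(e) NULL, error = function(e) NULL)
    if (is.null(sens)) return(list(status = "failed", seed = seed_b))
    list(status = "converged", seed = seed_b,
         params = res$p_star, period = res$cycle$period, cost = res$cost,
         sens = sens$values,
         traj = res$cycle$sampler(phase * res$cycle$period))
  })
  status <- vapply(trials, `[[`, "", "status")
  results <- trials[status == "converged"]
  ens <- structure(list(
    results = results,
    n_requested = B,
    n_failed = as.integer(sum(status == "failed")),
    n_steady = as.integer(sum(status == "steady_state")),
    master_seed = as.integer(master_seed),
    phase_grid = phase,
    param_names = model$param_names,
    state_names = model$state_names,
    model_name = model$name,
    noise = unclass(noise)[c("xi", "eta")],
    M = truth$M
  ), class = "bootstrap_ensemble")
  if (length(results) == 0)
    cfStop("cyclefit_empty_ensemble_error",
           "all %d bootstrap trials were discarded (%d failed, %d steady state)",
           B, ens$n_failed, ens$n_steady)
  ens
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf("<bootstrap_ensemble> '%s': %d/%d converged (%d failed, %d steady state)\n",
              x$model_name, length(x$results), x$n_requested,
              x$n_failed, x$n_steady))
  if (length(x$results)) {
    per <- vapply(x$results, `[[`, 0, "period")
    cat(sprintf("  period: median %.5g [%.5g, %.5g]\n", stats::median(per),
                stats::quantile(per, 0.05), stats::quantile(per, 0.95)))
  }
  invisible(x)
}

## Matrix of a per-trial named vector field across the ensemble
## (trials x entries).
ensembleMatrix <- function(ensemble, field) {
  do.call(rbind, lapply(ensemble$results, `[[`, field))
}

#' Pointwise percentile band of bootstrap trajectories
#'
#' Each converged trial's re-solved limit cycle is stored on its own
#' normalized phase grid; the band is the pointwise empirical percentile
#' (linear interpolation between order statistics, quantile type 7) of
#' those curves on a common phase grid, so cycles with different fitted
#' periods are compared at equal fractions of their own period.
#'
#' @param ensemble a [runBootstrap()] ensemble.
#' @param state state name or index.
#' @param grid phase grid in [0, 1]; defaults to the stored grid.
#' @param lo,hi percentiles (default 5 and 95).
#' @return list with `phase`, `lower`, `upper`, `median`.
#' @export
percentileBand <- function(ensemble, state, grid = NULL, lo = 5, hi = 95) {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"))
  if (length(ensemble$results) == 0) cfArgError("empty ensemble")
  if (!(lo >= 0 && lo < hi && hi <= 100))
    cfArgError("need 0 <= lo < hi <= 100")
  if (is.character(state)) {
    i <- match(state, ensemble$state_names)
    if (is.na(i)) cfArgError("unknown state '%s'", state)
  } else i <- as.integer(state)
  curves <- lapply(ensemble$results, function(r) r$traj[i, ])
  phase0 <- ensemble$phase_grid
  if (is.null(grid)) grid <- phase0
  mat <- do.call(rbind, lapply(curves, function(v) {
    if (identical(grid, phase0)) v
    else stats::spline(phase0, v, xout = grid %% 1, method = "periodic")$y
  }))
  list(phase = grid,
       lower = apply(mat, 2, stats::quantile, probs = lo / 100, type = 7),
       upper = apply(mat, 2, stats::quantile, probs = hi / 100, type = 7),
       median = apply(mat, 2, stats::median))
}

#' Classify practical identifiability of predicted responses
#'
#' A relative period sensitivity is declared practically identifiable for
#' the given data quality when at least a fraction `level` (default 0.95)
#' of its bootstrap distribution keeps one sign. A second, interval-based
#' rule is also reported: whether the 5th-95th percentile interval avoids
#' spanning zero (note the interval holds 90% of the mass, so the two
#' rules can disagree; the fraction rule is the default). Parameter
#' distributions are summarized by the same percentile interval.
#'
#' @param ensemble a [runBootstrap()] ensemble.
#' @param level sign-consistency level gamma in (0.5, 1].
#' @param lo,hi reporting percentiles (default 5/95).
#' @return an object of class `identifiability_report`: `table` (one row
#'   per parameter: parameter quantiles, sensitivity quantiles and median,
#'   `sign_consistent_fraction`, `identifiable` by the fraction rule,
#'   `identifiable_interval` by the interval rule), `level`, `n_results`,
#'   `low_power` flag (fewer than 20 trials).
#' @export
classifyIdentifiability <- function(ensemble, level = 0.95, lo = 5, hi = 95) {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"))
  n <- length(ensemble$results)
  if (n == 0) cfArgError("empty ensemble")
  if (!(level > 0.5 && level <= 1)) cfArgError("level must be in (0.5, 1]")
  P <- ensembleMatrix(ensemble, "params")
  S <- ensembleMatrix(ensemble, "sens")
  q <- function(v, pr) as.numeric(stats::quantile(v, pr / 100, type = 7, na.rm = TRUE))
  tab <- do.call(rbind, lapply(seq_along(ensemble$param_names), function(k) {
    s <- S[, k]; s <- s[!is.na(s)]
    fpos <- mean(s > 0); fneg <- mean(s < 0)
    frac <- max(fpos, fneg)
    slo <- q(s, lo); shi <- q(s, hi)
    data.frame(
      name = ensemble$param_names[k],
      param_lo = q(P[, k], lo), param_median = q(P[, k], 50),
      param_hi = q(P[, k], hi),
      sens_lo = slo, sens_median = q(s, 50), sens_hi = shi,
      sign_consistent_fraction = frac,
      identifiable = frac >= level,
      identifiable_interval = !(slo < 0 && shi > 0),
      stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, level = level, lo = lo, hi = hi,
                 n_results = n, low_power = n < 20,
                 rule = "fraction"),
            class = "identifiability_report")
}

#' @export
print.identifiability_report <- function(x, ...) {
  cat(sprintf("<identifiability_report>: %d trials, level %.2f%s\n",
              x$n_results, x$level,
              if (x$low_power) " [low power: < 20 trials]" else ""))
  df <- x$table
  df[-1] <- lapply(df[-1], function(v) if (is.numeric(v)) signif(v, 4) else v)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Cross-model consistency of identifiable responses
#'
#' Compares two identifiability reports over pairs of shared responses: a
#' pair is flagged robust when both sides are identifiable at their own
#' level and their median sensitivities share a sign — i.e. the predicted
#' response direction survives both measurement noise and the change of
#' model structure.
#'
#' @param reportA,reportB [classifyIdentifiability()] reports.
#' @param mapping named character vector `c(nameInA = nameInB, ...)`;
#'   defaults to the identity map on common names.
#' @return data.frame with one row per pair: names, per-side
#'   identifiability and median sign, and `robust`.
#' @export
compareModels <- function(reportA, reportB, mapping = NULL) {
  stopifnot(inherits(reportA, "identifiability_report"),
            inherits(reportB, "identifiability_report"))
  ta <- reportA$table; tb <- reportB$table
  if (is.null(mapping)) {
    common <- intersect(ta$name, tb$name)
    mapping <- stats::setNames(common, common)
  }
  out <- do.call(rbind, lapply(seq_along(mapping), function(i) {
    na <- names(mapping)[i]; nb <- mapping[[i]]
    ia <- match(na, ta$name); ib <- match(nb, tb$name)
    if (is.na(ia)) cfArgError("response '%s' not in reportA", na)
    if (is.na(ib)) cfArgError("response '%s' not in reportB", nb)
    sa <- sign(ta$sens_median[ia]); sb <- sign(tb$sens_median[ib])
    data.frame(
      response_a = na, response_b = nb,
      identifiable_a = ta$identifiable[ia],
      identifiable_b = tb$identifiable[ib],
      median_sign_a = sa, median_sign_b = sb,
      robust = ta$identifiable[ia] && tb$identifiable[ib] &&
        sa == sb && sa != 0,
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
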