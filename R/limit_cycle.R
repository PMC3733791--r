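#' Estimate the oscillation period from a sampled dataset
#'
#' The sampling design assumed throughout is that the data cover exactly
#' one cycle on an equispaced (or nearly equispaced) grid; the period is
#' then the span of the time grid extended by one sampling interval, so for
#' M points at spacing dt starting at t1 the estimate is t_M - t_1 + dt.
#' Flat (non-oscillatory) data are rejected.
#'
#' @param dataset a [timeSeriesDataset()] with M >= 4 points.
#' @return positive scalar period estimate.
#' @export
estimatePeriod <- function(dataset) {
  stopifnot(inherits(dataset, "time_series_dataset"))
  if (dataset$M < 4) cfArgError("need at least 4 sampling points")
  rng <- apply(dataset$means, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) 0 else diff(range(v))
  })
  scale <- apply(dataset$means, 1, function(v) mean(abs(v), na.rm = TRUE))
  if (all(rng < 1e-3 * pmax(scale, 1e-12) + 1e-12))
    cfStop("cyclefit_estimation_error",
           "data are flat; cannot estimate an oscillation period")
  diff(range(dataset$times)) + stats::median(diff(dataset$times))
}

## Periodic cubic-spline sampler through columns of `values` at `times`
## (times in [0, T), value at T identified with value at 0).
periodicSampler <- function(times, values, period, anchor_value = NULL) {
  nstate <- nrow(values)
  tt <- c(times, times[1] + period)
  splines <- lapply(seq_len(nstate), function(i) {
    y <- c(values[i, ], values[i, 1])
    stats::splinefun(tt, y, method = "periodic")
  })
  function(t) {
    tm <- times[1] + (t - times[1]) %% period
    out <- vapply(splines, function(s) s(tm), numeric(length(t)))
    if (length(t) == 1L) matrix(out, ncol = 1) else t(out)
  }
}

## Integrate state + monodromy (+ parameter sensitivities) over [0, tend].
## Returns xT, M = dphi/dx0, and S = dphi/dp when with_params.
variationalFlow <- function(model, p, x0, tend, with_params = FALSE,
                            rtol = 1e-9, atol = 1e-11) {
  neq <- model$neq; np <- model$np
  nv <- neq + neq * neq + if (with_params) neq * np else 0
  y0 <- c(x0, as.numeric(diag(neq)), if (with_params) rep(0, neq * np))
  deriv <- function(t, y, parms) {
    x <- y[1:neq]
    J <- modelJacobian(model, x, p)
    Phi <- matrix(y[neq + 1:(neq * neq)], neq, neq)
    dy <- c(model$rhs(x, p), as.numeric(J %*% Phi))
    if (with_params) {
      S <- matrix(y[neq + neq * neq + 1:(neq * np)], neq, np)
      dy <- c(dy, as.numeric(J %*% S + modelParamJacobian(model, x, p)))
    }
    list(dy)
  }
  out <- deSolve::ode(y0, c(0, tend), deriv, parms = NULL,
                      rtol = rtol, atol = atol, maxsteps = 100000)
  if (nrow(out) < 2 || !all(is.finite(out[2, -1])))
    cfStop("cyclefit_integration_error", "variational integration failed")
  yT <- out[2, -1]
  list(x = yT[1:neq],
       M = matrix(yT[neq + 1:(neq * neq)], neq, neq),
       S = if (with_params) matrix(yT[neq + neq * neq + 1:(neq * np)], neq, np))
}

## Locate the anchor for the phase condition: integrate a few periods,
## check for steady state, and return (state at the last/highest peak of
## state 1, refined period guess from peak spacing).
locateAnchor <- function(model, p, x0, T_guess, n_periods = 6,
                         steady_threshold = 1e-3) {
  grid <- seq(0, n_periods * T_guess, length.out = n_periods * 160 + 1)
  tr <- simulateModel(model, p, x0, grid)
  half <- tr$times >= max(tr$times) / 2
  if (detectSteadyState(tr, threshold = steady_threshold,
                        period = T_guess))
    cfStop("cyclefit_steady_state_error",
           "trajectory relaxes to a steady state; no limit cycle")
  t2 <- tr$times[half]; x1 <- tr$values[1, half]
  pk <- which(diff(sign(diff(x1))) == -2) + 1
  if (length(pk) >= 1) {
    # among peaks, take the one with the largest x1 (tie-break rule)
    best <- pk[which.max(x1[pk])]
    anchor <- tr$values[, half, drop = FALSE][, best]
    if (length(pk) >= 3) T_guess <- stats::median(diff(t2[pk]))
  } else {
    anchor <- tr$values[, ncol(tr$values)]
  }
  list(x0 = anchor, T = T_guess)
}

#' Find a limit cycle by single shooting
#'
#' Solves the periodic boundary-value problem x(T; x0) = x0 together with
#' the phase condition f_1(x0, p) = 0 (the anchor is a maximum of state 1,
#' which removes the time-translation degeneracy) by a damped Newton
#' iteration. The Newton Jacobian uses the monodromy matrix from the
#' variational equations. The returned period is checked to be fundamental
#' (x(T/2) differs from x0 whenever T/2 exceeds a small period floor), and
#' orbits whose relative amplitude falls below `steady_threshold` raise a
#' steady-state error so bootstrap callers can discard the trial.
#'
#' @param model an [oscillatorModel()].
#' @param p parameter vector (> 0).
#' @param x0_guess starting state; with `refine = TRUE` it only needs to be
#'   in the basin of the cycle (a pre-integration relocates it to a peak of
#'   state 1).
#' @param T_guess positive period guess.
#' @param refine run the pre-integration anchor search (default TRUE; turn
#'   off for warm starts already near the orbit).
#' @param tol Newton residual tolerance (default 1e-8, relative to 1+|x0|).
#' @param max_iter maximum Newton steps.
#' @param steady_threshold relative amplitude below which the orbit is
#'   declared degenerate.
#' @param n_dense number of dense output points stored on the orbit.
#' @return an object of class `limit_cycle`: fields `period`,
#'   `anchor_state`, `times`, `values` (dense orbit over one period),
#'   `sampler` (periodic interpolant, t -> state matrix), `amplitude`
#'   (per-state peak-to-peak), `residual`, `p`.
#' @export
findLimitCycle <- function(model, p = model$nominal_params, x0_guess,
                           T_guess = model$period_hint, refine = TRUE,
                           tol = 1e-8, max_iter = 50,
                           steady_threshold = 1e-3, n_dense = 241) {
  stopifnot(inherits(model, "oscillator_model"))
  p <- as.numeric(p)
  if (is.null(T_guess) || T_guess <= 0) cfArgError("T_guess must be positive")
  if (any(p <= 0)) cfArgError("parameters must be strictly positive")
  neq <- model$neq
  if (refine) {
    a <- locateAnchor(model, p, x0_guess, T_guess,
                      steady_threshold = steady_threshold)
    x0 <- a$x0; T <- a$T
  } else {
    x0 <- as.numeric(x0_guess); T <- T_guess
  }
  min_period <- 1e-3 * T_guess
  resfun <- function(x0, T) {
    fl <- variationalFlow(model, p, x0, T)
    r <- c(fl$x - x0, model$rhs(x0, p)[1])
    list(r = r, fl = fl)
  }
  cur <- resfun(x0, T)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    nrm <- sqrt(sum(cur$r^2))
    if (nrm <= tol * (1 + sqrt(sum(x0^2)))) { converged <- TRUE; break }
    f0 <- model$rhs(x0, p)
    if (max(abs(f0)) < 1e-9 * (1 + max(abs(x0))))
      cfStop("cyclefit_steady_state_error",
             "shooting iteration landed on a fixed point")
    fT <- model$rhs(cur$fl$x, p)
    J <- rbind(cbind(cur$fl$M - diag(neq), fT),
               c(modelJacobian(model, x0, p)[1, ], 0))
    step <- tryCatch(unname(solve(J, -cur$r)), error = function(e)
      cfStop("cyclefit_no_cycle_error",
             "singular shooting Jacobian (degenerate orbit?)"))
    lam <- 1
    for (h in 1:10) {
      x0n <- x0 + lam * step[1:neq]
      Tn <- T + lam * step[neq + 1]
      if (Tn > min_period) {
        nxt <- tryCatch(resfun(x0n, Tn), error = function(e) NULL)
        if (!is.null(nxt) && sqrt(sum(nxt$r^2)) < nrm) break
      }
      lam <- lam / 2
      nxt <- NULL
    }
    if (is.null(nxt))
      cfStop("cyclefit_no_cycle_error",
             "Newton line search failed at iteration %d (residual %.3e)", it, nrm)
    x0 <- x0n; T <- Tn; cur <- nxt
  }
  if (!converged) {
    if (sqrt(sum(cur$r^2)) <= tol * (1 + sqrt(sum(x0^2)))) converged <- TRUE
    else cfStop("cyclefit_no_cycle_error",
                "shooting Newton did not converge in %d iterations", max_iter)
  }
  if (T <= min_period)
    cfStop("cyclefit_no_cycle_error", "period collapsed below the floor")
  # fundamental-period check: fold out integer multiples
  for (div in c(3L, 2L)) {
    while (T / div > min_period) {
      xm <- flowMap(model, p, x0, T / div)
      if (sqrt(sum((xm - x0)^2)) < 1e-6 * (1 + sqrt(sum(x0^2)))) T <- T / div
      else break
    }
  }
  grid <- seq(0, T, length.out = n_dense)
  orbit <- simulateModel(model, p, x0, grid, rtol = 1e-10, atol = 1e-12)
  amp <- apply(orbit$values, 1, function(v) diff(range(v)))
  scale <- pmax(rowMeans(abs(orbit$values)), 1e-12)
  if (all(amp < steady_threshold * scale + 1e-12))
    cfStop("cyclefit_steady_state_error",
           "converged orbit is degenerate (amplitude below threshold)")
  structure(list(
    period = T,
    anchor_state = x0,
    times = orbit$times,
    values = orbit$values,
    sampler = periodicSampler(orbit$times[-n_dense],
                              orbit$values[, -n_dense, drop = FALSE], T),
    amplitude = stats::setNames(amp, model$state_names),
    residual = sqrt(sum(cur$r^2)),
    n_iterations = it,
    p = stats::setNames(p, model$param_names)
  ), class = "limit_cycle")
}

#' @export
print.limit_cycle <- function(x, ...) {
  cat(sprintf("<limit_cycle>: period T = %.6g, residual %.2e\n",
              x$period, x$residual))
  cat("  amplitudes:", paste(sprintf("%.4g", x$amplitude), collapse = ", "), "\n")
  invisible(x)
}
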