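#' Construct a trajectory object
#'
#' A discrete representation of a solution path: a strictly increasing time
#' grid and an NEQ x length(times) matrix of state values.
#'
#' @param times strictly increasing numeric vector.
#' @param values numeric matrix, one row per state, one column per time;
#'   a vector is accepted for single-state systems.
#' @param state_names optional character vector of row names.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(times, values, state_names = NULL) {
  times <- as.numeric(times)
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  values <- as.matrix(values)
  if (any(diff(times) <= 0)) cfArgError("trajectory times must be strictly increasing")
  if (ncol(values) != length(times))
    cfArgError("values must have one column per time point")
  if (!all(is.finite(values))) cfArgError("trajectory values must be finite")
  if (!is.null(state_names)) rownames(values) <- state_names
  structure(list(times = times, values = values), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory>: %d states x %d times on [%.4g, %.4g]\n",
              nrow(x$values), length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Integrate an oscillator model
#'
#' Stiff-capable initial-value integration of `dx/dt = f(x, p)` on a given
#' time grid, wrapping [deSolve::ode()] (lsoda).
#'
#' @param model an [oscillatorModel()].
#' @param p parameter vector (> 0); defaults to the model's nominal values.
#' @param x0 initial state vector.
#' @param times strictly increasing output grid.
#' @param rtol,atol integrator tolerances (defaults 1e-8 / 1e-10).
#' @return a [trajectory()].
#' @export
simulateModel <- function(model, p = model$nominal_params, x0, times,
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "oscillator_model"))
  p <- as.numeric(p); x0 <- as.numeric(x0)
  if (any(p <= 0)) cfArgError("parameters must be strictly positive")
  if (any(diff(times) <= 0)) cfArgError("times must be strictly increasing")
  if (length(x0) != model$neq) cfArgError("x0 has wrong length")
  deriv <- function(t, x, parms) list(model$rhs(x, p))
  jacf <- if (!is.null(model$jac)) function(t, x, parms) model$jac(x, p)
  out <- try(deSolve::ode(y = x0, times = times, func = deriv, parms = NULL,
                          jacfunc = jacf,
                          jactype = if (is.null(jacf)) "fullint" else "fullusr",
                          rtol = rtol, atol = atol, maxsteps = 50000),
             silent = TRUE)
  if (inherits(out, "try-error"))
    cfStop("cyclefit_integration_error", "ODE integration failed: %s",
           attr(out, "condition")$message)
  if (nrow(out) < length(times) || !all(is.finite(out[, -1])))
    cfStop("cyclefit_integration_error",
           "ODE integration failed near t = %.6g", out[nrow(out), 1])
  trajectory(out[, 1], t(out[, -1, drop = FALSE]), model$state_names)
}

## Flow map: integrate from x0 over [0, tend], return final state.
flowMap <- function(model, p, x0, tend, rtol = 1e-8, atol = 1e-10) {
  tr <- simulateModel(model, p, x0, c(0, tend), rtol = rtol, atol = atol)
  tr$values[, ncol(tr$values)]
}

#' Detect a steady-state (non-oscillatory) trajectory
#'
#' A trajectory is flagged as steady state when, over its final window,
#' every state's peak-to-peak range is below `threshold` times the state's
#' mean magnitude (with a small absolute floor to handle states near zero).
#' Bootstrap trials whose fitted dynamics end up here are discarded, since
#' the period and its sensitivities are undefined at a fixed point.
#'
#' @param traj a [trajectory()] covering at least two putative periods.
#' @param threshold relative amplitude threshold (default 1e-3).
#' @param period optional window length (time units) to inspect at the end
#'   of the trajectory; defaults to half the trajectory span.
#' @return logical scalar.
#' @export
detectSteadyState <- function(traj, threshold = 1e-3, period = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  span <- diff(range(traj$times))
  if (is.null(period)) period <- span / 2
  if (period <= 0 || span < 2 * period)
    cfArgError("trajectory too short: must cover at least two periods")
  sel <- traj$times >= max(traj$times) - period
  if (sum(sel) < 4) cfArgError("too few points in the final period window")
  w <- traj$values[, sel, drop = FALSE]
  rng <- apply(w, 1, function(v) diff(range(v)))
  scale <- pmax(rowMeans(abs(w)), 1e-12)
  all(rng < threshold * scale + 1e-12)
}
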