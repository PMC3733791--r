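#' Relative period sensitivities via the variational equations
#'
#' Computes the dimensionless first-order sensitivities
#' \eqn{s_k = \partial \ln T / \partial \ln p_k = (p_k/T)\, dT/dp_k}
#' of a limit cycle's period to each parameter. The state and parametric
#' variational equations are integrated over one period to obtain the
#' monodromy matrix \eqn{M = \partial x(T)/\partial x_0} and the parameter
#' sensitivity block \eqn{S = \partial x(T)/\partial p}; differentiating
#' the periodic boundary-value residual
#' \eqn{[x(T; x_0, p) - x_0;\ f_1(x_0, p)] = 0} with respect to p then
#' gives a bordered linear system for \eqn{dx_0/dp} and \eqn{dT/dp}:
#' \deqn{\begin{pmatrix} M - I & f(x_0) \\ \nabla_x f_1 & 0 \end{pmatrix}
#'       \begin{pmatrix} dx_0/dp \\ dT/dp \end{pmatrix} =
#'       -\begin{pmatrix} S \\ \partial f_1/\partial p \end{pmatrix}.}
#' The bordered matrix is singular when a second Floquet multiplier sits at
#' 1 (degenerate orbit); this raises a degeneracy error.
#'
#' @param model an [oscillatorModel()].
#' @param cycle a [findLimitCycle()] result at parameters `p`.
#' @param p parameter vector (defaults to the cycle's).
#' @return an object of class `period_sensitivity`: `values` (named vector,
#'   length NP), `method = "variational"`, `period`, `condition` (condition
#'   number of the bordered matrix).
#' @export
variationalPeriodSensitivities <- function(model, cycle, p = cycle$p) {
  stopifnot(inherits(model, "oscillator_model"), inherits(cycle, "limit_cycle"))
  p <- as.numeric(p)
  if (any(p <= 0)) cfArgError("parameters must be strictly positive")
  neq <- model$neq
  x0 <- cycle$anchor_state
  T <- cycle$period
  fl <- variationalFlow(model, p, x0, T, with_params = TRUE)
  f0 <- model$rhs(x0, p)
  A <- rbind(cbind(fl$M - diag(neq), f0),
             c(modelJacobian(model, x0, p)[1, ], 0))
  kap <- kappa(A, exact = TRUE)
  if (!is.finite(kap) || kap > 1e10)
    cfStop("cyclefit_degeneracy_error",
           "bordered periodic-BVP system is singular (condition %.3e)", kap)
  B <- -rbind(fl$S, modelParamJacobian(model, x0, p)[1, ])
  sol <- solve(A, B)
  dTdp <- sol[neq + 1, ]
  structure(list(
    values = stats::setNames(p / T * dTdp, model$param_names),
    method = "variational",
    period = T,
    condition = kap
  ), class = "period_sensitivity")
}

#' Relative period sensitivities by central finite differences
#'
#' Independent cross-check of [variationalPeriodSensitivities()]: each
#' parameter is perturbed multiplicatively to \eqn{p_k e^{\pm h}}, the
#' limit cycle is re-solved warm-started from the unperturbed orbit, and
#' the sensitivity is the exact symmetric log-difference
#' \eqn{(\ln T_+ - \ln T_-)/(2h)}. A perturbation that destroys the
#' oscillation yields `NA` for that parameter.
#'
#' @param model an [oscillatorModel()].
#' @param cycle unperturbed [findLimitCycle()] result.
#' @param p parameter vector (defaults to the cycle's).
#' @param rel_step relative step h in (0, 0.1]; default 1e-3.
#' @return a `period_sensitivity` object with `method = "finite_difference"`.
#' @export
fdPeriodSensitivities <- function(model, cycle, p = cycle$p, rel_step = 1e-3) {
  stopifnot(inherits(model, "oscillator_model"), inherits(cycle, "limit_cycle"))
  if (rel_step <= 0 || rel_step > 0.1)
    cfArgError("rel_step must be in (0, 0.1]")
  p <- as.numeric(p)
  solveT <- function(pk) {
    cyc <- tryCatch(
      findLimitCycle(model, pk, cycle$anchor_state, cycle$period,
                     refine = FALSE),
      cyclefit_steady_state_error = function(e) NULL,
      cyclefit_no_cycle_error = function(e) NULL)
    if (is.null(cyc)) NA_real_ else cyc$period
  }
  vals <- vapply(seq_along(p), function(k) {
    pp <- p; pm <- p
    pp[k] <- p[k] * exp(rel_step)
    pm[k] <- p[k] * exp(-rel_step)
    Tp <- solveT(pp); Tm <- solveT(pm)
    if (is.na(Tp) || is.na(Tm)) return(NA_real_)
    (log(Tp) - log(Tm)) / (2 * rel_step)
  }, numeric(1))
  structure(list(
    values = stats::setNames(vals, model$param_names),
    method = "finite_difference",
    period = cycle$period,
    rel_step = rel_step
  ), class = "period_sensitivity")
}

#' @export
print.period_sensitivity <- function(x, ...) {
  cat(sprintf("<period_sensitivity> (%s), T = %.6g\n", x$method, x$period))
  print(round(x$values, 6))
  invisible(x)
}

#' Finite-ratio sensitivity from measured fractional changes
#'
#' Calibration helper converting an experimentally measured fractional
#' period change under a known fractional parameter change into a relative
#' sensitivity magnitude: e.g. a 5% period change caused by a 50% increase
#' of a degradation rate corresponds to a relative period sensitivity of
#' 0.1. Useful for judging which predicted sensitivities are large enough
#' to verify experimentally.
#'
#' @param period_change_fraction fractional change in period (e.g. 0.05).
#' @param param_change_fraction fractional change in the parameter
#'   (non-zero, e.g. 0.50).
#' @return scalar ratio.
#' @export
finiteRatioSensitivity <- function(period_change_fraction, param_change_fraction) {
  if (!is.finite(param_change_fraction) || param_change_fraction == 0)
    cfArgError("param_change_fraction must be non-zero")
  period_change_fraction / param_change_fraction
}
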