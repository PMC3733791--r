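#' Construct an autonomous oscillator model
#'
#' An `oscillator_model` bundles an autonomous right-hand side
#' \eqn{dx/dt = f(x, p)} with state/parameter names and nominal parameter
#' values. The right-hand side must depend only on the state vector and the
#' parameter vector, never on time; all parameters are interpreted as
#' positive kinetic rates.
#'
#' @param state_names character vector of unique state identifiers (length NEQ).
#' @param param_names character vector of unique parameter identifiers (length NP).
#' @param rhs function `(x, p) -> dx/dt` returning a numeric vector of length NEQ.
#' @param nominal_params named or unnamed numeric vector of length NP; all
#'   entries must be finite and strictly positive.
#' @param period_hint optional positive scalar, a rough guess of the
#'   oscillation period in the time units of the data (hours for the
#'   circadian-style fixtures).
#' @param jac optional function `(x, p)` returning the NEQ x NEQ state
#'   Jacobian of `rhs`; a central finite-difference Jacobian is used when
#'   omitted.
#' @param pjac optional function `(x, p)` returning the NEQ x NP parameter
#'   Jacobian of `rhs`; finite differences when omitted.
#' @param name optional model label used in printing and serialization.
#'
#' @return an object of class `oscillator_model` with fields
#'   `state_names`, `param_names`, `rhs`, `nominal_params`, `period_hint`,
#'   `neq`, `np`.
#' @seealso [goodwinFixture()], [dampedFixture()], [evaluateRhs()]
#' @export
oscillatorModel <- function(state_names, param_names, rhs, nominal_params,
                            period_hint = NULL, jac = NULL, pjac = NULL,
                            name = "oscillator") {
  state_names <- as.character(state_names)
  param_names <- as.character(param_names)
  if (anyDuplicated(state_names)) stop("state_names must be unique", call. = FALSE)
  if (anyDuplicated(param_names)) stop("param_names must be unique", call. = FALSE)
  if (!is.function(rhs)) stop("rhs must be a function(x, p)", call. = FALSE)
  nominal_params <- as.numeric(nominal_params)
  if (length(nominal_params) != length(param_names))
    stop("nominal_params length must equal length(param_names)", call. = FALSE)
  if (!all(is.finite(nominal_params)))
    stop("nominal_params must be finite", call. = FALSE)
  if (any(nominal_params <= 0))
    stop("nominal_params must be strictly positive (kinetic rates)", call. = FALSE)
  if (!is.null(period_hint)) {
    period_hint <- as.numeric(period_hint)
    if (length(period_hint) != 1L || !is.finite(period_hint) || period_hint <= 0)
      stop("period_hint must be a positive scalar", call. = FALSE)
  }
  names(nominal_params) <- param_names
  structure(list(
    state_names = state_names,
    param_names = param_names,
    rhs = rhs,
    jac = jac,
    pjac = pjac,
    nominal_params = nominal_params,
    period_hint = period_hint,
    neq = length(state_names),
    np = length(param_names),
    name = name
  ), class = "oscillator_model")
}

#' @export
print.oscillator_model <- function(x, ...) {
  cat(sprintf("<oscillator_model '%s'>: %d states, %d parameters\n",
              x$name, x$neq, x$np))
  cat("  states:    ", paste(x$state_names, collapse = ", "), "\n")
  cat("  parameters:", paste(sprintf("%s=%.4g", x$param_names, x$nominal_params),
                             collapse = ", "), "\n")
  if (!is.null(x$period_hint))
    cat(sprintf("  period hint: %.4g\n", x$period_hint))
  invisible(x)
}

#' Evaluate the model right-hand side
#'
#' Computes the derivative vector \eqn{f(x, p)} of an oscillator model at a
#' given state and parameter vector, with dimension and finiteness checks.
#'
#' @param model an [oscillatorModel()].
#' @param x numeric state vector of length `model$neq`.
#' @param p numeric parameter vector of length `model$np`, elementwise > 0.
#' @return numeric derivative vector of length `model$neq`.
#' @export
evaluateRhs <- function(model, x, p = model$nominal_params) {
  stopifnot(inherits(model, "oscillator_model"))
  x <- as.numeric(x); p <- as.numeric(p)
  if (length(x) != model$neq)
    stop(sprintf("state vector has length %d, expected NEQ = %d",
                 length(x), model$neq), call. = FALSE)
  if (length(p) != model$np)
    stop(sprintf("parameter vector has length %d, expected NP = %d",
                 length(p), model$np), call. = FALSE)
  if (any(p <= 0)) stop("parameters must be strictly positive", call. = FALSE)
  dx <- as.numeric(model$rhs(x, p))
  if (length(dx) != model$neq)
    stop("rhs returned a vector of the wrong length", call. = FALSE)
  if (!all(is.finite(dx)))
    stop("rhs evaluation produced non-finite values",
         call. = FALSE)
  dx
}

## State Jacobian of f, analytic when the model supplies one, otherwise
## central finite differences with a step scaled to the state magnitude.
modelJacobian <- function(model, x, p) {
  if (!is.null(model$jac)) return(model$jac(x, p))
  n <- length(x)
  J <- matrix(0.0, n, n)
  h <- 1e-6 * pmax(abs(x), 1)
  for (k in seq_len(n)) {
    xp <- x; xm <- x
    xp[k] <- xp[k] + h[k]; xm[k] <- xm[k] - h[k]
    J[, k] <- (model$rhs(xp, p) - model$rhs(xm, p)) / (2 * h[k])
  }
  J
}

## Parameter Jacobian df/dp (NEQ x NP), analytic or central differences.
modelParamJacobian <- function(model, x, p) {
  if (!is.null(model$pjac)) return(model$pjac(x, p))
  np <- length(p)
  Jp <- matrix(0.0, length(x), np)
  h <- 1e-6 * pmax(abs(p), 1e-8)
  for (k in seq_len(np)) {
    pp <- p; pm <- p
    pp[k] <- pp[k] + h[k]; pm[k] <- pm[k] - h[k]
    Jp[, k] <- (model$rhs(x, pp) - model$rhs(x, pm)) / (2 * h[k])
  }
  Jp
}

goodwinRhsFactory <- function(hill) {
  force(hill)
  function(x, p) {
    c(p[1] / (1 + x[3]^hill) - p[2] * x[1],
      p[3] * x[1] - p[4] * x[2],
      p[5] * x[2] - p[6] * x[3])
  }
}

goodwinJacFactory <- function(hill) {
  force(hill)
  function(x, p) {
    matrix(c(-p[2], 0,     -p[1] * hill * x[3]^(hill - 1) / (1 + x[3]^hill)^2,
             p[3],  -p[4],  0,
             0,      p[5], -p[6]),
           nrow = 3, byrow = TRUE)
  }
}

goodwinPjacFactory <- function(hill) {
  force(hill)
  function(x, p) {
    matrix(c(1 / (1 + x[3]^hill), -x[1], 0,     0,    0,    0,
             0,                   0,     x[1], -x[2], 0,    0,
             0,                   0,     0,     0,    x[2], -x[3]),
           nrow = 3, byrow = TRUE)
  }
}

#' Goodwin-type negative-feedback oscillator fixture
#'
#' A three-state transcription/translation loop in which the end product
#' represses synthesis of the first species through a Hill function:
#' \deqn{dx_1/dt = a/(1 + x_3^n) - b x_1,\quad
#'       dx_2/dt = c x_1 - d x_2,\quad
#'       dx_3/dt = e x_2 - g x_3.}
#' With high Hill cooperativity (default \eqn{n = 10}; sustained
#' oscillation of this loop requires \eqn{n > 8}) and the nominal rates
#' chosen here, the model has an attracting limit cycle with a period of
#' about 24 hours, mimicking a minimal circadian oscillator. The Hill
#' exponent is a structural constant of the fixture, not an estimated
#' parameter, and every estimated parameter enters the right-hand side as a
#' multiplicative rate, so the model obeys the time-rescaling symmetry
#' \eqn{f(x, \lambda p) = \lambda f(x, p)}.
#'
#' @param hill Hill exponent \eqn{n} (structural constant; default 10).
#' @return an [oscillatorModel()] with states `x1, x2, x3` and parameters
#'   `a, b, c, d, e, g`.
#' @export
goodwinFixture <- function(hill = 10) {
  oscillatorModel(
    state_names = c("x1", "x2", "x3"),
    param_names = c("a", "b", "c", "d", "e", "g"),
    rhs = goodwinRhsFactory(hill),
    jac = goodwinJacFactory(hill),
    pjac = goodwinPjacFactory(hill),
    nominal_params = c(a = 0.95, b = 0.16, c = 0.32, d = 0.16, e = 0.32, g = 0.16),
    period_hint = 24,
    name = sprintf("goodwin(n=%g)", hill)
  )
}

#' Damped negative-feedback fixture (negative control)
#'
#' The same three-state loop as [goodwinFixture()] but with Hill exponent
#' below the oscillation threshold, so all trajectories spiral into a
#' stable fixed point. Used to exercise steady-state detection and the
#' bootstrap discard rules.
#'
#' @param hill Hill exponent, default 2 (no sustained oscillation).
#' @return an [oscillatorModel()] whose nominal dynamics are damped.
#' @export
dampedFixture <- function(hill = 2) {
  m <- goodwinFixture(hill = hill)
  m$name <- sprintf("damped-goodwin(n=%g)", hill)
  m
}
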