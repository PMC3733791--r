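## Legendre polynomial coefficients (ascending powers) by the three-term
## recurrence (n+1) P_{n+1} = (2n+1) x P_n - n P_{n-1}.
legendreCoef <- function(n) {
  if (n == 0) return(1)
  if (n == 1) return(c(0, 1))
  pm1 <- 1; p <- c(0, 1)
  for (k in 1:(n - 1)) {
    xp <- c(0, p)                       # x * P_k
    a <- (2 * k + 1) * xp
    b <- c(k * pm1, rep(0, length(xp) - length(pm1) - 1))
    nxt <- (a - c(b, 0)[seq_along(a)]) / (k + 1)
    pm1 <- p; p <- nxt
  }
  p
}

#' Radau collocation points
#'
#' Returns the K collocation points of the right-endpoint Radau (Radau IIA)
#' family on the normalized element (0, 1]. These nodes include the right
#' endpoint of the element, which makes element-end states explicit for the
#' continuity constraints and gives the stiff-stable discretization used by
#' the fitting transcription. The points are the roots of
#' \eqn{P_{K-1}(2\tau-1) - P_K(2\tau-1)} where \eqn{P_K} is the Legendre
#' polynomial of degree K.
#'
#' @param K polynomial degree (number of collocation points), K >= 1.
#' @param scheme collocation family; only `"radau"` is supported.
#' @return numeric vector of K strictly increasing points in (0, 1], the
#'   last equal to 1.
#' @export
collocationPoints <- function(K, scheme = "radau") {
  if (!identical(scheme, "radau"))
    cfArgError("unsupported collocation scheme '%s' (only 'radau')", scheme)
  K <- as.integer(K)
  if (K < 1) cfArgError("degree K must be >= 1")
  if (K == 1) return(1.0)
  a <- legendreCoef(K - 1); b <- legendreCoef(K)
  co <- c(a, 0) - b                      # P_{K-1} - P_K, ascending in x
  r <- polyroot(co)
  r <- Re(r[abs(Im(r)) < 1e-8])
  pts <- sort((r + 1) / 2)
  # polish with Newton on the polynomial for clean double-precision roots
  f <- function(x) {
    xi <- 2 * x - 1
    sum(co * xi^(seq_along(co) - 1))
  }
  df <- function(x) {
    k <- seq_along(co) - 1
    xi <- 2 * x - 1
    2 * sum(co[-1] * k[-1] * xi^(k[-1] - 1))
  }
  for (i in seq_along(pts)) {
    for (it in 1:5) pts[i] <- pts[i] - f(pts[i]) / df(pts[i])
  }
  pts[length(pts)] <- 1.0
  pts
}

## Lagrange basis over nodes `xs`, evaluated at `x`: weights w with
## sum_l w_l * y_l = interpolant(x). Direct product formula; the node
## counts here (<= ~10) make stability a non-issue.
lagrangeWeights <- function(xs, x) {
  n <- length(xs)
  w <- numeric(n)
  for (l in seq_len(n)) {
    num <- 1; den <- 1
    for (m in seq_len(n)) {
      if (m == l) next
      num <- num * (x - xs[m])
      den <- den * (xs[l] - xs[m])
    }
    w[l] <- num / den
  }
  w
}

## Derivative of the Lagrange basis at `x`: w'_l(x).
lagrangeDerivWeights <- function(xs, x) {
  n <- length(xs)
  d <- numeric(n)
  for (l in seq_len(n)) {
    den <- prod(xs[l] - xs[-l])
    s <- 0
    for (m in seq_len(n)) {
      if (m == l) next
      s <- s + prod(x - xs[-c(l, m)])
    }
    d[l] <- s / den
  }
  d
}

## Differentiation matrix D[q, l] = l_l'(tau_q) over nodes0 = (0, radau pts),
## rows only at the K collocation points.
collocationDiffMatrix <- function(nodes0, colloc) {
  D <- matrix(0.0, length(colloc), length(nodes0))
  for (q in seq_along(colloc))
    D[q, ] <- lagrangeDerivWeights(nodes0, colloc[q])
  D
}

#' Number of decision variables of the collocation NLP
#'
#' The transcription carries the state values at all K+1 nodes of each of
#' the N finite elements plus the NP parameters, giving
#' \eqn{N (K+1) NEQ + NP} variables. (The implementation additionally
#' treats the period as one extra free variable; this helper reports the
#' textbook count for the fixed-period transcription.)
#'
#' @param N number of finite elements.
#' @param K polynomial degree per element.
#' @param NEQ number of state variables.
#' @param NP number of parameters.
#' @return integer N*(K+1)*NEQ + NP.
#' @export
countDecisionVariables <- function(N, K, NEQ, NP) {
  stopifnot(N >= 0, K >= 0, NEQ >= 0, NP >= 0)
  as.integer(round(N * (K + 1) * NEQ + NP))
}

#' Collocation and solver settings
#'
#' @param n_elements number of finite elements N (>= 1) on the normalized
#'   period.
#' @param degree polynomial degree K (>= 1) per element.
#' @param scheme collocation point family (only `"radau"`).
#' @param bound_factor multiplicative half-range of the parameter box:
#'   parameters are kept in `[guess/bound_factor, guess*bound_factor]`
#'   (log-scaled internally), which keeps rates positive and conditions the
#'   problem.
#' @param period_bound_factor multiplicative box for the free period.
#' @param constraint_tol maximum absolute collocation/continuity residual
#'   accepted as "converged" (default 1e-6).
#' @param max_outer maximum augmented-Lagrangian sweeps.
#' @param max_iter Levenberg-Marquardt iterations per sweep.
#' @param penalty initial quadratic-penalty weight on the constraints.
#' @param ftol,ptol inner solver tolerances (see [minpack.lm::nls.lm()]).
#' @return an object of class `collocation_config`.
#' @export
collocationConfig <- function(n_elements = 10, degree = 4, scheme = "radau",
                              bound_factor = 1e3, period_bound_factor = 5,
                              constraint_tol = 1e-6, max_outer = 10,
                              max_iter = 120, penalty = 1e4,
                              ftol = 1e-12, ptol = 1e-12) {
  if (n_elements < 1 || degree < 1)
    cfArgError("n_elements and degree must both be >= 1")
  colloc <- collocationPoints(degree, scheme)   # validates scheme
  structure(list(
    n_elements = as.integer(n_elements), degree = as.integer(degree),
    scheme = scheme, colloc = colloc, nodes0 = c(0, colloc),
    diffmat = collocationDiffMatrix(c(0, colloc), colloc),
    bound_factor = bound_factor, period_bound_factor = period_bound_factor,
    constraint_tol = constraint_tol, max_outer = as.integer(max_outer),
    max_iter = as.integer(max_iter), penalty = penalty,
    ftol = ftol, ptol = ptol
  ), class = "collocation_config")
}

#' @export
print.collocation_config <- function(x, ...) {
  cat(sprintf("<collocation_config>: N=%d elements, K=%d (%s), constraint tol %.1e\n",
              x$n_elements, x$degree, x$scheme, x$constraint_tol))
  invisible(x)
}
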