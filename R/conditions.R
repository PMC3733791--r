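## Classed conditions so callers (and the bootstrap discard logic) can
## distinguish "no limit cycle", "converged to steady state", integrator
## blow-up, and plain argument errors.

cfStop <- function(class, fmt, ..., data = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "cyclefit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), data = data)
  )
  stop(cond)
}

cfArgError <- function(fmt, ...) cfStop("cyclefit_argument_error", fmt, ...)
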