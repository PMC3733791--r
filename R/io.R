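## JSON serialization for results. Documents carry a schema tag and a type
## so readResults can dispatch; numbers are written at full double
## precision (17 significant digits) to guarantee round-trips.

cfSchema <- "cyclefit/1"

resultPayload <- function(x) {
  if (inherits(x, "estimate_result")) {
    list(
      type = "estimate_result",
      p_star = as.list(x$p_star), period = x$period,
      cost = x$cost, initial_cost = x$initial_cost,
      initial_objective = x$initial_objective,
      status = x$status, n_iterations = x$n_iterations,
      constraint_violation = x$constraint_violation,
      consistency = x$consistency, model_name = x$model_name,
      config = list(n_elements = x$config$n_elements,
                    degree = x$config$degree, scheme = x$config$scheme),
      trajectory = if (!is.null(x$cycle)) list(
        times = x$cycle$times,
        values = x$cycle$values,
        anchor_state = x$cycle$anchor_state,
        amplitude = as.list(x$cycle$amplitude))
    )
  } else if (inherits(x, "bootstrap_ensemble")) {
    list(
      type = "bootstrap_ensemble",
      n_requested = x$n_requested, n_failed = x$n_failed,
      n_steady = x$n_steady, master_seed = x$master_seed,
      phase_grid = x$phase_grid, param_names = x$param_names,
      state_names = x$state_names, model_name = x$model_name,
      noise = x$noise, M = x$M,
      results = lapply(x$results, function(r)
        list(status = r$status, seed = r$seed, params = as.list(r$params),
             period = r$period, cost = r$cost, sens = as.list(r$sens),
             traj = r$traj))
    )
  } else if (inherits(x, "identifiability_report")) {
    list(type = "identifiability_report", level = x$level,
         lo = x$lo, hi = x$hi, n_results = x$n_results,
         low_power = x$low_power, rule = x$rule, table = x$table)
  } else cfArgError("cannot serialize objects of class '%s'", class(x)[1])
}

#' Write a result object to JSON
#'
#' Serializes an `estimate_result`, `bootstrap_ensemble` or
#' `identifiability_report` to a schema-versioned JSON document at full
#' numeric precision. [readResults()] reconstructs an equal object (dense
#' interpolants are rebuilt from the stored trajectory grid).
#'
#' @param x the object to write.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeResults <- function(x, path) {
  doc <- c(list(schema = cfSchema), resultPayload(x))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           na = "null", null = "null", pretty = TRUE)
  ok <- tryCatch({ writeLines(json, path); TRUE },
                 error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) cfStop("cyclefit_io_error", "cannot write to '%s'", path)
  invisible(path)
}

#' Read a result object back from JSON
#'
#' @param path a file written by [writeResults()].
#' @return an object of the class recorded in the document.
#' @export
readResults <- function(path) {
  if (!file.exists(path)) cfArgError("file not found: %s", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$schema, cfSchema))
    cfStop("cyclefit_parse_error", "unknown or missing schema in '%s'", path)
  num <- function(x) as.numeric(unlist(x))
  nmat <- function(x) do.call(rbind, lapply(x, num))   # list of rows -> matrix
  if (doc$type == "estimate_result") {
    out <- list(
      p_star = unlist(doc$p_star), period = num(doc$period),
      cycle = if (!is.null(doc$trajectory)) {
        tv <- doc$trajectory
        times <- num(tv$times)
        values <- nmat(tv$values)
        n <- length(times)
        structure(list(
          period = num(doc$period), anchor_state = num(tv$anchor_state),
          times = times, values = values,
          sampler = periodicSampler(times[-n], values[, -n, drop = FALSE],
                                    num(doc$period)),
          amplitude = unlist(tv$amplitude), residual = NA_real_,
          p = unlist(doc$p_star)), class = "limit_cycle")
      },
      cost = num(doc$cost), initial_cost = num(doc$initial_cost),
      initial_objective = num(doc$initial_objective), status = doc$status,
      n_iterations = as.integer(doc$n_iterations),
      constraint_violation = num(doc$constraint_violation),
      consistency = num(doc$consistency), model_name = doc$model_name,
      config = doc$config, z = NULL, message = "")
    class(out) <- "estimate_result"
    out
  } else if (doc$type == "bootstrap_ensemble") {
    results <- lapply(doc$results, function(r)
      list(status = r$status, seed = as.integer(r$seed),
           params = unlist(r$params), period = num(r$period),
           cost = num(r$cost), sens = unlist(r$sens),
           traj = nmat(r$traj)))
    structure(list(
      results = results, n_requested = as.integer(doc$n_requested),
      n_failed = as.integer(doc$n_failed),
      n_steady = as.integer(doc$n_steady),
      master_seed = as.integer(doc$master_seed),
      phase_grid = num(doc$phase_grid),
      param_names = unlist(doc$param_names),
      state_names = unlist(doc$state_names),
      model_name = doc$model_name, noise = doc$noise,
      M = as.integer(doc$M)
    ), class = "bootstrap_ensemble")
  } else if (doc$type == "identifiability_report") {
    tab <- do.call(rbind, lapply(doc$table, function(r)
      data.frame(r, stringsAsFactors = FALSE)))
    structure(list(table = tab, level = num(doc$level), lo = num(doc$lo),
                   hi = num(doc$hi), n_results = as.integer(doc$n_results),
                   low_power = isTRUE(doc$low_power), rule = doc$rule),
              class = "identifiability_report")
  } else cfStop("cyclefit_parse_error", "unknown result type '%s'", doc$type)
}

#' Read a model definition from a YAML/JSON config file
#'
#' The config selects a built-in right-hand side through a registry key
#' and may override its nominal parameter values and period hint:
#' \preformatted{
#' name: my-oscillator
#' registry: goodwin      # or 'damped'
#' hill: 10               # optional structural constant
#' params: {a: 0.95, b: 0.16, c: 0.32, d: 0.16, e: 0.32, g: 0.16}
#' period_hint: 24
#' }
#' User-defined right-hand sides are supplied programmatically with
#' [oscillatorModel()]; there is deliberately no eval-from-config path.
#'
#' @param path YAML (or JSON) file.
#' @return an [oscillatorModel()].
#' @export
readModelConfig <- function(path) {
  if (!file.exists(path)) cfArgError("model config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  registry <- cfg$registry
  if (is.null(registry))
    cfStop("cyclefit_parse_error", "model config needs a 'registry' key")
  model <- switch(registry,
    goodwin = if (is.null(cfg$hill)) goodwinFixture() else goodwinFixture(cfg$hill),
    damped = if (is.null(cfg$hill)) dampedFixture() else dampedFixture(cfg$hill),
    cfStop("cyclefit_parse_error", "unknown model registry key '%s'", registry))
  if (!is.null(cfg$params)) {
    p <- unlist(cfg$params)
    unknown <- setdiff(names(p), model$param_names)
    if (length(unknown))
      cfStop("cyclefit_parse_error", "unknown parameter(s): %s",
             paste(unknown, collapse = ", "))
    model$nominal_params[names(p)] <- as.numeric(p)
    if (any(model$nominal_params <= 0))
      cfStop("cyclefit_parse_error", "parameters must be positive")
  }
  if (!is.null(cfg$period_hint)) model$period_hint <- as.numeric(cfg$period_hint)
  if (!is.null(cfg$name)) model$name <- cfg$name
  model
}
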