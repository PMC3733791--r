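#' Periodic time-series dataset
#'
#' Measurements of every state of an oscillator over (nominally) one
#' period: times t_j, per-state means and per-point standard deviations.
#' The standard deviations double as the weights of the least-squares fit,
#' so they must be strictly positive wherever a mean is present. Individual
#' missing points are allowed as `NA` (their terms are dropped from the
#' cost); a fully missing state row is rejected by [buildInitialGuess()].
#'
#' @param times strictly increasing numeric vector of M sampling times.
#' @param means NEQ x M numeric matrix of measured means (rows = states).
#' @param stds NEQ x M numeric matrix of standard deviations, > 0 where the
#'   mean is non-missing; may be omitted for noise-free "truth" tables
#'   (filled with NA until a noise model sets them).
#' @param state_names optional character vector of row names.
#' @return an object of class `time_series_dataset` with fields `times`,
#'   `means`, `stds`, `M`, `state_names`.
#' @export
timeSeriesDataset <- function(times, means, stds = NULL, state_names = NULL) {
  times <- as.numeric(times)
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  means <- as.matrix(means)
  if (any(diff(times) <= 0)) cfArgError("times must be strictly increasing")
  if (ncol(means) != length(times))
    cfArgError("means must have one column per sampling time")
  if (any(!is.finite(means) & !is.na(means)))
    cfArgError("means must be finite or NA")
  if (is.null(stds)) {
    stds <- matrix(NA_real_, nrow(means), ncol(means))
  } else {
    if (is.null(dim(stds))) stds <- matrix(stds, nrow = 1)
    stds <- as.matrix(stds)
    if (!all(dim(stds) == dim(means)))
      cfArgError("stds must have the same shape as means")
    bad <- !is.na(means) & (is.na(stds) | stds <= 0)
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      cfArgError("stds must be > 0 wherever a mean is present (state %d, time index %d)",
                 idx[1], idx[2])
    }
  }
  if (is.null(state_names)) {
    state_names <- rownames(means)
    if (is.null(state_names))
      state_names <- paste0("x", seq_len(nrow(means)))
  }
  rownames(means) <- rownames(stds) <- state_names
  structure(list(times = times, means = means, stds = stds,
                 M = length(times), state_names = state_names),
            class = "time_series_dataset")
}

#' @export
print.time_series_dataset <- function(x, ...) {
  cat(sprintf("<time_series_dataset>: %d states x M=%d points on [%.4g, %.4g]\n",
              nrow(x$means), x$M, min(x$times), max(x$times)))
  invisible(x)
}

#' Weighted least-squares cost of a prediction against a dataset
#'
#' Computes the chi-square-style objective
#' \deqn{\sum_i \sum_j \frac{(\hat x_i(t_j) - x_i(t_j))^2}{\sigma_{ij}^2}}
#' over all non-missing measurements.
#'
#' @param dataset a [timeSeriesDataset()] with positive `stds`.
#' @param predicted NEQ x M matrix of model values at the dataset times, or
#'   a function `t -> NEQ-vector` (or NEQ x length(t) matrix) evaluated at
#'   the dataset times.
#' @return non-negative scalar.
#' @export
datasetCost <- function(dataset, predicted) {
  stopifnot(inherits(dataset, "time_series_dataset"))
  if (is.function(predicted)) {
    predicted <- vapply(dataset$times, function(t) as.numeric(predicted(t)),
                        numeric(nrow(dataset$means)))
  }
  if (is.null(dim(predicted))) predicted <- matrix(predicted, nrow = 1)
  predicted <- as.matrix(predicted)
  if (!all(dim(predicted) == dim(dataset$means)))
    cfArgError("prediction must be available at every sampling time for every state")
  use <- !is.na(dataset$means)
  if (any(is.na(dataset$stds[use]) | dataset$stds[use] <= 0))
    cfArgError("dataset stds must be > 0 to act as weights")
  r <- (dataset$means[use] - predicted[use]) / dataset$stds[use]
  sum(r^2)
}

#' Read a dataset from CSV
#'
#' Expects a `time` column followed by `<state>_mean` / `<state>_std`
#' column pairs, one row per sampling time.
#'
#' @param path CSV file path.
#' @return a [timeSeriesDataset()].
#' @export
readDataset <- function(path) {
  if (!file.exists(path)) cfArgError("dataset file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df))
    cfStop("cyclefit_parse_error", "dataset CSV must have a 'time' column")
  mean_cols <- grep("_mean$", names(df), value = TRUE)
  if (length(mean_cols) == 0)
    cfStop("cyclefit_parse_error", "no '<state>_mean' columns found")
  states <- sub("_mean$", "", mean_cols)
  std_cols <- paste0(states, "_std")
  missing_std <- std_cols[!std_cols %in% names(df)]
  if (length(missing_std))
    cfStop("cyclefit_parse_error", "missing std column(s): %s",
           paste(missing_std, collapse = ", "))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "NA" & df[[col]] != "")
    if (length(bad))
      cfStop("cyclefit_parse_error", "non-numeric cell in column '%s', row %d",
             col, bad[1])
    v
  }
  times <- num("time")
  means <- t(vapply(mean_cols, num, numeric(nrow(df))))
  stds <- t(vapply(std_cols, num, numeric(nrow(df))))
  bad <- which(!is.na(means) & (is.na(stds) | stds <= 0), arr.ind = TRUE)
  if (nrow(bad))
    cfStop("cyclefit_parse_error",
           "non-positive standard deviation in column '%s', row %d",
           std_cols[bad[1, 1]], bad[1, 2])
  timeSeriesDataset(times, means, stds, state_names = states)
}

#' Write a dataset to CSV
#'
#' Inverse of [readDataset()]; numbers are written with full double
#' precision so a read-back reproduces the dataset exactly.
#'
#' @param dataset a [timeSeriesDataset()].
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeDataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "time_series_dataset"))
  df <- data.frame(time = dataset$times, check.names = FALSE)
  for (i in seq_along(dataset$state_names)) {
    s <- dataset$state_names[i]
    df[[paste0(s, "_mean")]] <- dataset$means[i, ]
    df[[paste0(s, "_std")]] <- dataset$stds[i, ]
  }
  old <- options(digits = 17); on.exit(options(old))
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
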