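#' Plot a bootstrap percentile band for one state
#'
#' Shades the region between the lower and upper pointwise percentiles of
#' the ensemble's limit-cycle trajectories (on normalized phase), with the
#' pointwise median drawn on top. Returns a ggplot object; numerical
#' output from [percentileBand()] is the authoritative result, the figure
#' is a convenience.
#'
#' @param ensemble a [runBootstrap()] ensemble.
#' @param state state name or index.
#' @param lo,hi band percentiles (default 5/95).
#' @return a ggplot object.
#' @export
plotBand <- function(ensemble, state, lo = 5, hi = 95) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    cfArgError("ggplot2 is required for plotting")
  b <- percentileBand(ensemble, state, lo = lo, hi = hi)
  df <- data.frame(phase = b$phase, lower = b$lower, upper = b$upper,
                   median = b$median)
  ggplot2::ggplot(df, ggplot2::aes(x = phase)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                         alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = median)) +
    ggplot2::labs(x = "phase (fraction of period)",
                  y = if (is.character(state)) state
                      else ensemble$state_names[state],
                  title = sprintf("%g-%g%% bootstrap band", lo, hi)) +
    ggplot2::theme_minimal()
}

#' Plot bootstrap parameter or sensitivity distributions
#'
#' One violin per parameter summarizing the bootstrap distribution of the
#' estimates (`what = "params"`) or of the relative period sensitivities
#' (`what = "sens"`); sensitivities flagged non-identifiable at the given
#' level are shown in red.
#'
#' @param ensemble a [runBootstrap()] ensemble.
#' @param what `"params"` or `"sens"`.
#' @param level identifiability level used for coloring (default 0.95).
#' @return a ggplot object.
#' @export
plotDistributions <- function(ensemble, what = c("sens", "params"),
                              level = 0.95) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    cfArgError("ggplot2 is required for plotting")
  what <- match.arg(what)
  M <- ensembleMatrix(ensemble, if (what == "sens") "sens" else "params")
  idrep <- classifyIdentifiability(ensemble, level = level)
  df <- data.frame(
    name = factor(rep(ensemble$param_names, each = nrow(M)),
                  levels = ensemble$param_names),
    value = as.numeric(M),
    identifiable = rep(idrep$table$identifiable, each = nrow(M)))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = name, y = value))
  if (what == "sens") {
    gg <- gg +
      ggplot2::geom_violin(ggplot2::aes(fill = identifiable), scale = "width") +
      ggplot2::scale_fill_manual(values = c(`TRUE` = "grey65", `FALSE` = "red3")) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::labs(y = "relative period sensitivity dlnT/dlnp")
  } else {
    gg <- gg + ggplot2::geom_violin(fill = "grey65", scale = "width") +
      ggplot2::labs(y = "estimated parameter value")
  }
  gg + ggplot2::labs(x = NULL) + ggplot2::theme_minimal()
}
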