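# ggplot2 visualizations mirroring the standard figure layouts.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_errorbar geom_tile geom_abline facet_grid facet_wrap labs
#'   scale_fill_gradient2 theme_minimal
#' @export
ggplot2::autoplot

#' Plot a unisensory summary (bias and SD curves)
#'
#' @param object A `unisensory_summary`.
#' @param ... Unused.
#' @return A ggplot object with bias and SD panels over stimulus bin centers.
#' @export
autoplot.unisensory_summary <- function(object, ...) {
  dat <- dplyr::bind_rows(
    dplyr::mutate(object$bias, statistic = "bias"),
    dplyr::mutate(object$sd, statistic = "response SD")
  )
  ggplot(dat, aes(x = .data$bin_center, y = .data$mean,
    color = .data$source, group = .data$source)) +
    geom_line() +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
      ymax = .data$mean + .data$sem), width = 0.8) +
    facet_wrap(~ .data$statistic, scales = "free_y") +
    labs(x = "stimulus location (deg)", y = "mean ± SEM",
      title = unique(dat$task)) +
    theme_minimal()
}

#' Plot a "same"-rate or bias-versus-disparity summary
#'
#' Works for the outputs of [bc_summary()] (same-rate curves, stratified by
#' reliability and eccentricity) and [bisensory_localization_summary()] (bias
#' curves, stratified by reliability and side).
#'
#' @param summary_tbl Output tibble of [bc_summary()] or
#'   [bisensory_localization_summary()].
#' @return A ggplot object.
#' @export
plot_bisensory_summary <- function(summary_tbl) {
  strat <- if ("eccentricity" %in% names(summary_tbl)) "eccentricity" else "side"
  ylab <- if ("eccentricity" %in% names(summary_tbl)) {
    "fraction 'same' responses"
  } else {
    "mean estimation bias (deg)"
  }
  ggplot(summary_tbl, aes(x = .data$disparity_center, y = .data$mean,
    color = .data$source, group = .data$source)) +
    geom_line() +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
      ymax = .data$mean + .data$sem), width = 0.8) +
    facet_grid(stats::reformulate(strat, "reliability")) +
    labs(x = "stimulus disparity s_A - s_V (deg)", y = ylab) +
    theme_minimal()
}

#' Heatmap of a model-recovery matrix
#'
#' Rows are generating models, columns fitted models; cell color shows the
#' group-summed difference of the chosen metric to the generating (diagonal)
#' model. All-positive off-diagonal cells indicate successful recovery.
#'
#' @param object A `recovery_matrix`.
#' @param metric `"bic"`, `"aic"` or `"nll"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_matrix <- function(object, metric = "bic", ...) {
  col <- paste0("delta_", match.arg(metric, c("bic", "aic", "nll")))
  ggplot(object, aes(x = .data$fitted, y = .data$generator,
    fill = sign(.data[[col]]) * log10(1 + abs(.data[[col]])))) +
    geom_tile() +
    scale_fill_gradient2(low = "#c51b7d", mid = "white", high = "#4d9221",
      name = sprintf("sign × log10(1+|Δ%s|)", toupper(metric))) +
    labs(x = "fitted model", y = "generating model") +
    theme_minimal()
}

#' Unity plots of parameter recovery
#'
#' True generative parameter values against recovered values, one panel per
#' parameter, with the identity line marking perfect recovery.
#'
#' @param object A `recovery_scatter`.
#' @param terms Optional subset of parameter names.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_scatter <- function(object, terms = NULL, ...) {
  dat <- object$pairs
  if (!is.null(terms)) dat <- dat[dat$term %in% terms, , drop = FALSE]
  ggplot(dat, aes(x = .data$true, y = .data$recovered)) +
    geom_abline(slope = 1, intercept = 0, color = "#4d9221") +
    geom_point() +
    facet_wrap(~ .data$term, scales = "free") +
    labs(x = "ground-truth parameter value", y = "recovered parameter value") +
    theme_minimal()
}
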