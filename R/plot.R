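# Forest-plot rendering of pooled MR results.

#' Forest plot of pooled MR estimates
#'
#' Odds ratio of the outcome per 1 SD of each exposure with its 95% CI, on a
#' log-scaled axis with the null (OR = 1) marked.
#'
#' @param object An `mr_analysis` object.
#' @param method Which pooled method to plot (default `"ivw_fixed"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_analysis <- function(object, method = "ivw_fixed", ...) {
  dat <- object$results[object$results$method == method, ]
  if (nrow(dat) == 0) abort(paste0("no results for method ", method))
  dat$exposure <- factor(dat$exposure, levels = rev(unique(dat$exposure)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$or, y = .data$exposure)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Odds ratio per 1 SD of exposure (95% CI)", y = NULL,
      title = paste0("Mendelian randomization estimates (", method, ")")
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mr_analysis
#' @param x An `mr_analysis` object.
#' @export
plot_mr_forest <- function(x, method = "ivw_fixed", ...) {
  autoplot(x, method = method, ...)
}
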