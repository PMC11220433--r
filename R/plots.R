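#' Plot helpers for corpus series, rankings and signal estimates
#'
#' Thin ggplot2 layers over the package's tabular results, returned as
#' ggplot objects for further styling.
#'
#' @param series Monthly-series tibble from [monthly_series()].
#' @param breakpoints Optional breakpoint tibble from [detect_breakpoints()]
#'   drawn as dashed vertical lines.
#' @return A ggplot object.
#' @export
plot_monthly_series <- function(series, breakpoints = NULL) {
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$month, y = .data$n)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = NULL, y = "events per month") +
    ggplot2::theme_minimal()
  if (!is.null(breakpoints) && nrow(breakpoints) && "month" %in% names(breakpoints)) {
    p <- p + ggplot2::geom_vline(
      data = breakpoints,
      ggplot2::aes(xintercept = .data$month),
      linetype = "dashed", colour = "firebrick"
    )
  }
  p
}

#' @param estimates Cumulative estimate series from
#'   [cumulative_prr_series()]; not-computable months are dropped from the
#'   ribbon.
#' @rdname plot_monthly_series
#' @export
plot_signal_series <- function(estimates) {
  est <- estimates[estimates$computable, ]
  ggplot2::ggplot(est, ggplot2::aes(x = .data$month, y = .data$log_point)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$log_ci_low,
                                      ymax = .data$log_ci_high),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = paste0("log ", estimates$measure[1], " (95% CI)")) +
    ggplot2::theme_minimal()
}

#' @param ranking Ranked distribution from [rank_by()].
#' @param top_n Bars to show (default 20).
#' @rdname plot_monthly_series
#' @export
plot_ranked <- function(ranking, top_n = 20) {
  d <- utils::head(ranking, top_n)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n,
                                  y = stats::reorder(.data$label, .data$n))) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "annotations", y = NULL) +
    ggplot2::theme_minimal()
}

#' @param object A `cusum_path` or `ciss_lasso` object.
#' @param ... Unused.
#' @rdname plot_monthly_series
#' @export
autoplot.cusum_path <- function(object, ...) {
  d <- tibble(i = seq_along(object$S) - 1L, S = object$S)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$i, y = .data$S)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$argmax, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "month index", y = "cumulative deviation S") +
    ggplot2::theme_minimal()
}

#' @rdname plot_monthly_series
#' @export
autoplot.ciss_lasso <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$selection_freq,
                                  y = stats::reorder(.data$atc_code, .data$selection_freq),
                                  fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60")) +
    ggplot2::labs(x = paste0("selection frequency over B = ", object$config$B, " draws"),
                  y = NULL, fill = paste0("retained (q = ", object$config$q, ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
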