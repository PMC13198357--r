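# ggplot2 displays for the result objects.

#' Plot an ROC curve
#'
#' @param object An `svt_roc` from [roc_analysis()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot svt_roc
#' @export
autoplot.svt_roc <- function(object, ...) {
  pts <- object$points
  best <- pts[which.min(abs(pts$threshold - object$youden_cutoff)), ]
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_point(data = best, colour = "red", size = 2) +
    ggplot2::annotate("text", x = 0.65, y = 0.1,
                      label = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("Youden cutoff ≤ %.0f ms",
                                  object$youden_cutoff)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Dot plot of an index by mechanism
#'
#' Per-case values with the arm medians marked, in the style used to
#' display postpacing-difference indices across SVT mechanisms.
#'
#' @param cohort A cohort tibble (see [generate_cohort()]).
#' @param index Index column name, e.g. `"ippi_tcl"`.
#' @param cutoff Optional horizontal reference cutoff (ms).
#' @return A ggplot.
#' @export
plot_index_dotplot <- function(cohort, index = "ippi_tcl", cutoff = NULL) {
  stopifnot(index %in% names(cohort))
  df <- cohort[is.finite(cohort[[index]]), , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mechanism,
                                        y = .data[[index]])) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1.2) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, linewidth = 0.4, colour = "red") +
    ggplot2::labs(x = NULL, y = paste(index, "(ms)")) +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dotted")
  }
  p
}

#' Plot an annotated electrogram event series as a ladder diagram
#'
#' @param object An `egm_series`.
#' @param t0,t1 Optional window (ms).
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot egm_series
#' @export
autoplot.egm_series <- function(object, t0 = -Inf, t1 = Inf, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$time_ms >= t0 & df$time_ms < t1, , drop = FALSE]
  df$channel <- factor(df$channel, levels = rev(EGM_CHANNELS))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$channel,
                                   shape = .data$kind, colour = .data$kind)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}
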