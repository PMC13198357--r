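# broom-style tidiers for the fitted/result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ROC result
#'
#' @param x An `svt_roc`.
#' @param ... Ignored.
#' @return The per-threshold operating points as a tibble.
#' @method tidy svt_roc
#' @export
tidy.svt_roc <- function(x, ...) x$points

#' One-row summary of an ROC result
#'
#' @param x An `svt_roc`.
#' @param ... Ignored.
#' @return A one-row tibble with the AUC and the Youden operating point.
#' @method glance svt_roc
#' @export
glance.svt_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, youden_cutoff = x$youden_cutoff,
                 youden_sens = x$youden_sens, youden_spec = x$youden_spec,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy a cohort evaluation
#'
#' @param x An `svt_evaluation`.
#' @param ... Ignored.
#' @return The per-cutoff diagnostic metrics as a tibble.
#' @method tidy svt_evaluation
#' @export
tidy.svt_evaluation <- function(x, ...) {
  dplyr::mutate(x$cutoff_metrics, index = x$index, .before = 1)
}

#' One-row summary of a cohort evaluation
#'
#' @param x An `svt_evaluation`.
#' @param ... Ignored.
#' @return A one-row tibble with the AUC, Youden cutoff and the group
#'   comparison p-value.
#' @method glance svt_evaluation
#' @export
glance.svt_evaluation <- function(x, ...) {
  dplyr::mutate(glance.svt_roc(x$roc), index = x$index,
                p_value = x$comparison$p_value, .before = 1)
}

#' Tidy a diagnostic adjudication
#'
#' @param x An `svt_diagnosis`.
#' @param ... Ignored.
#' @return One row per fired criterion (zero rows if none fired).
#' @method tidy svt_diagnosis
#' @export
tidy.svt_diagnosis <- function(x, ...) {
  tibble::tibble(diagnosis = rep(x$diagnosis, length(x$fired)),
                 criterion = x$fired)
}
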