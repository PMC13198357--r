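# Statistical evaluation stage: nonparametric group comparisons, rank
# correlation, ROC analysis with Youden cutoffs, and 2x2 diagnostic
# metrics.

#' Nonparametric comparison of index values between groups
#'
#' Two groups are compared with the two-sided Mann-Whitney U test (exact
#' enumeration for small untied samples, normal approximation with tie
#' correction otherwise); three or more groups with the Kruskal-Wallis
#' test.
#'
#' @param data A data frame, or a list of numeric vectors (one per group).
#' @param value,group When `data` is a data frame: the value column and the
#'   grouping column (tidy evaluation).
#' @return A one-row tibble with `method`, `statistic`, `p_value` and
#'   `n_groups`.
#' @examples
#' compare_groups(list(c(1, 2, 3), c(10, 11, 12)))
#' @export
compare_groups <- function(data, value, group) {
  groups <- if (is.data.frame(data)) {
    v <- rlang::eval_tidy(rlang::enquo(value), data)
    g <- rlang::eval_tidy(rlang::enquo(group), data)
    keep <- is.finite(v) & !is.na(g)
    split(v[keep], g[keep], drop = TRUE)
  } else if (is.list(data)) {
    data
  } else {
    stop("data must be a data frame or a list of numeric vectors", call. = FALSE)
  }
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    stop("need at least two non-empty groups", call. = FALSE)
  }
  if (length(groups) == 2) {
    x <- groups[[1]]; y <- groups[[2]]
    exact <- max(length(x), length(y)) <= 20 &&
      !anyDuplicated(c(x, y))
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = !exact))
    tibble::tibble(method = "Mann-Whitney U", statistic = unname(ht$statistic),
                   p_value = ht$p.value, n_groups = 2L)
  } else {
    ht <- stats::kruskal.test(groups)
    tibble::tibble(method = "Kruskal-Wallis", statistic = unname(ht$statistic),
                   p_value = ht$p.value, n_groups = length(groups))
  }
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties.
#'
#' @param x,y Numeric vectors of equal length (at least 3); pairs with a
#'   missing value are dropped.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  stats::cor(x[keep], y[keep], method = "spearman")
}

#' ROC analysis with a low-score-positive rule
#'
#' Sweeps every distinct score as an inclusive threshold (`score <= t` is
#' called positive, matching the clinical "<= cutoff" convention for
#' postpacing indices), computes the ROC curve and the trapezoidal AUC, and
#' selects the cutoff maximizing the Youden index `sens + spec - 1`, with
#' ties broken toward the smaller threshold.
#'
#' @param labels Logical vector (or coercible via `positive`): `TRUE` for
#'   the positive class.
#' @param scores Numeric scores (ms); lower scores indicate the positive
#'   class.
#' @param positive When `labels` is not logical, the level counted as
#'   positive.
#' @return A list of class `svt_roc`: `points` (tibble of threshold,
#'   sensitivity, specificity, fpr, tpr), `auc`, `youden_cutoff`,
#'   `youden_sens`, `youden_spec`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(labels, scores, positive = NULL) {
  if (!is.logical(labels)) {
    if (is.null(positive)) stop("supply `positive` for non-logical labels",
                                call. = FALSE)
    labels <- labels == positive
  }
  keep <- is.finite(scores) & !is.na(labels)
  labels <- labels[keep]; scores <- scores[keep]
  if (length(labels) != length(scores) || length(labels) == 0) {
    stop("labels and scores must be non-empty and of equal length", call. = FALSE)
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present", call. = FALSE)

  th <- sort(unique(scores))
  sens <- vapply(th, function(t) sum(labels & scores <= t) / n_pos, numeric(1))
  fpr <- vapply(th, function(t) sum(!labels & scores <= t) / n_neg, numeric(1))
  points <- tibble::tibble(threshold = c(-Inf, th),
                           sensitivity = c(0, sens),
                           specificity = c(1, 1 - fpr),
                           fpr = c(0, fpr), tpr = c(0, sens))
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                   utils::tail(points$tpr, -1)) / 2)
  j <- sens + (1 - fpr) - 1
  best <- which(j == max(j))[1]  # ties toward the smaller threshold
  structure(list(points = points, auc = auc,
                 youden_cutoff = th[best], youden_sens = sens[best],
                 youden_spec = 1 - fpr[best],
                 n_pos = n_pos, n_neg = n_neg),
            class = "svt_roc")
}

#' @export
print.svt_roc <- function(x, ...) {
  cat(sprintf("<svt_roc: AUC %.3f (%d pos / %d neg)>\n", x$auc, x$n_pos, x$n_neg))
  cat(sprintf("Youden cutoff <= %.1f ms: sensitivity %.1f%%, specificity %.1f%%\n",
              x$youden_cutoff, 100 * x$youden_sens, 100 * x$youden_spec))
  invisible(x)
}

#' Diagnostic metrics from a 2x2 confusion matrix
#'
#' @param tp,fn,fp,tn Non-negative counts; `tp + fn > 0` and `tn + fp > 0`.
#' @return A one-row tibble with `sens`, `spec`, `ppv`, `npv` as
#'   proportions (`ppv` is `NA` when no case tests positive).
#' @examples
#' diagnostic_metrics(37, 4, 0, 41)
#' @export
diagnostic_metrics <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (tp + fn == 0 || tn + fp == 0) {
    stop("both classes must be represented (tp+fn > 0 and tn+fp > 0)",
         call. = FALSE)
  }
  tibble::tibble(
    sens = tp / (tp + fn),
    spec = tn / (tn + fp),
    ppv = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    npv = if (tn + fn == 0) NA_real_ else tn / (tn + fn)
  )
}

#' Evaluate the diagnostic performance of an index on a cohort
#'
#' Restricts the cohort to the positive and negative mechanism arms,
#' compares the index between them, runs [roc_analysis()] (low values call
#' the positive mechanism) and tabulates sensitivity/specificity/PPV/NPV at
#' the requested inclusive cutoffs.
#'
#' @param cohort A cohort tibble (see [generate_cohort()]).
#' @param index Name of the index column (e.g. `"c_ippi_tcl"`).
#' @param positive,negative Mechanism labels for the two arms.
#' @param cutoffs Inclusive cutoffs (ms) at which to report 2x2 metrics.
#' @return A list of class `svt_evaluation`: `index`, `roc`, `comparison`,
#'   `cutoff_metrics` (tibble with one row per cutoff).
#' @export
evaluate_cohort <- function(cohort, index, positive = "ORT",
                            negative = "AVNRT", cutoffs = c(110, 125)) {
  stopifnot(is.data.frame(cohort), index %in% names(cohort))
  sub <- cohort[cohort$mechanism %in% c(positive, negative), , drop = FALSE]
  scores <- sub[[index]]
  labels <- sub$mechanism == positive
  roc <- roc_analysis(labels, scores)
  cmp <- compare_groups(list(scores[labels & is.finite(scores)],
                             scores[!labels & is.finite(scores)]))
  cut_tab <- dplyr::bind_rows(lapply(cutoffs, function(ct) {
    pos_call <- scores <= ct
    dplyr::mutate(diagnostic_metrics(
      tp = sum(labels & pos_call, na.rm = TRUE),
      fn = sum(labels & !pos_call, na.rm = TRUE),
      fp = sum(!labels & pos_call, na.rm = TRUE),
      tn = sum(!labels & !pos_call, na.rm = TRUE)
    ), cutoff = ct, .before = 1)
  }))
  structure(list(index = index, positive = positive, negative = negative,
                 roc = roc, comparison = cmp, cutoff_metrics = cut_tab),
            class = "svt_evaluation")
}

#' @export
print.svt_evaluation <- function(x, ...) {
  cat(sprintf("<svt_evaluation: %s, %s vs %s>\n", x$index, x$positive, x$negative))
  print(x$roc)
  cat(sprintf("Mann-Whitney p = %.3g\n", x$comparison$p_value))
  print(as.data.frame(x$cutoff_metrics), row.names = FALSE, digits = 3)
  invisible(x)
}
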