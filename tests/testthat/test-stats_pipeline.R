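# brute-force oracle: AUC as the pairwise concordance probability that a
# positive case scores lower than a negative one (ties count half)
auc_oracle <- function(labels, scores) {
  pos <- scores[labels]; neg <- scores[!labels]
  num <- 0
  for (p in pos) for (q in neg) {
    num <- num + (p < q) + 0.5 * (p == q)
  }
  num / (length(pos) * length(neg))
}

test_that("group comparisons use the exact and approximate U test correctly", {
  out <- compare_groups(list(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(out$method, "Mann-Whitney U")
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 0.1)  # exact two-sided 2/20

  same <- compare_groups(list(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(same$p_value, 1)

  kw <- compare_groups(list(rnorm(10), rnorm(10), rnorm(10)))
  expect_equal(kw$method, "Kruskal-Wallis")
  expect_equal(kw$n_groups, 3L)

  expect_error(compare_groups(list(1:3)), "two non-empty")
  expect_error(compare_groups(list(1:3, numeric(0))), "two non-empty")

  # data-frame interface
  df <- data.frame(v = c(1, 2, 3, 10, 11, 12),
                   g = rep(c("a", "b"), each = 3))
  expect_equal(compare_groups(df, v, g)$p_value, 0.1)
})

test_that("default synthetic arms separate as strongly as the clinical cohort", {
  pvals <- vapply(1:10, function(seed) {
    tab <- generate_cohort(cohort_config(seed = seed))
    compare_groups(tab[tab$mechanism != "AT", ], ippi_tcl, mechanism)$p_value
  }, numeric(1))
  expect_true(all(pvals < 0.001))
})

test_that("Spearman correlation handles monotone and tied inputs", {
  x <- c(1, 5, 9, 12)
  expect_equal(spearman_rho(x, 2 * x + 3), 1)
  expect_equal(spearman_rho(x, -x^3), -1)
  expect_error(spearman_rho(1:4, 1:5), "equal length")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("ROC analysis equals the concordance oracle on exhaustive inputs", {
  score_sets <- list(1:8, c(1, 1, 2, 2, 3, 3, 4, 4), c(5, 2, 2, 7, 7, 7, 1, 9))
  for (scores in score_sets) {
    for (n in c(4, 6, 8)) {
      s <- scores[1:n]
      for (mask in 1:(2^n - 2)) {
        labels <- as.logical(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1))
        roc <- roc_analysis(labels, s)
        expect_equal(roc$auc, auc_oracle(labels, s), tolerance = 1e-12)
      }
    }
  }
})

test_that("ROC endpoints, null behaviour and invariances hold", {
  roc <- roc_analysis(c(TRUE, TRUE, FALSE, FALSE), c(1, 2, 10, 11))
  expect_equal(roc$auc, 1)
  expect_equal(roc$youden_sens, 1)
  expect_equal(roc$youden_spec, 1)
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(tail(roc$points$tpr, 1), 1)
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))

  set.seed(1)
  labels <- rep(c(TRUE, FALSE), 500)
  scores <- rnorm(1000)
  expect_equal(roc_analysis(labels, scores)$auc, 0.5, tolerance = 0.1)

  # invariance under strictly monotone transformation of the scores
  l <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  s <- c(3, 9, 4, 8, 5, 7)
  r1 <- roc_analysis(l, s)
  r2 <- roc_analysis(l, exp(s / 3))
  expect_equal(r1$points$tpr, r2$points$tpr)
  expect_equal(r1$points$fpr, r2$points$fpr)
  expect_equal(r1$auc, r2$auc)

  expect_error(roc_analysis(c(TRUE, TRUE), c(1, 2)), "both classes")
})

test_that("the Youden cutoff matches exhaustive search and ties break low", {
  l <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  s <- c(1, 2, 3, 4, 5, 6)
  roc <- roc_analysis(l, s)
  # exhaustive search over all thresholds
  cand <- sort(unique(s))
  j <- vapply(cand, function(t) {
    mean(s[l] <= t) + mean(s[!l] > t) - 1
  }, numeric(1))
  expect_equal(roc$youden_cutoff, cand[which.max(j)])
  # tie: perfect separation at both 3 and 3.5-equivalents; smaller wins
  l2 <- c(TRUE, TRUE, FALSE)
  s2 <- c(1, 2, 10)
  expect_equal(roc_analysis(l2, s2)$youden_cutoff, 2)
})

test_that("ROC agrees with an independent implementation on cohort data", {
  skip_if_not_installed("pROC")
  tab <- generate_cohort(cohort_config(seed = 7))
  sub <- tab[tab$mechanism != "AT", ]
  ours <- roc_analysis(sub$mechanism == "ORT", sub$c_ippi_tcl)
  ref <- pROC::roc(response = sub$mechanism, predictor = sub$c_ippi_tcl,
                   levels = c("AVNRT", "ORT"), direction = ">", quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
})

test_that("diagnostic metrics and prevalence identities are exact", {
  m <- diagnostic_metrics(37, 4, 0, 41)
  expect_equal(round(100 * m$sens, 1), 90.2)
  expect_equal(100 * m$spec, 100)
  expect_equal(100 * m$ppv, 100)
  expect_equal(round(100 * m$npv, 1), 91.1)

  all100 <- diagnostic_metrics(10, 0, 0, 10)
  expect_true(all(all100 == 1))
  zero <- diagnostic_metrics(0, 10, 0, 10)
  expect_equal(zero$sens, 0)
  expect_equal(zero$npv, 0.5)
  expect_true(is.na(zero$ppv))

  # ppv/npv recomputed from (sens, spec, prevalence) match the counts
  tp <- 30; fn <- 12; fp <- 7; tn <- 25
  m2 <- diagnostic_metrics(tp, fn, fp, tn)
  prev <- (tp + fn) / (tp + fn + fp + tn)
  ppv_id <- m2$sens * prev / (m2$sens * prev + (1 - m2$spec) * (1 - prev))
  npv_id <- m2$spec * (1 - prev) / ((1 - m2$sens) * prev + m2$spec * (1 - prev))
  expect_equal(m2$ppv, ppv_id)
  expect_equal(m2$npv, npv_id)

  expect_error(diagnostic_metrics(-1, 2, 3, 4), "non-negative")
  expect_error(diagnostic_metrics(0, 0, 1, 2), "both classes")
})

test_that("cohort evaluation bundles ROC, comparison and cutoff metrics", {
  tab <- generate_cohort(cohort_config(seed = 2))
  ev <- evaluate_cohort(tab, "c_ippi_tcl", cutoffs = c(110, 125))
  expect_s3_class(ev, "svt_evaluation")
  expect_equal(nrow(ev$cutoff_metrics), 2)
  expect_gt(ev$roc$auc, 0.85)
  g <- glance(ev)
  expect_equal(g$auc, ev$roc$auc)
  td <- tidy(ev)
  expect_equal(td$cutoff, c(110, 125))
})
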