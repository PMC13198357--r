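report_row <- function(...) {
  defaults <- list(tcl = NA_real_, ippi = NA_real_, ippi_tcl = NA_real_,
                   ah_induction = NA_real_, ah_tachycardia = NA_real_,
                   c_ippi_tcl = NA_real_, ppi = NA_real_, ppi_tcl = NA_real_,
                   ah_post_vop = NA_real_, c_ppi_tcl = NA_real_,
                   sa_va = NA_real_, delta_va = NA_real_,
                   iva_sequence = NA_character_,
                   post_vop_sequence = NA_character_, eaas = NA_character_)
  args <- list(...)
  defaults[names(args)] <- args
  tibble::as_tibble(defaults)
}

test_that("conventional adjudication applies criteria in order with vetoes", {
  th <- svt_thresholds()

  # a positive delta-VA after differential atrial overdrive diagnoses AT
  at <- classify_conventional(diagnostic_evidence(report_row(), delta_va = 30), th)
  expect_equal(at$diagnosis, "AT")
  expect_true("AT_DELTA_VA" %in% at$fired)

  # short corrected PPI-TCL with a V-A-V response diagnoses ORT
  ort <- classify_conventional(
    diagnostic_evidence(report_row(c_ppi_tcl = 52, post_vop_sequence = "V_A_V")),
    th)
  expect_equal(ort$diagnosis, "ORT")
  expect_true("ORT_C_PPI_TCL" %in% ort$fired)

  # V-A-V with long indices and no ORT criterion: AVNRT by double exclusion
  av <- classify_conventional(
    diagnostic_evidence(report_row(post_vop_sequence = "V_A_V", ppi_tcl = 165,
                                   c_ppi_tcl = 150, sa_va = 144)), th)
  expect_equal(av$diagnosis, "AVNRT")

  # the V-A-V veto beats an AT inclusion
  veto <- classify_conventional(
    diagnostic_evidence(report_row(post_vop_sequence = "V_A_V"), delta_va = 30),
    th)
  expect_false(veto$diagnosis == "AT")

  # an ORT exclusion vetoes ORT inclusions
  ortx <- classify_conventional(
    diagnostic_evidence(report_row(c_ppi_tcl = 52, post_vop_sequence = "V_A_V"),
                        av_block_during_svt = TRUE), th)
  expect_equal(ortx$diagnosis, "AVNRT")

  # no usable evidence degrades to INDETERMINATE, never a guess
  expect_equal(classify_conventional(diagnostic_evidence(report_row()), th)$diagnosis,
               "INDETERMINATE")
})

test_that("threshold comparisons match the printed cutoff semantics", {
  th <- svt_thresholds()
  at_cut <- function(x) classify_conventional(
    diagnostic_evidence(report_row(c_ppi_tcl = x, post_vop_sequence = "V_A_V")),
    th)$diagnosis
  expect_equal(at_cut(110), "ORT")       # inclusive <=
  expect_equal(at_cut(110.5), "AVNRT")
  sa <- function(x) classify_conventional(
    diagnostic_evidence(report_row(sa_va = x, post_vop_sequence = "V_A_V")),
    th)$diagnosis
  expect_equal(sa(84.9), "ORT")          # strict <
  expect_equal(sa(85), "AVNRT")
  dv <- function(x) classify_conventional(
    diagnostic_evidence(report_row(), delta_va = x), th)$diagnosis
  expect_equal(dv(20), "INDETERMINATE")  # strict >
  expect_equal(dv(20.5), "AT")
})

test_that("the fired-criteria audit is reproducible", {
  ev <- diagnostic_evidence(report_row(c_ppi_tcl = 90, ppi_tcl = 100,
                                       sa_va = 60, post_vop_sequence = "V_A_V"))
  f1 <- classify_conventional(ev)$fired
  f2 <- classify_conventional(ev)$fired
  expect_identical(f1, f2)
  expect_setequal(f1, c("AT_EXCL_VAV_RESPONSE", "ORT_PPI_TCL", "ORT_C_PPI_TCL",
                        "ORT_SA_VA"))
})

test_that("AVNRT subclassification uses limb delays with an EAAS tie-break", {
  expect_equal(subclassify_avnrt(250, 40), "SLOW_FAST")
  expect_equal(subclassify_avnrt(120, 90), "FAST_SLOW")
  expect_equal(subclassify_avnrt(250, 90), "SLOW_SLOW")
  # borderline HA: the earliest atrial activation site decides
  expect_equal(subclassify_avnrt(120, 75, eaas = "CS_PROX"), "FAST_SLOW")
  expect_equal(subclassify_avnrt(250, 75, eaas = "HIS"), "SLOW_FAST")
  expect_equal(subclassify_avnrt(250, 65, eaas = "CS_PROX"), "SLOW_SLOW")
  expect_error(subclassify_avnrt(120, 40), "not a reentrant")
})

test_that("the induction classifier maps sequence and corrected index to mechanism", {
  th <- svt_thresholds()
  expect_equal(classify_induction("V_A_A_V", 500, th), "AT")
  expect_equal(classify_induction("V_A_A_V", 50, th), "AT")
  expect_equal(classify_induction("V_A_V", 86, th), "ORT")
  expect_equal(classify_induction("V_A_V", 110, th), "ORT")
  expect_equal(classify_induction("V_A_V", 150, th), "AVNRT")
  expect_equal(classify_induction("INDETERMINATE", 50, th), "INDETERMINATE")
  # vectorized over a cohort
  out <- classify_induction(c("V_A_A_V", "V_A_V", "V_A_V"), c(NA, 90, 140), th)
  expect_equal(out, c("AT", "ORT", "AVNRT"))
})

test_that("conventional adjudication recovers every simulated mechanism", {
  cases <- mech_cases()
  entr <- cases[cases$entrained & !cases$terminated, ]
  expect_equal(mean(entr$conventional_dx == entr$mechanism), 1)
})
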