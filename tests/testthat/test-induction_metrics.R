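test_that("stable TCL is the median of a late 5-beat window", {
  s <- toy_tachycardia(rep(400, 19))
  expect_equal(measure_tcl(s), 400)

  # alternating intervals from beat 10: freeze the value of the stated rule
  # computed by an independent median
  vv <- rep(c(398, 402), 10)
  s2 <- toy_tachycardia(vv)
  expected <- median(vv[10:14])
  expect_equal(measure_tcl(s2), expected)

  # early instability is skipped (window starts at the 10th beat)
  s3 <- toy_tachycardia(c(470, 450, 430, 415, rep(400, 16)))
  expect_equal(measure_tcl(s3), 400)

  expect_error(measure_tcl(toy_tachycardia(rep(400, 5))),
               class = "svt_measurement_error")
  # no 5 consecutive intervals within 20 ms
  expect_error(measure_tcl(toy_tachycardia(rep(c(380, 430), 10))),
               class = "svt_measurement_error")
})

test_that("TCL of a simulated circuit matches its loop transit time", {
  m <- make_model("ORT_FREE_WALL", 8, decrement_free = TRUE)
  s <- run_induction_study(m)
  expect_equal(measure_tcl(s), m$tcl_nominal, tolerance = 1e-6)
})

test_that("iPPI spans last stimulus to first conducted apical V", {
  s <- toy_tachycardia(rep(400, 19), ippi = 622)
  expect_equal(measure_ippi(s), 622)
  expect_gt(measure_ippi(s), 0)
  no_v <- egm_series(data.frame(time_ms = c(0, 400), channel = "RVA",
                                kind = "STIM", origin = "PACED"))
  expect_error(measure_ippi(no_v), class = "svt_measurement_error")
})

test_that("AH correction subtracts the induction-phase AV-nodal excess", {
  expect_equal(corrected_ippi_tcl(123, 50, 50), 123)   # zero AH difference
  expect_equal(corrected_ippi_tcl(222, 380, 216), 58)
  expect_equal(corrected_ippi_tcl(186, 350, 216), 52)
  # invariant under equal shifts of both AH values
  for (shift in c(-40, 15, 90)) {
    expect_equal(corrected_ippi_tcl(222, 380 + shift, 216 + shift), 58)
  }
})

test_that("AH measurement picks the right beats and errors without His data", {
  d <- fixture_dir()
  s <- read_event_table(file.path(d, "fig3.csv"))
  expect_equal(measure_ah(s, "FIRST_INDUCED"), 380)
  expect_equal(measure_ah(s, "STABLE"), 216)
  expect_equal(measure_ah(s, "FIRST_POST_VOP"), 350)
  no_his <- toy_tachycardia(rep(400, 19))
  expect_error(measure_ah(no_his, "FIRST_INDUCED"),
               class = "svt_measurement_error")
})

test_that("VA sequence counting matches the worked examples", {
  d <- fixture_dir()
  expect_equal(classify_va_sequence(read_event_table(file.path(d, "fig2a.csv")),
                                    "INDUCTION"), "V_A_A_V")
  expect_equal(classify_va_sequence(read_event_table(file.path(d, "fig2b.csv")),
                                    "INDUCTION"), "V_A_V")
  f3 <- read_event_table(file.path(d, "fig3.csv"))
  expect_equal(classify_va_sequence(f3, "INDUCTION"), "V_A_V")
  expect_equal(classify_va_sequence(f3, "POST_VOP"), "V_A_V")
})

test_that("the His guard rejects pseudo V-A-A-V from late atrial candidates", {
  base <- function(second_a_time) {
    egm_series(dplyr::bind_rows(
      tibble::tibble(time_ms = c(0, 400, 800), channel = "RVA", kind = "STIM",
                     origin = "PACED"),
      tibble::tibble(time_ms = 1050, channel = "HRA", kind = "A",
                     origin = "CONDUCTED"),
      tibble::tibble(time_ms = second_a_time, channel = "CS_PROX", kind = "A",
                     origin = "CONDUCTED"),
      tibble::tibble(time_ms = 1250, channel = "HIS", kind = "H",
                     origin = "CONDUCTED"),
      tibble::tibble(time_ms = 1300 + 400 * (0:18), channel = "RVA",
                     kind = "V", origin = "CONDUCTED")
    ))
  }
  # a genuine second atrial cycle before the His of the return beat counts
  expect_equal(classify_va_sequence(base(1200), "INDUCTION"), "V_A_A_V")
  # the same candidate after that His potential does not (guard fires)
  expect_equal(classify_va_sequence(base(1280), "INDUCTION"), "V_A_V")
})

test_that("post-overdrive indices and SA-VA are measured from the VOP segment", {
  d <- fixture_dir()
  s <- read_event_table(file.path(d, "fig3.csv"))
  expect_equal(measure_ppi(s), 586)
  sa_va <- measure_sa_va(s)
  expect_true(is.finite(sa_va))
  expect_equal(measure_delta_va(120, 120), 0)
  expect_equal(measure_delta_va(155, 120), 35)
  no_vop <- read_event_table(file.path(d, "fig2b.csv"))
  expect_error(measure_ppi(no_vop), class = "svt_measurement_error")
})

test_that("simulated AVNRT shows a long SA-VA and ORT tracks 2d", {
  cases <- mech_cases()
  av <- cases[cases$mechanism == "AVNRT" & cases$entrained & !cases$terminated, ]
  expect_true(all(av$sa_va > 85))
  ort <- cases[cases$mechanism == "ORT" & cases$entrained & !cases$terminated, ]
  expect_gt(cor(ort$sa_va, ort$d), 0.9)
})

test_that("index reports satisfy their arithmetic identities", {
  d <- fixture_dir()
  r <- build_index_report(read_event_table(file.path(d, "fig3.csv")))
  expect_equal(r$ippi_tcl, r$ippi - r$tcl, tolerance = 0.05)
  expect_equal(r$ppi_tcl, r$ppi - r$tcl, tolerance = 0.05)
  expect_equal(r$c_ippi_tcl,
               r$ippi_tcl - (r$ah_induction - r$ah_tachycardia),
               tolerance = 0.05)
  expect_equal(r$c_ppi_tcl,
               r$ppi_tcl - (r$ah_post_vop - r$ah_tachycardia),
               tolerance = 0.05)

  cases <- mech_cases()
  ok <- cases[cases$induced, ]
  expect_true(all(abs(ok$ippi_tcl - (ok$ippi - ok$tcl)) < 0.05, na.rm = TRUE))

  # induction-only input leaves the post-pacing fields absent
  r2 <- build_index_report(read_event_table(file.path(d, "fig2c.csv")))
  expect_true(is.na(r2$ppi) && is.na(r2$ppi_tcl) && is.na(r2$c_ppi_tcl))
  expect_equal(r2$ippi, 402)
})

test_that("a re-read series yields an identical index report", {
  d <- fixture_dir()
  s <- read_event_table(file.path(d, "fig3.csv"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_table(s, path)
  r1 <- build_index_report(s)
  r2 <- build_index_report(read_event_table(path))
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("field-level measurement failures do not abort the report", {
  s <- toy_tachycardia(rep(400, 19))  # no His, no atrial events
  r <- build_index_report(s)
  expect_equal(r$tcl, 400)
  expect_true(is.na(r$ah_induction))
  errs <- attr(r, "errors")
  expect_true("ah_induction" %in% names(errs))
})
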