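test_that("conduction time follows the exponential recovery curve", {
  e <- list(ct_base = 80, decrement_amp = 60, recovery_tau = 100, erp = 300)
  expect_true(is.na(conduction_time(e, 250)))       # ci < ERP blocks
  expect_equal(conduction_time(e, 300), 140)        # erp: full decrement
  # closed-form limit: within 0.05 ms of ct_base for ci > erp + 20 tau
  expect_equal(conduction_time(e, 300 + 20 * 100 + 1), 80, tolerance = 0.05 / 80)
  # monotone non-increasing
  ci <- seq(300, 2000, by = 10)
  expect_true(all(diff(conduction_time(e, ci)) <= 0))
  # no-decrement limit
  e0 <- list(ct_base = 80, decrement_amp = 0, recovery_tau = 100, erp = 300)
  expect_equal(conduction_time(e0, c(300, 500, 5000)), rep(80, 3))
  expect_error(conduction_time(e, 0), "positive")
})

test_that("substrate construction is deterministic and structurally valid", {
  m1 <- make_model("ORT", 11)
  m2 <- make_model("ORT", 11)
  expect_identical(m1$elements, m2$elements)
  expect_true("accessory_pathway" %in% m1$elements$name)
  expect_true(is.finite(m1$d) && m1$d >= 30 && m1$d <= 90)

  at <- make_model("AT", 5)
  expect_true(all(c("slow_zone", "fast_limb") %in% at$elements$name))
  expect_identical(at$eaas, "HRA")
})

test_that("all dual-pathway substrates keep the slow antegrade ERP below the fast", {
  for (s in 1:100) {
    m <- make_model("AVNRT", s)
    el <- m$elements
    slow <- el$erp[el$name == "slow_pathway"]
    fast <- el$erp[el$name %in% c("fast_pathway", "slow_pathway_ante")]
    expect_lt(slow, fast)
  }
})

test_that("propagation is deterministic for identical inputs", {
  m <- make_model("AVNRT", 7)
  s1 <- run_induction_study(m)
  s2 <- run_induction_study(m)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_identical(egm_meta(s1), egm_meta(s2))
})

test_that("induction requires a unidirectional block window", {
  m <- make_model("AVNRT_FAST_SLOW", 3)
  # remove the window: make the retrograde (slow) limb refractory at every
  # protocol coupling, so no stimulus can block one limb yet traverse the
  # other
  i <- m$elements$name == "slow_pathway"
  m$elements$erp[i] <- 900
  m$elements$erp_retro[i] <- 900
  s <- run_induction_study(m)
  expect_false(isTRUE(egm_meta(s)$induced))
  expect_true(isTRUE(egm_meta(s)$not_inducible))
})

test_that("every substrate induces a sustained tachycardia with >= 30 beats", {
  cases <- mech_cases()
  expect_true(all(cases$induced))
  for (s in 1:3) {
    ser <- run_induction_study(make_model("AT", s))
    last <- as.numeric(egm_meta(ser)$induction_train_end)
    v <- ser$time_ms[ser$kind == "V" & ser$channel == "RVA" &
                       ser$origin == "CONDUCTED" & ser$time_ms > last]
    expect_gte(length(v), 30)
  }
})

test_that("induction sequence is V-A-A-V exactly for atrial tachycardia", {
  cases <- mech_cases()
  expect_true(all(cases$iva_sequence[cases$mechanism == "AT"] == "V_A_A_V"))
  expect_true(all(cases$iva_sequence[cases$mechanism != "AT"] == "V_A_V"))
})

test_that("induction and post-overdrive sequences are fully concordant", {
  cases <- mech_cases()
  entr <- cases[cases$entrained & !cases$terminated, ]
  expect_gt(nrow(entr), 20)
  expect_equal(mean(entr$iva_sequence == entr$post_vop_sequence), 1)
})

test_that("decrement-free circuits obey PPI - TCL = iPPI - TCL = 2 d exactly", {
  df <- decrement_free_cases()
  df <- df[df$entrained & !df$terminated, ]
  expect_gt(nrow(df), 4)
  expect_true(all(abs(df$ippi_tcl - 2 * df$d) < 0.05))
  expect_true(all(abs(df$ppi_tcl - 2 * df$d) < 0.05))
})

test_that("iPPI is non-increasing in the extrastimulus coupling interval", {
  m <- make_model("ORT_SEPTAL", 4)
  ippi_at <- function(s2) {
    p <- pacing_protocol("EXTRASTIM", s2_start = s2, s2_floor = s2)
    ser <- simulate_svt(m, p)
    if (!isTRUE(egm_meta(ser)$induced)) return(NA_real_)
    measure_ippi(ser)
  }
  vals <- vapply(seq(330, 230, by = -10), ippi_at, numeric(1))
  vals <- vals[!is.na(vals)]
  expect_gt(length(vals), 3)
  # coupling decreases along the sweep, so iPPI must be non-decreasing here
  expect_true(all(diff(vals) >= -0.05))
})

test_that("overdrive pacing entrains and the tachycardia resumes", {
  cases <- mech_cases()
  expect_gt(mean(cases$entrained), 0.9)
  m <- make_model("AT", 6)
  v <- run_vop(m, run_induction_study(m))
  meta <- egm_meta(v)
  expect_true(isTRUE(meta$entrained))
  # entrained atrial rate equals the pacing cycle length
  pcl <- as.numeric(meta$vop_pcl)
  a <- v$time_ms[v$kind == "A" & v$channel == "HRA" &
                   v$time_ms > as.numeric(meta$vop_first_stim) &
                   v$time_ms <= as.numeric(meta$vop_train_end) + pcl]
  expect_true(all(abs(tail(diff(a), 8) - pcl) <= 1))
})
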