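# Measurement of the induction and entrainment indices from an annotated
# event series: tachycardia cycle length, induction postpacing interval
# (iPPI) and its AH-corrected difference from the TCL, the induction
# ventriculoatrial sequence, and the conventional post-overdrive indices
# (PPI, SA-VA, delta-VA).

measurement_error <- function(code, msg) {
  cond <- structure(list(message = sprintf("%s: %s", code, msg), call = NULL),
                    class = c("svt_measurement_error", "error", "condition"))
  attr(cond, "code") <- code
  stop(cond)
}

meta_num <- function(series, key) {
  v <- egm_meta(series)[[key]]
  if (is.null(v)) NA_real_ else suppressWarnings(as.numeric(v))
}

# Last stimulus of the inducing train. Recorded by the simulator; for
# hand-authored tables without metadata, the last stimulus before the
# overdrive train (or overall) is used.
induction_stim_end <- function(series) {
  m <- meta_num(series, "induction_train_end")
  if (is.finite(m)) return(m)
  stim <- series$time_ms[series$kind == "STIM"]
  vf <- meta_num(series, "vop_first_stim")
  if (is.finite(vf)) stim <- stim[stim < vf]
  if (length(stim) == 0) measurement_error("NO_STIM", "series contains no stimuli")
  max(stim)
}

induction_v_window_end <- function(series) {
  vf <- meta_num(series, "vop_first_stim")
  if (is.finite(vf)) vf else Inf
}

conducted_v_times <- function(series, after, before = Inf) {
  sel <- series$kind == "V" & series$channel == "RVA" &
    series$origin != "PACED" & series$time_ms > after & series$time_ms < before
  sort(series$time_ms[sel])
}

atrial_events <- function(series, after = -Inf, before = Inf) {
  sel <- series$kind == "A" & series$time_ms > after & series$time_ms < before
  out <- series[sel, c("time_ms", "channel")]
  out[order(out$time_ms), , drop = FALSE]
}

# Groups atrial annotations across channels into discrete atrial cycles:
# a new cycle starts when the gap to the previous atrial event exceeds
# `gap`. Clustering runs over a padded window so that a cycle whose
# activation spread straddles the window edge is not split; only cycles
# whose earliest A lies in [after, before) are returned (one row per cycle:
# earliest A and its channel).
atrial_cycles <- function(series, after = -Inf, before = Inf, gap = 100) {
  pad <- 200
  a <- atrial_events(series,
                     if (is.finite(after)) after - pad else after,
                     if (is.finite(before)) before + pad else before)
  if (nrow(a) == 0) return(a[0, ])
  cyc <- cumsum(c(1, diff(a$time_ms) > gap))
  first <- a[!duplicated(cyc), , drop = FALSE]
  first[first$time_ms > after & first$time_ms < before, , drop = FALSE]
}

# Stable-window search: V-V intervals on RVA, starting at the 10th
# post-induction beat, first run of 5 consecutive intervals within 20 ms of
# one another. Returns the interval indices of the run.
stable_window <- function(vv) {
  if (length(vv) < 14) return(NULL)
  for (k in 10:(length(vv) - 4)) {
    w <- vv[k:(k + 4)]
    if (max(w) - min(w) <= 20 + MS_TOL) return(k:(k + 4))
  }
  NULL
}

#' Measure the stable tachycardia cycle length
#'
#' The TCL is the median of 5 consecutive V-V intervals on the right
#' ventricular apical channel, taken from the 10th post-induction beat
#' onwards (skipping the early postinduction fluctuation), all within 20 ms
#' of one another.
#'
#' @param series An `egm_series` containing an induced tachycardia.
#' @return TCL in ms.
#' @export
measure_tcl <- function(series) {
  stopifnot(inherits(series, "egm_series"))
  v <- conducted_v_times(series, induction_stim_end(series),
                         induction_v_window_end(series))
  if (length(v) < 15) {
    measurement_error("STABILITY", "fewer than 15 conducted beats after induction")
  }
  vv <- diff(v)
  w <- stable_window(vv)
  if (is.null(w)) measurement_error("STABILITY", "no stable 5-beat window found")
  stats::median(vv[w])
}

#' Measure the induction postpacing interval (iPPI)
#'
#' The interval from the last ventricular pacing stimulus of the inducing
#' train to the first conducted ventricular electrogram on the right
#' ventricular apical channel.
#'
#' @param series An `egm_series` containing an induced tachycardia.
#' @return iPPI in ms.
#' @export
measure_ippi <- function(series) {
  stopifnot(inherits(series, "egm_series"))
  last_stim <- induction_stim_end(series)
  v <- conducted_v_times(series, last_stim, induction_v_window_end(series))
  if (length(v) == 0) {
    measurement_error("NO_RETURN_V", "no conducted V after the last stimulus")
  }
  v[1] - last_stim
}

#' AH-corrected difference between the iPPI and the TCL
#'
#' Subtracts the excess AV-nodal delay of the induction beat relative to
#' stable tachycardia: `ippi_tcl - (ah_induction - ah_tachycardia)`. The
#' result is invariant under equal shifts of both AH values.
#'
#' @param ippi_tcl iPPI minus TCL (ms).
#' @param ah_induction AH interval of the first induced beat (ms).
#' @param ah_tachycardia AH interval during stable tachycardia (ms).
#' @return Corrected iPPI-TCL in ms.
#' @export
corrected_ippi_tcl <- function(ippi_tcl, ah_induction, ah_tachycardia) {
  stopifnot(is.finite(ippi_tcl), is.finite(ah_induction), is.finite(ah_tachycardia))
  ippi_tcl - (ah_induction - ah_tachycardia)
}

ah_of_beat <- function(series, v_time) {
  his <- series[series$channel == "HIS", , drop = FALSE]
  h <- his$time_ms[his$kind == "H" & his$time_ms < v_time]
  if (length(h) == 0) measurement_error("NO_HIS", "no His potential before beat")
  h <- max(h)
  a <- his$time_ms[his$kind == "A" & his$time_ms < h]
  if (length(a) == 0) measurement_error("NO_HIS", "no atrial electrogram before His")
  h - max(a)
}

#' Measure an AH interval
#'
#' Atrio-Hisian interval on the His channel for a named beat:
#' `"FIRST_INDUCED"` (first conducted beat after the inducing train),
#' `"STABLE"` (mean over the 5 beats of the stable TCL window) or
#' `"FIRST_POST_VOP"` (first conducted beat after overdrive cessation).
#'
#' @param series An `egm_series`.
#' @param beat Which beat to measure.
#' @return AH interval in ms.
#' @export
measure_ah <- function(series, beat = c("FIRST_INDUCED", "STABLE",
                                        "FIRST_POST_VOP")) {
  stopifnot(inherits(series, "egm_series"))
  beat <- match.arg(beat)
  if (beat == "FIRST_POST_VOP") {
    vt <- meta_num(series, "vop_train_end")
    if (!is.finite(vt)) measurement_error("NO_VOP", "series has no overdrive segment")
    v <- conducted_v_times(series, vt)
    if (length(v) == 0) measurement_error("NO_RETURN_V", "no conducted V after VOP")
    return(ah_of_beat(series, v[1]))
  }
  last_stim <- induction_stim_end(series)
  v <- conducted_v_times(series, last_stim, induction_v_window_end(series))
  if (length(v) == 0) measurement_error("NO_RETURN_V", "no conducted V after induction")
  if (beat == "FIRST_INDUCED") return(ah_of_beat(series, v[1]))
  vv <- diff(v)
  w <- stable_window(vv)
  if (is.null(w)) measurement_error("STABILITY", "no stable window for AH")
  mean(vapply(v[w + 1], function(t) ah_of_beat(series, t), numeric(1)))
}

# Analysis of the post-pacing ventriculoatrial response shared by the
# sequence classifier and the SA-VA measurement. The atrial cycles between
# the last stimulus and the return V begin with the activations still
# entrained by the train (more than one when the VA conduction time exceeds
# the pacing cycle length, so a wavefront is in flight at cessation): the
# longest prefix whose spacing continues the train's rhythm. The last of
# these is the last entrained atrial activation; the response is
# counted from it.
va_response <- function(series, phase) {
  if (phase == "POST_VOP") {
    last_stim <- meta_num(series, "vop_train_end")
    if (!is.finite(last_stim)) {
      measurement_error("NO_VOP", "series has no overdrive segment")
    }
    first_stim <- meta_num(series, "vop_first_stim")
    v_end <- Inf
  } else {
    last_stim <- induction_stim_end(series)
    first_stim <- -Inf
    v_end <- induction_v_window_end(series)
  }
  stim <- series$time_ms[series$kind == "STIM" &
                           series$time_ms <= last_stim + MS_TOL &
                           series$time_ms >= first_stim - MS_TOL]
  stim <- sort(stim)
  v <- conducted_v_times(series, last_stim, v_end)
  if (length(v) == 0) return(NULL)
  cyc <- atrial_cycles(series, after = last_stim, before = v[1])
  if (nrow(cyc) == 0) return(list(v = v[1], cycles = cyc, j = 0L, count = 0L))
  # pseudo-sequence guard: an atrial candidate after the His potential that
  # precedes the return V is not a separate atrial cycle
  h <- series$time_ms[series$kind == "H" & series$time_ms < v[1]]
  if (length(h) > 0) {
    cyc <- cyc[cyc$time_ms <= max(h) + MS_TOL, , drop = FALSE]
  }
  if (nrow(cyc) == 0) return(list(v = v[1], cycles = cyc, j = 0L, count = 0L))
  j <- 1L
  if (nrow(cyc) > 1 && length(stim) >= 2) {
    iv <- diff(stim)
    cl_last <- iv[length(iv)]
    # an extrastimulus train ends on a premature coupling; decremental
    # conduction of that beat can stretch its atrial spacing well beyond
    # the coupling interval
    extrastim <- length(iv) >= 2 &&
      abs(cl_last - stats::median(iv[-length(iv)])) > 20
    hi <- if (extrastim) cl_last + 95 else cl_last + 8
    lo <- cl_last - 8
    gaps <- diff(cyc$time_ms)
    while (j < nrow(cyc) && gaps[j] >= lo && gaps[j] <= hi) j <- j + 1L
  }
  list(v = v[1], cycles = cyc, j = j, count = nrow(cyc) - j + 1L)
}

#' Classify the ventriculoatrial response after pacing
#'
#' Counts the discrete atrial activations (earliest A per atrial cycle
#' across all atrial channels, cycles separated by more than 100 ms) from
#' the last entrained atrial activation to the first conducted return V on
#' the right ventricular apical channel: one atrial cycle is a V-A-V
#' response, two is V-A-A-V. Atrial cycles that continue the pacing train's
#' rhythm (wavefronts still in flight at cessation when VA conduction
#' exceeds the pacing cycle length) are part of the entrained prefix, and an
#' atrial candidate that follows the His potential preceding the return V is
#' not counted as a separate cycle (pseudo-V-A-A-V exclusion for delayed
#' His-region ventricular electrograms).
#'
#' @param series An `egm_series`.
#' @param phase `"INDUCTION"` or `"POST_VOP"`.
#' @return `"V_A_V"`, `"V_A_A_V"` or `"INDETERMINATE"`.
#' @export
classify_va_sequence <- function(series, phase = c("INDUCTION", "POST_VOP")) {
  stopifnot(inherits(series, "egm_series"))
  phase <- match.arg(phase)
  r <- va_response(series, phase)
  if (is.null(r)) return("INDETERMINATE")
  switch(as.character(r$count), "1" = "V_A_V", "2" = "V_A_A_V",
         "INDETERMINATE")
}

#' Measure the conventional postpacing interval after overdrive pacing
#'
#' @param series An `egm_series` from [run_vop()] (or a recording with
#'   `vop_train_end` metadata).
#' @return PPI in ms.
#' @export
measure_ppi <- function(series) {
  stopifnot(inherits(series, "egm_series"))
  vt <- meta_num(series, "vop_train_end")
  if (!is.finite(vt)) measurement_error("NO_VOP", "series has no overdrive segment")
  v <- conducted_v_times(series, vt)
  if (length(v) == 0) {
    measurement_error("NO_RETURN_V", "no conducted V after the last VOP stimulus")
  }
  v[1] - vt
}

va_during_tachycardia <- function(series) {
  last_stim <- induction_stim_end(series)
  v <- conducted_v_times(series, last_stim, induction_v_window_end(series))
  vv <- diff(v)
  w <- stable_window(vv)
  if (is.null(w)) measurement_error("STABILITY", "no stable window for VA")
  tcl <- stats::median(vv[w])
  va <- vapply(v[w], function(t) {
    a <- atrial_cycles(series, after = t - 100, before = t + tcl - 100)
    if (nrow(a) == 0) return(NA_real_)
    a$time_ms[1] - t
  }, numeric(1))
  if (all(is.na(va))) measurement_error("NO_ATRIAL", "no atrial events in window")
  stats::median(va, na.rm = TRUE)
}

#' Measure the SA minus VA interval
#'
#' Stimulus-to-atrial interval of the last entrained beat minus the
#' ventriculoatrial interval during stable tachycardia (earliest atrial
#' activation in both cases).
#'
#' @param series An `egm_series` from [run_vop()].
#' @return SA-VA in ms.
#' @export
measure_sa_va <- function(series) {
  stopifnot(inherits(series, "egm_series"))
  vt <- meta_num(series, "vop_train_end")
  if (!is.finite(vt)) measurement_error("NO_VOP", "series has no overdrive segment")
  r <- va_response(series, "POST_VOP")
  if (is.null(r) || r$j == 0) {
    measurement_error("NO_ATRIAL", "no entrained atrial activation after VOP")
  }
  sa <- r$cycles$time_ms[r$j] - vt
  sa - va_during_tachycardia(series)
}

#' Delta-VA interval
#'
#' Difference between the ventriculoatrial interval after cessation of
#' pacing and the ventriculoatrial interval during tachycardia.
#'
#' @param va_post_pacing,va_tachycardia VA intervals in ms.
#' @return Delta-VA in ms.
#' @export
measure_delta_va <- function(va_post_pacing, va_tachycardia) {
  stopifnot(is.finite(va_post_pacing), is.finite(va_tachycardia))
  va_post_pacing - va_tachycardia
}

measured_eaas <- function(series) {
  last_stim <- induction_stim_end(series)
  v <- conducted_v_times(series, last_stim, induction_v_window_end(series))
  vv <- diff(v)
  w <- stable_window(vv)
  if (is.null(w)) measurement_error("STABILITY", "no stable window for EAAS")
  tcl <- stats::median(vv[w])
  ch <- vapply(v[w], function(t) {
    a <- atrial_cycles(series, after = t - 100, before = t + tcl - 100)
    if (nrow(a) == 0) return(NA_character_)
    a$channel[1]
  }, character(1))
  ch <- ch[!is.na(ch)]
  if (length(ch) == 0) measurement_error("NO_ATRIAL", "no atrial events in window")
  names(sort(table(ch), decreasing = TRUE))[1]
}

#' Assemble the per-case index report
#'
#' Measures every derivable index from an induction recording and, when an
#' overdrive segment is available, the conventional post-pacing indices.
#' Fields whose measurement fails are reported as `NA`, with the error codes
#' collected in the `errors` attribute; the report is never aborted by a
#' single failing field.
#'
#' @param induction_series Series from [run_induction_study()] (or any
#'   induction recording).
#' @param vop_series Optional series from [run_vop()]. If omitted and
#'   `induction_series` itself carries an overdrive segment, that segment is
#'   used.
#' @return A one-row tibble of class `svt_index_report` with columns `tcl`,
#'   `ippi`, `ippi_tcl`, `ah_induction`, `ah_tachycardia`, `c_ippi_tcl`,
#'   `ppi`, `ppi_tcl`, `ah_post_vop`, `c_ppi_tcl`, `sa_va`, `delta_va`,
#'   `iva_sequence`, `post_vop_sequence`, `eaas`.
#' @export
build_index_report <- function(induction_series, vop_series = NULL) {
  stopifnot(inherits(induction_series, "egm_series"))
  vop_src <- vop_series %||% induction_series
  errors <- list()
  grab <- function(field, expr) {
    tryCatch(expr, svt_measurement_error = function(e) {
      errors[[field]] <<- attr(e, "code") %||% conditionMessage(e)
      NA
    })
  }
  tcl <- grab("tcl", measure_tcl(induction_series))
  ippi <- grab("ippi", measure_ippi(induction_series))
  ippi_tcl <- if (is.finite(tcl) && is.finite(ippi)) ippi - tcl else NA_real_
  ah_ind <- grab("ah_induction", measure_ah(induction_series, "FIRST_INDUCED"))
  ah_tach <- grab("ah_tachycardia", measure_ah(induction_series, "STABLE"))
  c_ippi <- if (is.finite(ippi_tcl) && is.finite(ah_ind) && is.finite(ah_tach)) {
    corrected_ippi_tcl(ippi_tcl, ah_ind, ah_tach)
  } else NA_real_

  has_vop <- is.finite(meta_num(vop_src, "vop_train_end"))
  ppi <- if (has_vop) grab("ppi", measure_ppi(vop_src)) else NA_real_
  ppi_tcl <- if (is.finite(ppi) && is.finite(tcl)) ppi - tcl else NA_real_
  ah_pv <- if (has_vop) grab("ah_post_vop", measure_ah(vop_src, "FIRST_POST_VOP")) else NA_real_
  c_ppi <- if (is.finite(ppi_tcl) && is.finite(ah_pv) && is.finite(ah_tach)) {
    corrected_ippi_tcl(ppi_tcl, ah_pv, ah_tach)
  } else NA_real_
  sa_va <- if (has_vop) grab("sa_va", measure_sa_va(vop_src)) else NA_real_
  pv_seq <- if (has_vop) {
    grab("post_vop_sequence", classify_va_sequence(vop_src, "POST_VOP"))
  } else NA_character_

  out <- tibble::tibble(
    tcl = as.numeric(tcl), ippi = as.numeric(ippi), ippi_tcl = ippi_tcl,
    ah_induction = as.numeric(ah_ind), ah_tachycardia = as.numeric(ah_tach),
    c_ippi_tcl = c_ippi,
    ppi = as.numeric(ppi), ppi_tcl = ppi_tcl,
    ah_post_vop = as.numeric(ah_pv), c_ppi_tcl = c_ppi,
    sa_va = as.numeric(sa_va), delta_va = NA_real_,
    iva_sequence = grab("iva_sequence",
                        classify_va_sequence(induction_series, "INDUCTION")),
    post_vop_sequence = as.character(pv_seq),
    eaas = grab("eaas", measured_eaas(induction_series))
  )
  structure(out, class = c("svt_index_report", class(out)), errors = errors)
}
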