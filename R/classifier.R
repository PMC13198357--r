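# Rule-based diagnostic adjudication: the conventional criteria
# (entrainment responses, postpacing indices, pacing maneuvers) and the
# induction-based classifier (iVA sequence plus corrected iPPI-TCL).

#' Diagnostic threshold set
#'
#' The conventional cutoffs used by the adjudication rules, in ms:
#' PPI-TCL <= 115 and corrected PPI-TCL <= 110 support ORT over AVNRT;
#' SA-VA < 85 supports ORT; delta-VA > 20 supports AT; AH > 200 indicates a
#' slow antegrade AV-nodal limb and HA > 70 a slow retrograde limb; the
#' induction indices use iPPI-TCL <= 125 and corrected iPPI-TCL <= 110;
#' total pacing prematurity < 125 supports ORT.
#'
#' @param ... Named overrides of individual thresholds.
#' @return A list of class `svt_thresholds`.
#' @export
svt_thresholds <- function(...) {
  th <- list(
    ppi_tcl_ort_max = 115, c_ppi_tcl_ort_max = 110, sa_va_ort_max = 85,
    delta_va_at_min = 20, ah_slow_min = 200, ha_slow_min = 70,
    ippi_tcl_cutoff = 125, c_ippi_tcl_cutoff = 110,
    total_prematurity_ort_max = 125
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(th))
  if (length(bad) > 0) stop("unknown threshold(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
  th[names(dots)] <- dots
  if (any(unlist(th) <= 0)) stop("all thresholds must be positive", call. = FALSE)
  structure(th, class = "svt_thresholds")
}

#' Bundle measurements and maneuver evidence for adjudication
#'
#' Collects the per-case index report together with the boolean results of
#' pacing maneuvers that are observed in the laboratory but lie outside the
#' measurement scope of this package (they are supplied externally, e.g.
#' from the operator's reading of the signals). Flags are tri-state:
#' `TRUE`, `FALSE` or `NA` (unknown); unknown flags never fire a criterion.
#'
#' @param report A one-row [build_index_report()] tibble (or a list/row with
#'   the same fields).
#' @param delta_va Delta-VA after differential atrial overdrive pacing (ms).
#' @param a_h_v_after_atrial_overdrive A-H-V activation sequence after
#'   cessation of atrial overdrive pacing with orthodromic atrial capture.
#' @param termination_without_atrial_capture Tachycardia termination during
#'   VOP or a PVC without atrial capture.
#' @param pvc_resets_atrium Atrial cycle-length prolongation in response to
#'   a premature ventricular contraction.
#' @param av_block_during_svt AH block during tachycardia.
#' @param va_block_during_svt VA block during tachycardia.
#' @param orthodromic_his_capture Orthodromic His capture during VOP.
#' @param ipsilateral_bbb_tcl_prolongation_without_ah TCL prolongation
#'   without AH prolongation during bundle-branch block ipsilateral to the
#'   accessory pathway.
#' @param fusion_during_vop Constant or progressive fusion during VOP.
#' @param total_prematurity Total pacing prematurity (ms).
#' @param exaggerated_vaav_return Return atrial interval of a V-A-A-V
#'   response substantially exceeding the TCL.
#' @return A list of class `svt_evidence`.
#' @export
diagnostic_evidence <- function(report = NULL, delta_va = NA_real_,
                                a_h_v_after_atrial_overdrive = NA,
                                termination_without_atrial_capture = NA,
                                pvc_resets_atrium = NA,
                                av_block_during_svt = NA,
                                va_block_during_svt = NA,
                                orthodromic_his_capture = NA,
                                ipsilateral_bbb_tcl_prolongation_without_ah = NA,
                                fusion_during_vop = NA,
                                total_prematurity = NA_real_,
                                exaggerated_vaav_return = NA) {
  structure(list(
    report = report, delta_va = delta_va,
    a_h_v_after_atrial_overdrive = a_h_v_after_atrial_overdrive,
    termination_without_atrial_capture = termination_without_atrial_capture,
    pvc_resets_atrium = pvc_resets_atrium,
    av_block_during_svt = av_block_during_svt,
    va_block_during_svt = va_block_during_svt,
    orthodromic_his_capture = orthodromic_his_capture,
    ipsilateral_bbb_tcl_prolongation_without_ah =
      ipsilateral_bbb_tcl_prolongation_without_ah,
    fusion_during_vop = fusion_during_vop,
    total_prematurity = total_prematurity,
    exaggerated_vaav_return = exaggerated_vaav_return
  ), class = "svt_evidence")
}

is_true <- function(x) isTRUE(as.logical(x))
num_or_na <- function(x) if (is.null(x) || length(x) == 0) NA_real_ else as.numeric(x)

report_field <- function(ev, field) {
  r <- ev$report
  if (is.null(r)) return(NA)
  v <- r[[field]]
  if (is.null(v) || length(v) == 0) NA else v[[1]]
}

#' Conventional rule-based diagnosis of the SVT mechanism
#'
#' Applies the established electrophysiological criteria in a fixed order:
#' AT exclusions, AT inclusions, ORT exclusions, ORT inclusions, then AVNRT
#' by double exclusion (findings inconsistent with both AT and ORT). Any
#' exclusion vetoes the corresponding diagnosis regardless of inclusions;
#' unknown evidence never fires a criterion, so a partial workup degrades to
#' `INDETERMINATE` rather than misclassifying.
#'
#' @param evidence A [diagnostic_evidence()] object.
#' @param thresholds A [svt_thresholds()] set.
#' @return A list of class `svt_diagnosis` with elements `diagnosis`
#'   (`"AT"`, `"ORT"`, `"AVNRT"` or `"INDETERMINATE"`) and `fired` (the
#'   identifiers of every criterion that evaluated true, for audit).
#' @export
classify_conventional <- function(evidence, thresholds = svt_thresholds()) {
  stopifnot(inherits(evidence, "svt_evidence"),
            inherits(thresholds, "svt_thresholds"))
  fired <- character(0)
  note <- function(id, cond) {
    if (isTRUE(cond)) fired <<- c(fired, id)
    isTRUE(cond)
  }
  pseq <- report_field(evidence, "post_vop_sequence")
  ppi_tcl <- num_or_na(report_field(evidence, "ppi_tcl"))
  c_ppi_tcl <- num_or_na(report_field(evidence, "c_ppi_tcl"))
  sa_va <- num_or_na(report_field(evidence, "sa_va"))
  delta_va <- num_or_na(evidence$delta_va)
  if (!is.finite(delta_va)) {
    delta_va <- num_or_na(report_field(evidence, "delta_va"))
  }

  at_excluded <-
    note("AT_EXCL_VAV_RESPONSE", identical(pseq, "V_A_V")) |
    note("AT_EXCL_TERMINATION_WITHOUT_A",
         is_true(evidence$termination_without_atrial_capture)) |
    note("AT_EXCL_PVC_RESETS_ATRIUM", is_true(evidence$pvc_resets_atrium)) |
    note("AT_EXCL_VA_BLOCK", is_true(evidence$va_block_during_svt))

  at_included <-
    note("AT_DELTA_VA",
         is.finite(delta_va) && delta_va > thresholds$delta_va_at_min) |
    note("AT_AHV_AFTER_ATRIAL_OVERDRIVE",
         is_true(evidence$a_h_v_after_atrial_overdrive)) |
    note("AT_EXAGGERATED_VAAV", identical(pseq, "V_A_A_V") &&
           is_true(evidence$exaggerated_vaav_return))

  ort_excluded <-
    note("ORT_EXCL_AV_BLOCK", is_true(evidence$av_block_during_svt))

  tp <- num_or_na(evidence$total_prematurity)
  ort_included <-
    note("ORT_PPI_TCL", is.finite(ppi_tcl) &&
           ppi_tcl <= thresholds$ppi_tcl_ort_max) |
    note("ORT_C_PPI_TCL", is.finite(c_ppi_tcl) &&
           c_ppi_tcl <= thresholds$c_ppi_tcl_ort_max) |
    note("ORT_HIS_CAPTURE", is_true(evidence$orthodromic_his_capture)) |
    note("ORT_BBB_TCL_PROLONGATION",
         is_true(evidence$ipsilateral_bbb_tcl_prolongation_without_ah)) |
    note("ORT_SA_VA", is.finite(sa_va) && sa_va < thresholds$sa_va_ort_max) |
    note("ORT_FUSION", is_true(evidence$fusion_during_vop)) |
    note("ORT_TOTAL_PREMATURITY", is.finite(tp) &&
           tp < thresholds$total_prematurity_ort_max)

  diagnosis <- if (!at_excluded && at_included) {
    "AT"
  } else if (!ort_excluded && ort_included) {
    "ORT"
  } else if (at_excluded && !(ort_included && !ort_excluded)) {
    # inconsistent with AT; no surviving ORT criterion: AVNRT by double
    # exclusion (requires the VOP workup to be present)
    if (identical(pseq, "V_A_V")) "AVNRT" else "INDETERMINATE"
  } else {
    "INDETERMINATE"
  }
  structure(list(diagnosis = diagnosis, fired = sort(unique(fired))),
            class = "svt_diagnosis")
}

#' @export
print.svt_diagnosis <- function(x, ...) {
  cat("diagnosis:", x$diagnosis, "\n")
  if (length(x$fired) > 0) cat("criteria fired:", paste(x$fired, collapse = ", "), "\n")
  invisible(x)
}

#' Subclassify AVNRT from limb conduction times
#'
#' An AH interval above the slow-pathway threshold indicates a slow
#' antegrade limb; a retrograde HA interval above its threshold indicates a
#' slow retrograde limb. The earliest atrial activation site breaks ties
#' when the HA interval lies within 10 ms of its threshold (His region:
#' fast retrograde; CS ostium: slow retrograde).
#'
#' @param ah Antegrade AH interval during tachycardia (ms).
#' @param ha Retrograde His-atrial interval (ms).
#' @param eaas Earliest atrial activation channel (`"HIS"`, `"HRA"`,
#'   `"CS_PROX"`, ...).
#' @param thresholds A [svt_thresholds()] set.
#' @return `"SLOW_FAST"`, `"FAST_SLOW"` or `"SLOW_SLOW"`.
#' @export
subclassify_avnrt <- function(ah, ha, eaas = NA_character_,
                              thresholds = svt_thresholds()) {
  stopifnot(is.finite(ah), is.finite(ha))
  slow_ante <- ah > thresholds$ah_slow_min
  slow_retro <- ha > thresholds$ha_slow_min
  if (!is.na(eaas) && abs(ha - thresholds$ha_slow_min) <= 10) {
    slow_retro <- eaas %in% c("CS_PROX", "CS_MID", "CS_DIST")
  }
  if (slow_ante && slow_retro) return("SLOW_SLOW")
  if (slow_ante) return("SLOW_FAST")
  if (slow_retro) return("FAST_SLOW")
  stop("neither limb is slow: not a reentrant AVNRT conduction pattern",
       call. = FALSE)
}

#' Induction-based diagnosis of the SVT mechanism
#'
#' A V-A-A-V induction sequence indicates AT; a V-A-V sequence with a
#' corrected iPPI-TCL at or below the cutoff indicates ORT, and above it
#' AVNRT. Vectorized over cases.
#'
#' @param iva_sequence `"V_A_V"`, `"V_A_A_V"` or `"INDETERMINATE"`.
#' @param c_ippi_tcl Corrected iPPI-TCL values (ms).
#' @param thresholds A [svt_thresholds()] set.
#' @return Character vector of diagnoses.
#' @export
classify_induction <- function(iva_sequence, c_ippi_tcl,
                               thresholds = svt_thresholds()) {
  stopifnot(length(iva_sequence) == length(c_ippi_tcl))
  cutoff <- thresholds$c_ippi_tcl_cutoff
  dplyr::case_when(
    iva_sequence == "V_A_A_V" ~ "AT",
    iva_sequence == "V_A_V" & is.finite(c_ippi_tcl) & c_ippi_tcl <= cutoff ~ "ORT",
    iva_sequence == "V_A_V" ~ "AVNRT",
    TRUE ~ "INDETERMINATE"
  )
}

#' Apply the induction classifier to a cohort table
#'
#' @param cohort A cohort tibble with columns `iva_sequence` and
#'   `c_ippi_tcl` (as produced by [generate_cohort()]).
#' @param thresholds A [svt_thresholds()] set.
#' @return The cohort with an `induction_dx` column appended.
#' @export
classify_cohort <- function(cohort, thresholds = svt_thresholds()) {
  stopifnot(is.data.frame(cohort))
  dplyr::mutate(cohort,
                induction_dx = classify_induction(.data$iva_sequence,
                                                  .data$c_ippi_tcl, thresholds))
}
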