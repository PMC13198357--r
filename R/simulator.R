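# Discrete-event conduction simulator for SVT substrates under programmed
# ventricular stimulation, burst pacing and ventricular overdrive pacing.
#
# The substrate is a small directed graph of conduction elements between
# named nodes (ventricular apex, His bundle, atrial recording sites, and for
# atrial tachycardia a two-limb atrial ring). Each element has a base
# conduction time, a recovery-dependent decremental delay, and an effective
# refractory period; propagation is a strict time-ordered event queue with
# per-node refractoriness, in-element wavefront collision, and AV-nodal
# concealment (every penetration resets the element's recovery clock).

NODE_REFRACTORY_MS <- 130

SVT_MECHANISMS <- c("AT", "AVNRT", "ORT",
                    "AVNRT_SLOW_FAST", "AVNRT_FAST_SLOW", "AVNRT_SLOW_SLOW",
                    "ORT_FREE_WALL", "ORT_SEPTAL")

#' Recovery-dependent conduction time of a single element
#'
#' Conduction time follows a single-exponential AV-nodal recovery curve:
#' `ct_base + decrement_amp * exp(-(ci - erp) / recovery_tau)` for coupling
#' intervals `ci >= erp`, and block (`NA`) for `ci < erp`. The curve is
#' monotone non-increasing in `ci` and tends to `ct_base` for long coupling
#' intervals.
#'
#' @param element A list (or one-row data frame) with fields `ct_base`,
#'   `decrement_amp`, `recovery_tau` and `erp`, all in ms.
#' @param ci Coupling interval(s) in ms; must be positive.
#' @return Conduction time(s) in ms, `NA_real_` where the element blocks.
#' @examples
#' el <- list(ct_base = 80, decrement_amp = 60, recovery_tau = 100, erp = 300)
#' conduction_time(el, c(250, 300, 400, 2000))
#' @export
conduction_time <- function(element, ci) {
  if (any(!is.finite(ci) | ci <= 0)) stop("ci must be positive and finite",
                                          call. = FALSE)
  stopifnot(element$ct_base > 0, element$decrement_amp >= 0,
            element$recovery_tau > 0, element$erp > 0)
  ct <- element$ct_base +
    element$decrement_amp * exp(-(ci - element$erp) / element$recovery_tau)
  ct[ci < element$erp] <- NA_real_
  ct
}

r01 <- function(x) round(x, 1)

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

runif1 <- function(lo, hi) r01(stats::runif(1, lo, hi))

#' Default physiologic parameter ranges for substrate construction
#'
#' Uniform sampling bounds (ms) used by [make_model()]. Fast AV-nodal
#' pathways conduct quickly with long refractoriness; slow pathways conduct
#' slowly and decrementally with short refractoriness; accessory pathways
#' are fast and non-decremental; the atrial-tachycardia ring couples a slow
#' conduction zone to a short fast limb.
#'
#' @return A named list of `c(lo, hi)` bounds.
#' @export
model_ranges <- function() {
  list(
    fast_ct = c(50, 120), fast_erp = c(310, 400),
    slow_ct = c(210, 330), slow_erp = c(200, 280),
    ap_ct = c(30, 80), ap_erp = c(200, 260),
    at_loop_cl = c(360, 470),
    d_ort = c(30, 90), d_avnrt_myo = c(5, 50),
    hv = c(25, 40)
  )
}

new_node_table <- function(names, channels, kinds) {
  tibble::tibble(name = names, channel = channels, kind = kinds,
                 refractory = NODE_REFRACTORY_MS)
}

# Nodes are listed in channel-priority order so that simultaneous queue
# entries resolve deterministically (RVA < HIS(H) < HIS(A) < HRA < CS...).
base_nodes <- function(extra = character(0)) {
  nm <- c("V_apex", "His", "A_sept", "A_hra", "A_cs_prox", "A_cs_dist",
          "V_ins", "V_ins2", extra)
  ch <- c("RVA", "HIS", "HIS", "HRA", "CS_PROX", "CS_DIST",
          NA, NA, rep(NA, length(extra)))
  kd <- c("V", "H", "A", "A", "A", "A", NA, NA, rep(NA, length(extra)))
  new_node_table(nm, ch, kd)
}

el <- function(name, n1, n2, ct, amp = 0, tau = 100, erp = 150,
               erp_retro = NA_real_) {
  tibble::tibble(name = name, n1 = n1, n2 = n2, direction = "BIDIRECTIONAL",
                 ct_base = ct, decrement_amp = amp, recovery_tau = tau,
                 erp = erp, erp_retro = ifelse(is.na(erp_retro), erp, erp_retro))
}

atrial_elements <- function() {
  dplyr::bind_rows(
    el("sept_hra", "A_sept", "A_hra", runif1(25, 40)),
    el("sept_csp", "A_sept", "A_cs_prox", runif1(15, 30)),
    el("csp_csd", "A_cs_prox", "A_cs_dist", runif1(20, 35))
  )
}

#' Construct a randomized SVT substrate
#'
#' Draws element parameters uniformly from physiologic ranges (see
#' [model_ranges()]) and assembles the conduction graph for the requested
#' mechanism. The umbrella mechanisms `"AVNRT"` and `"ORT"` sample a subtype
#' with the frequencies observed clinically for ventricular-pacing-induced
#' SVT. Construction is deterministic for a fixed `(mechanism, seed)` pair,
#' and every model sustains its tachycardia for at least 30 beats once
#' induced (loop transit time exceeds every circuit element's refractory
#' period by a safety margin).
#'
#' @param mechanism One of `"AT"`, `"AVNRT"`, `"ORT"`,
#'   `"AVNRT_SLOW_FAST"`, `"AVNRT_FAST_SLOW"`, `"AVNRT_SLOW_SLOW"`,
#'   `"ORT_FREE_WALL"`, `"ORT_SEPTAL"`.
#' @param seed Integer seed for the parameter draws. All randomness lives
#'   here; propagation in [simulate_svt()] is deterministic.
#' @param decrement_free If `TRUE`, zero every decrement amplitude. In this
#'   limit the postpacing and induction postpacing intervals obey
#'   `PPI - TCL = iPPI - TCL = 2 d` exactly, where `d` is the one-way
#'   conduction time from the pacing site to the circuit.
#' @return An object of class `svt_circuit`: a list with the mechanism and
#'   subtype, the extra-circuit conduction time `d` (ms; `NA` for AT, whose
#'   access path traverses the decremental AV node), the expected earliest
#'   atrial activation site `eaas`, the nominal loop cycle length
#'   `tcl_nominal`, and `nodes` / `elements` tables.
#' @export
make_model <- function(mechanism, seed, decrement_free = FALSE) {
  mechanism <- match.arg(toupper(mechanism), SVT_MECHANISMS)
  with_seed(seed, {
    subtype <- switch(mechanism,
      AVNRT = sample(c("AVNRT_SLOW_FAST", "AVNRT_FAST_SLOW", "AVNRT_SLOW_SLOW"),
                     1, prob = c(18, 16, 7)),
      ORT = sample(c("ORT_FREE_WALL", "ORT_SEPTAL"), 1, prob = c(35, 6)),
      mechanism
    )
    m <- switch(subtype,
      AVNRT_SLOW_FAST = build_avnrt(subtype),
      AVNRT_FAST_SLOW = build_avnrt(subtype),
      AVNRT_SLOW_SLOW = build_avnrt(subtype),
      ORT_FREE_WALL = build_ort(subtype),
      ORT_SEPTAL = build_ort(subtype),
      AT = build_at()
    )
    if (decrement_free) m$elements$decrement_amp <- 0
    m$mechanism <- sub("_.*$", "", sub("^(AVNRT|ORT|AT).*", "\\1", subtype))
    m$subtype <- subtype
    m$seed <- seed
    m$decrement_free <- decrement_free
    class(m) <- "svt_circuit"
    m
  })
}

ct_of <- function(elements, name) elements$ct_base[elements$name == name]

build_avnrt <- function(subtype) {
  atr <- atrial_elements()
  # The pacing wavefront must cross the ventricle and the His-Purkinje axis
  # to reach the nodal circuit, so the extra-circuit time is long: the
  # postpacing differences (2d and above) then sit above the ORT cutoffs,
  # as they do clinically in AVNRT.
  d_myo <- runif1(30, 55)
  hv <- runif1(30, 42)
  link <- ct_of(atr, "sept_csp")

  if (subtype == "AVNRT_SLOW_FAST") {
    # Antegrade slow / retrograde fast rotation. The slow pathway's
    # retrograde ERP is high, so a premature ventricular wavefront blocks
    # retrogradely in the slow pathway and conducts up the fast pathway.
    ct_f <- runif1(50, 65)
    ct_s <- runif1(210, 330)
    ct_s <- max(ct_s, r01(350 - ct_f - link))
    tcl <- ct_f + link + ct_s
    fast <- el("fast_pathway", "A_sept", "His", ct_f, amp = runif1(10, 25),
               tau = runif1(60, 120), erp = runif1(310, 400),
               erp_retro = min(runif1(250, 300), r01(tcl - 45)))
    slow <- el("slow_pathway", "A_cs_prox", "His", ct_s, amp = runif1(30, 80),
               tau = runif1(80, 150), erp = runif1(200, 280),
               erp_retro = runif1(420, 480))
    eaas <- "HIS"
  } else if (subtype == "AVNRT_FAST_SLOW") {
    # The antegrade (fast) limb has a long retrograde ERP: the 600 ms drive
    # still conducts retrogradely over both pathways (with the slower
    # wavefront annihilated by collision), but premature beats and rapid
    # bursts block in the fast limb and travel the slow pathway alone --
    # the unidirectional block that starts the rotation.
    ct_f <- runif1(50, 120)
    ct_s <- runif1(210, 330)
    ct_s <- max(ct_s, r01(350 - ct_f - link))
    tcl <- ct_f + link + ct_s
    fast <- el("fast_pathway", "A_sept", "His", ct_f, amp = runif1(15, 40),
               tau = runif1(60, 120), erp = min(runif1(310, 400), r01(tcl - 45)),
               erp_retro = runif1(420, 480))
    slow <- el("slow_pathway", "A_cs_prox", "His", ct_s, amp = runif1(30, 80),
               tau = runif1(80, 150), erp = runif1(200, 280))
    eaas <- "CS_PROX"
  } else {
    ct_sa <- runif1(210, 300)
    tcl_target <- runif1(380, 460)
    ct_sr <- min(max(r01(tcl_target - ct_sa - link), 180), 330)
    tcl <- ct_sa + link + ct_sr
    fast <- el("slow_pathway_ante", "A_sept", "His", ct_sa,
               amp = runif1(30, 80), tau = runif1(80, 150),
               erp = min(runif1(320, 400), r01(tcl - 45)),
               erp_retro = runif1(420, 480))
    slow <- el("slow_pathway", "A_cs_prox", "His", ct_sr,
               amp = runif1(30, 80), tau = runif1(80, 150),
               erp = runif1(200, 280))
    eaas <- "CS_PROX"
  }

  elements <- dplyr::bind_rows(
    el("myo", "V_apex", "V_ins", d_myo),
    el("hv", "His", "V_ins", hv),
    fast, slow, atr
  )
  list(nodes = base_nodes(), elements = elements,
       d = r01(d_myo + hv), eaas = eaas, tcl_nominal = tcl)
}

build_ort <- function(subtype) {
  atr <- atrial_elements()
  d_myo <- runif1(30, 90)
  hv <- runif1(25, 40)
  ap_ct <- runif1(30, 80)
  ap_erp <- runif1(200, 240)
  node_ct <- runif1(90, 130)
  tcl_target <- runif1(350, 430)
  erp_jitter <- runif1(0, 25)

  a_ap <- if (subtype == "ORT_FREE_WALL") "A_cs_dist" else "A_cs_prox"
  atrpath <- if (subtype == "ORT_FREE_WALL") {
    ct_of(atr, "csp_csd") + ct_of(atr, "sept_csp")
  } else ct_of(atr, "sept_csp")

  # Every S1 drive beat conducts retrogradely through the AV node and its
  # concealed exit resets the node's atrial end. The induction wavefront
  # (ventricle -> accessory pathway -> atrium) must therefore reach the
  # node's atrial end at least the node ERP after that concealed exit: the
  # intramyocardial path to the pathway insertion (`pad`) is kept long
  # enough that the orthodromic arrival trails the nodal route by >= 40 ms
  # beyond the ERP at every coupling inside the block window.
  pad_raw <- r01(tcl_target - ap_ct - atrpath - hv - node_ct)
  pad_min <- r01(40 + hv + node_ct + 10 - ap_ct - atrpath)
  pad <- max(pad_raw, pad_min)
  tcl <- ap_ct + atrpath + node_ct + hv + pad
  node_erp <- r01(min(ap_erp + 40 + erp_jitter, tcl - 45))

  elements <- dplyr::bind_rows(
    el("myo", "V_apex", "V_ins", d_myo),
    el("hv", "His", "V_ins", hv),
    el("vpad", "V_ins", "V_ins2", pad),
    el("accessory_pathway", a_ap, "V_ins2", ap_ct, erp = ap_erp),
    el("av_node", "A_sept", "His", node_ct, amp = runif1(40, 90),
       tau = runif1(80, 150), erp = node_erp),
    atr
  )
  list(nodes = base_nodes(), elements = elements,
       d = d_myo, eaas = if (subtype == "ORT_FREE_WALL") "CS_DIST" else "CS_PROX",
       tcl_nominal = tcl)
}

build_at <- function() {
  atr <- atrial_elements()
  d_myo <- runif1(5, 50)
  hv <- runif1(25, 40)
  # Retrograde nodal conduction must stay 1:1 well below the fast-limb ERP
  # even after its decremental stretch of the delivered coupling, so the AT
  # node is given a shorter ERP and a milder decrement than the reentrant
  # substrates.
  node_ct <- runif1(60, 110)
  node_erp <- runif1(230, 260)
  entry_ct <- runif1(15, 30)
  # A short fast limb and a slow-zone entrance ERP comfortably above twice
  # the fast-limb conduction time keep a conducted antidromic wavefront from
  # chasing down and annihilating its own orthodromic wavefront: the
  # antidromic branch reaches the far end of the ring while the slow-zone
  # entrance there is still refractory from the previous cycle.
  fast_ct <- runif1(60, 75)
  atcl <- runif1(380, 470)
  slow_ct <- r01(atcl - fast_ct)
  # The fast-limb ERP lies between the premature couplings that start the
  # rotation (which must block antidromically: unidirectional block) and the
  # loop cycle length (the rotation itself must conduct at coupling = ATCL,
  # and 1:1 entrainment at ATCL minus the small overdrive offset). The band
  # is placed so that some burst cycle length both blocks the fast limb and
  # keeps the ring entrained (loop cycle length within 130 ms of the train):
  # every AT substrate is burst-inducible.
  fast_erp <- if (atcl > 425) runif1(395, atcl - 30) else runif1(345, atcl - 30)

  elements <- dplyr::bind_rows(
    el("myo", "V_apex", "V_ins", d_myo),
    el("hv", "His", "V_ins", hv),
    el("av_node", "A_sept", "His", node_ct, amp = runif1(30, 55),
       tau = runif1(80, 120), erp = node_erp),
    el("hra_loop", "A_hra", "AT_loop_entry", entry_ct),
    el("slow_zone", "AT_loop_entry", "AT_loop_exit", slow_ct,
       amp = runif1(10, 40), tau = runif1(80, 150), erp = runif1(190, 220)),
    el("fast_limb", "AT_loop_entry", "AT_loop_exit", fast_ct, erp = fast_erp),
    atr
  )
  list(nodes = base_nodes(c("AT_loop_entry", "AT_loop_exit")),
       elements = elements,
       d = NA_real_, eaas = "HRA", tcl_nominal = atcl)
}

#' @export
print.svt_circuit <- function(x, ...) {
  cat(sprintf("<svt_circuit %s (%s), seed %s>\n", x$mechanism, x$subtype,
              format(x$seed)))
  cat(sprintf("  nominal TCL %.1f ms, d %s ms, EAAS %s%s\n", x$tcl_nominal,
              format(x$d), x$eaas,
              if (isTRUE(x$decrement_free)) ", decrement-free" else ""))
  cat(sprintf("  %d nodes, %d elements\n", nrow(x$nodes), nrow(x$elements)))
  invisible(x)
}

#' Describe a pacing protocol
#'
#' @param mode `"BURST"` (trains at decreasing cycle length), `"EXTRASTIM"`
#'   (S1 drive train plus a single decrementing S2), `"VOP"` (ventricular
#'   overdrive pacing of a running tachycardia) or `"STUDY"` (burst sweep
#'   followed by extrastimulation, as in [run_induction_study()]).
#' @param burst_cl_sequence Burst train cycle lengths in ms.
#' @param burst_beats Beats per burst train.
#' @param s1_cl,s1_count Drive-train cycle length and beat count.
#' @param s2_start,s2_step,s2_floor Extrastimulus coupling sweep (ms).
#' @param vop_cl_offset How far below the TCL the overdrive cycle length
#'   sits (ms).
#' @param vop_beats Number of overdrive stimuli; long enough for the paced
#'   wavefronts to capture the circuit and show at least 8 consecutive
#'   atrial cycles at the pacing cycle length before cessation.
#' @return A list of class `pacing_protocol`.
#' @export
pacing_protocol <- function(mode = c("STUDY", "BURST", "EXTRASTIM", "VOP"),
                            burst_cl_sequence = seq(600, 300, by = -50),
                            burst_beats = 10,
                            s1_cl = 600, s1_count = 8,
                            s2_start = 500, s2_step = 10, s2_floor = 200,
                            vop_cl_offset = 20, vop_beats = 35) {
  mode <- match.arg(mode)
  stopifnot(all(burst_cl_sequence > 0), s1_cl > 0, s2_step > 0,
            s2_floor > 0, vop_cl_offset > 0)
  structure(list(mode = mode, burst_cl_sequence = burst_cl_sequence,
                 burst_beats = burst_beats, s1_cl = s1_cl, s1_count = s1_count,
                 s2_start = s2_start, s2_step = s2_step, s2_floor = s2_floor,
                 vop_cl_offset = vop_cl_offset, vop_beats = vop_beats),
            class = "pacing_protocol")
}

# ---- engine ----------------------------------------------------------------

new_engine <- function(model) {
  E <- new.env(parent = emptyenv())
  nd <- model$nodes
  elts <- model$elements
  E$node_name <- nd$name
  E$node_ch <- nd$channel
  E$node_kind <- nd$kind
  E$node_rp <- nd$refractory
  E$node_last <- rep(-1e9, nrow(nd))
  E$e_name <- elts$name
  E$e_n1 <- match(elts$n1, nd$name)
  E$e_n2 <- match(elts$n2, nd$name)
  E$e_ct <- elts$ct_base
  E$e_amp <- elts$decrement_amp
  E$e_tau <- elts$recovery_tau
  E$e_erp12 <- elts$erp        # entry at n1, conducting toward n2
  E$e_erp21 <- elts$erp_retro  # entry at n2, conducting toward n1
  # Per-end recovery clocks: the tissue at an element end depolarizes when a
  # wavefront enters there or exits there; ERP gates entry against the entry
  # end's clock. A retrograde penetration therefore resets the far (exit)
  # end too -- this is AV-nodal concealment.
  E$e_last1 <- rep(-1e9, nrow(elts))
  E$e_last2 <- rep(-1e9, nrow(elts))
  E$fl_active <- rep(FALSE, nrow(elts))
  E$fl_dir12 <- rep(NA, nrow(elts))
  E$fl_exit <- rep(0, nrow(elts))
  E$fl_qid <- rep(0L, nrow(elts))
  E$incident <- lapply(seq_len(nrow(nd)), function(i) {
    which(E$e_n1 == i | E$e_n2 == i)
  })
  E$apex <- match("V_apex", nd$name)
  cap <- 4096L
  E$q_t <- numeric(cap); E$q_node <- integer(cap); E$q_via <- integer(cap)
  E$q_stim <- logical(cap); E$q_active <- logical(cap)
  E$q_n <- 0L
  ecap <- 4096L
  E$ev_t <- numeric(ecap); E$ev_node <- integer(ecap); E$ev_stim <- logical(ecap)
  E$ev_n <- 0L
  E$stim_times <- numeric(0)
  E
}

q_push <- function(E, t, node, via, stim = FALSE) {
  n <- E$q_n + 1L
  if (n > length(E$q_t)) {
    grow <- function(x) c(x, vector(typeof(x), length(x)))
    E$q_t <- grow(E$q_t); E$q_node <- grow(E$q_node); E$q_via <- grow(E$q_via)
    E$q_stim <- grow(E$q_stim); E$q_active <- grow(E$q_active)
  }
  E$q_t[n] <- t; E$q_node[n] <- node; E$q_via[n] <- via
  E$q_stim[n] <- stim; E$q_active[n] <- TRUE
  E$q_n <- n
  n
}

q_compact <- function(E) {
  keep <- which(E$q_active[seq_len(E$q_n)])
  remap <- integer(E$q_n); remap[keep] <- seq_along(keep)
  E$q_t <- E$q_t[keep]; E$q_node <- E$q_node[keep]; E$q_via <- E$q_via[keep]
  E$q_stim <- E$q_stim[keep]; E$q_active <- rep(TRUE, length(keep))
  E$q_n <- length(keep)
  live <- which(E$fl_active & E$fl_qid > 0L)
  E$fl_qid[live] <- remap[E$fl_qid[live]]
  invisible(E)
}

emit <- function(E, t, node, stim) {
  n <- E$ev_n + 1L
  if (n > length(E$ev_t)) {
    E$ev_t <- c(E$ev_t, numeric(length(E$ev_t)))
    E$ev_node <- c(E$ev_node, integer(length(E$ev_node)))
    E$ev_stim <- c(E$ev_stim, logical(length(E$ev_stim)))
  }
  E$ev_t[n] <- t; E$ev_node[n] <- node; E$ev_stim[n] <- stim
  E$ev_n <- n
}

activate <- function(E, t, node, via, stim) {
  if (t - E$node_last[node] < E$node_rp[node]) {
    return(invisible(FALSE))  # annihilated in refractory tissue
  }
  E$node_last[node] <- t
  if (!is.na(E$node_ch[node]) || stim) emit(E, t, node, stim)
  if (stim) E$stim_times <- c(E$stim_times, t)
  for (f in E$incident[[node]]) {
    if (f == via) next
    from_n1 <- E$e_n1[f] == node
    ci <- t - (if (from_n1) E$e_last1[f] else E$e_last2[f])
    erp <- if (from_n1) E$e_erp12[f] else E$e_erp21[f]
    if (ci < erp) next  # entrance refractory: no penetration, no reset
    if (E$fl_active[f]) {
      if (E$fl_dir12[f] != from_n1 && E$fl_exit[f] > t) {
        # head-on collision inside the element: both wavefronts die
        E$q_active[E$fl_qid[f]] <- FALSE
        E$fl_active[f] <- FALSE
        if (from_n1) E$e_last1[f] <- t else E$e_last2[f] <- t
      }
      next  # same-direction in-flight: tissue occupied, no re-entry
    }
    ct <- r01(E$e_ct[f] + E$e_amp[f] * exp(-(ci - erp) / E$e_tau[f]))
    if (from_n1) E$e_last1[f] <- t else E$e_last2[f] <- t
    dest <- if (from_n1) E$e_n2[f] else E$e_n1[f]
    qid <- q_push(E, t + ct, dest, f)
    E$fl_active[f] <- TRUE; E$fl_dir12[f] <- from_n1
    E$fl_exit[f] <- t + ct; E$fl_qid[f] <- qid
  }
  invisible(TRUE)
}

engine_advance <- function(E, stim_times, t_end) {
  for (s in stim_times) q_push(E, s, E$apex, 0L, stim = TRUE)
  repeat {
    idx <- which(E$q_active[seq_len(E$q_n)])
    if (length(idx) == 0) break
    j <- idx[order(E$q_t[idx], E$q_node[idx])[1]]
    t <- E$q_t[j]
    if (t > t_end) break
    E$q_active[j] <- FALSE
    via <- E$q_via[j]
    if (via > 0L && E$fl_qid[via] == j) {
      E$fl_active[via] <- FALSE
      # the wavefront depolarizes the element's exit end as it leaves
      if (E$fl_dir12[via]) E$e_last2[via] <- t else E$e_last1[via] <- t
    }
    activate(E, t, E$q_node[j], via, E$q_stim[j])
    if (E$q_n > 4000L) q_compact(E)
  }
  invisible(E)
}

engine_series <- function(E, model, meta) {
  n <- E$ev_n
  idx <- seq_len(n)
  node <- E$ev_node[idx]
  stim <- E$ev_stim[idx]
  egm_series(tibble::tibble(
    time_ms = r01(E$ev_t[idx]),
    channel = ifelse(stim, "RVA", E$node_ch[node]),
    kind = ifelse(stim, "STIM", E$node_kind[node]),
    origin = ifelse(stim, "PACED", "CONDUCTED")
  ), meta = meta)
}

apex_v_after <- function(E, t) {
  sum(!E$ev_stim[seq_len(E$ev_n)] &
        E$ev_node[seq_len(E$ev_n)] == E$apex &
        E$ev_t[seq_len(E$ev_n)] > t)
}

attempt_stims <- function(protocol, mode, cl) {
  if (mode == "BURST") {
    100 + cl * (0:(protocol$burst_beats - 1))
  } else {
    s1s <- 100 + protocol$s1_cl * (0:(protocol$s1_count - 1))
    c(s1s, max(s1s) + cl)
  }
}

atrial_cycle_starts <- function(E, from, to, gap = 100) {
  sel <- seq_len(E$ev_n)
  a_nodes <- which(E$node_kind == "A")
  at <- sort(E$ev_t[sel][!E$ev_stim[sel] & E$ev_node[sel] %in% a_nodes &
                           E$ev_t[sel] > from - 200 & E$ev_t[sel] < to + 200])
  if (length(at) == 0) return(numeric(0))
  starts <- at[!duplicated(cumsum(c(1, diff(at) > gap)))]
  starts[starts > from & starts <= to]
}

# One induction attempt on a fresh engine. A burst attempt counts only if
# the atrium was cleanly entrained at the pacing cycle length over the last
# train beats (the clinical requirement of a consistent atrial sequence
# without pacing-tachycardia dissociation): a tachycardia that ignites
# mid-train and dissociates from the stimuli is discarded, exactly as such
# inductions were excluded from analysis in the laboratory.
run_attempt <- function(model, protocol, mode, cl) {
  E <- new_engine(model)
  stims <- attempt_stims(protocol, mode, cl)
  t_last <- max(stims)
  engine_advance(E, stims, t_last + 33 * model$tcl_nominal + 1500)
  last <- if (length(E$stim_times) > 0) max(E$stim_times) else t_last
  induced <- apex_v_after(E, last) >= 30
  clean <- TRUE
  if (induced && mode == "BURST") {
    a <- atrial_cycle_starts(E, min(stims) + 1.5 * cl, t_last + 0.6 * cl)
    clean <- length(a) >= 5 && all(abs(diff(a) - cl) <= 2)
  }
  list(E = E, induced = induced && clean, last_stim = last)
}

run_induction_core <- function(model, protocol) {
  modes <- switch(protocol$mode,
                  STUDY = c("BURST", "EXTRASTIM"),
                  BURST = "BURST", EXTRASTIM = "EXTRASTIM")
  for (mode in modes) {
    cls <- if (mode == "BURST") {
      protocol$burst_cl_sequence
    } else {
      seq(protocol$s2_start, protocol$s2_floor, by = -protocol$s2_step)
    }
    for (cl in cls) {
      res <- run_attempt(model, protocol, mode, cl)
      if (res$induced) {
        return(list(E = res$E, induced = TRUE, mode = mode, cl = cl,
                    last_stim = res$last_stim))
      }
    }
  }
  list(E = new_engine(model), induced = FALSE, mode = NA_character_,
       cl = NA_real_, last_stim = NA_real_)
}

base_meta <- function(model, ind) {
  list(mechanism = model$mechanism, subtype = model$subtype,
       seed = model$seed, tcl_nominal = model$tcl_nominal,
       d = model$d, eaas = model$eaas,
       induced = ind$induced, inducing_mode = ind$mode,
       inducing_cl = ind$cl, induction_train_end = ind$last_stim,
       not_inducible = !ind$induced)
}

#' Simulate an SVT substrate under a pacing protocol
#'
#' Event-driven propagation over the substrate graph honouring per-element
#' refractoriness, wavefront collision and AV-nodal concealment. Propagation
#' is fully deterministic: identical `(model, protocol)` inputs give
#' identical event series (all randomness is confined to [make_model()]).
#'
#' @param model An `svt_circuit` from [make_model()].
#' @param protocol A [pacing_protocol()]. `"STUDY"` runs the burst sweep
#'   then extrastimulation; `"VOP"` first induces the tachycardia with the
#'   study protocol and then performs overdrive pacing.
#' @param max_time Unused guard kept for interface stability.
#' @param seed Ignored (propagation is deterministic); accepted so callers
#'   can thread one seed through a whole pipeline.
#' @return An `egm_series` whose metadata records the mechanism, whether the
#'   tachycardia was induced (`induced`, with `not_inducible` set when the
#'   full protocol sweep fails), the inducing mode and cycle length, and the
#'   time of the last stimulus of the inducing train
#'   (`induction_train_end`).
#' @export
simulate_svt <- function(model, protocol = pacing_protocol(), max_time = 6e4,
                         seed = NULL) {
  stopifnot(inherits(model, "svt_circuit"), inherits(protocol, "pacing_protocol"))
  if (protocol$mode == "VOP") {
    return(run_vop(model, run_induction_study(model), protocol = protocol))
  }
  ind <- run_induction_core(model, protocol)
  engine_series(ind$E, model, base_meta(model, ind))
}

#' Run the full induction study on a substrate
#'
#' Executes ventricular burst pacing (600 down to 300 ms) and then
#' programmed extrastimulation (8 x 600 ms drive, S2 decrementing by 10 ms)
#' until a sustained tachycardia is induced. Because propagation is
#' deterministic, a successful attempt reproduces identically on repetition,
#' which satisfies the two-attempt reproducible-induction requirement by
#' construction.
#'
#' @inheritParams simulate_svt
#' @param protocol A `"STUDY"`-mode [pacing_protocol()].
#' @return An `egm_series`; `egm_meta(series)$induced` reports success and
#'   `not_inducible` is set when no protocol step induces.
#' @export
run_induction_study <- function(model, seed = NULL,
                                protocol = pacing_protocol("STUDY")) {
  p <- protocol; p$mode <- "STUDY"
  ind <- run_induction_core(model, p)
  engine_series(ind$E, model, base_meta(model, ind))
}

stable_tcl_from_engine <- function(E, after) {
  idx <- which(!E$ev_stim[seq_len(E$ev_n)] &
                 E$ev_node[seq_len(E$ev_n)] == E$apex &
                 E$ev_t[seq_len(E$ev_n)] > after)
  vt <- sort(E$ev_t[idx])
  if (length(vt) < 15) return(NA_real_)
  stats::median(diff(vt)[10:14])
}

#' Entrain a running tachycardia by ventricular overdrive pacing
#'
#' Re-simulates the induction recorded in `running` (propagation is
#' deterministic, so the replay is exact), measures the stable tachycardia
#' cycle length, then paces the ventricle at `TCL - vop_cl_offset` ms and
#' records the post-pacing response. Entrainment is accepted when the last
#' 8 atrial cycles on the earliest-activation channel before cessation equal
#' the pacing cycle length; termination is flagged when fewer than 10
#' conducted ventricular beats follow cessation.
#'
#' @inheritParams simulate_svt
#' @param running The series returned by [run_induction_study()] for the
#'   same model; must contain a sustained induced tachycardia.
#' @return The concatenated `egm_series` (induction plus overdrive and
#'   post-pacing segments); metadata gains `vop_pcl`, `vop_first_stim`,
#'   `vop_train_end`, `entrained` and `terminated`.
#' @export
run_vop <- function(model, running, seed = NULL,
                    protocol = pacing_protocol("STUDY")) {
  stopifnot(inherits(model, "svt_circuit"), inherits(running, "egm_series"))
  meta <- egm_meta(running)
  if (!isTRUE(as.logical(meta$induced))) {
    stop("running series does not contain an induced tachycardia", call. = FALSE)
  }
  # Replay the successful attempt exactly (propagation is deterministic).
  res <- run_attempt(model, protocol, meta$inducing_mode,
                     as.numeric(meta$inducing_cl))
  if (!res$induced) stop("could not replay the inducing attempt", call. = FALSE)
  E <- res$E
  ind <- list(induced = TRUE, mode = meta$inducing_mode,
              cl = as.numeric(meta$inducing_cl), last_stim = res$last_stim)
  tcl <- stable_tcl_from_engine(E, ind$last_stim)
  if (!is.finite(tcl)) stop("could not measure a stable TCL before VOP",
                            call. = FALSE)
  pcl <- r01(tcl - protocol$vop_cl_offset)
  t0 <- max(E$ev_t[seq_len(E$ev_n)]) + pcl
  stims <- t0 + pcl * (0:(protocol$vop_beats - 1))
  engine_advance(E, stims, max(stims) + 33 * model$tcl_nominal + 1500)
  vop_stims <- E$stim_times[E$stim_times >= t0 - MS_TOL]
  last_vop <- max(vop_stims)

  a_nodes <- which(E$node_ch == model$eaas & E$node_kind == "A")
  sel <- seq_len(E$ev_n)
  a_t <- sort(E$ev_t[sel][!E$ev_stim[sel] & E$ev_node[sel] %in% a_nodes &
                            E$ev_t[sel] > t0 - pcl & E$ev_t[sel] <= last_vop + pcl])
  entrained <- length(a_t) >= 9 &&
    all(abs(utils::tail(diff(a_t), 8) - pcl) <= 1)
  terminated <- apex_v_after(E, last_vop) < 10

  meta2 <- base_meta(model, ind)
  meta2$vop_pcl <- pcl
  meta2$vop_first_stim <- min(vop_stims)
  meta2$vop_train_end <- last_vop
  meta2$entrained <- entrained
  meta2$terminated <- terminated
  engine_series(E, model, meta2)
}
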