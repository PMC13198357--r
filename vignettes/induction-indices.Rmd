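---
title: "Induction indices during ventricular pacing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Induction indices during ventricular pacing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svtindices)
```

## The problem

Ventricular overdrive pacing (VOP) of a running supraventricular
tachycardia (SVT) is the workhorse of differential diagnosis: the atrial
response on cessation (V-A-V vs V-A-A-V) separates atrial tachycardia
(AT) from the reentrant AV mechanisms, and the postpacing interval minus
tachycardia cycle length (PPI − TCL) — the time the last paced wavefront
spends travelling from the pacing site into the circuit, once around, and
back — separates orthodromic reciprocating tachycardia (ORT, whose
circuit includes the paced ventricle) from AV-nodal reentrant tachycardia
(AVNRT, whose circuit does not). When the tachycardia will not sustain
long enough to entrain, the same physiology is visible at *induction* by
ventricular pacing: the wavefront of the last inducing stimulus also runs
pacing site → circuit → one rotation → ventricle. This package provides
the machinery to study those induction indices: a mechanistic conduction
simulator, the measurement layer, the diagnostic rules, a calibrated
cohort generator, and the statistical evaluation stage.

## The conduction model

A substrate is a small graph of conduction elements between named nodes
(ventricular apex, His bundle, septal/high-right-atrial/coronary-sinus
atrial sites, and for AT a two-node atrial ring). Each element carries

* a base conduction time `ct_base` (ms),
* a recovery-dependent decremental delay: for a local coupling interval
  `ci` the conduction time is
  `CT(ci) = ct_base + decrement_amp · exp(−(ci − erp)/recovery_tau)`,
* an effective refractory period `erp` (ms): entry with `ci < erp`
  blocks. The ERP may differ by direction (`erp_retro`), which is how
  pathways with poor retrograde conduction are expressed.

Propagation is a strict time-ordered discrete-event queue. The rules, in
order of application at each element entry:

1. **Entrance refractoriness.** The coupling interval is measured against
   the recovery clock of the *entry end* of the element. Each end's clock
   is reset when a wavefront enters there or exits there — so a
   retrograde penetration that crosses an AV-nodal pathway resets the
   atrial end as well. This is concealment: the next antegrade beat sees
   a shortened local coupling and conducts with decremental delay or
   blocks. Blocked entries do not reset anything.
2. **Occupancy.** An element carrying a same-direction wavefront cannot
   be re-entered.
3. **Collision.** Entry against an opposite-direction in-flight wavefront
   annihilates both.

Nodes (junctions) have a uniform 130 ms refractory period, which both
annihilates late arrivals harmlessly (e.g. the circuit wavefront
returning 20 ms after the next paced reset) and enforces physiologic
annotation spacing. All conduction times are rounded to the 0.1 ms grid
on which event tables are serialized; interval comparisons use an
absolute tolerance of 0.05 ms.

### Substrates

* **ORT** — loop: ventricular insertion → accessory pathway (fast,
  non-decremental, ERP ≈ 200–240 ms) → atrium → AV node (decremental,
  ERP placed ≥ 40 ms above the pathway's effective ventricular-side ERP
  and ≥ 45 ms below the TCL) → His → back to the ventricular insertion.
  The pacing site connects through a myocardial delay `d` (30–90 ms;
  free-wall pathways lie farther than septal ones). A premature stimulus
  in the window between the two ERPs blocks retrogradely in the node,
  traverses the pathway, and re-enters antegradely: unidirectional block
  followed by reentry.
* **AVNRT** — fast (short `ct`, long antegrade ERP) and slow (long `ct`,
  short ERP, strongly decremental) nodal pathways joined by the
  peri-nodal atrium; the ventricle is a bystander reached through the
  His–Purkinje axis, so the extra-circuit time `d` is long (≈ 60–97 ms
  one way) and the postpacing differences sit above the ORT cutoffs.
  Ventricular induction requires a coupling that blocks in one limb and
  conducts up the other; with a single ERP per pathway and the slow ERP
  below the fast ERP, pacing could only ever initiate the rotation with
  a retrograde slow limb. Substrates whose sustained rotation is
  slow–fast therefore carry a direction-specific ERP (high retrograde
  ERP on the slow pathway), and fast–slow/slow–slow substrates carry a
  high retrograde ERP on their antegrade limb. Both choices reflect the
  clinical observation that the non-participating direction of a limb is
  commonly a poor retrograde conductor, and both leave the stated
  antegrade ERP ordering (slow below fast) intact.
* **AT** — a two-limb atrial ring (slow-conduction zone plus a short fast
  limb) reached from the ventricle only through the AV node. The
  fast-limb ERP lies between the burst couplings that must block it
  (unidirectional block) and the ring cycle length (355–470 ms), and the
  AT node has a shorter ERP and milder decrement than the reentrant
  substrates so that retrograde 1:1 conduction survives the decremental
  stretch of the delivered coupling. After the last entrained beat the
  ring completes its rotation before the AV node (reset by the
  retrograde penetration) can carry an atrial beat down: the entrained A
  is followed by a second, circuit A and only then by a ventricular beat
  — the V-A-A-V signature.

All randomness lives in `make_model()` (uniform draws from the ranges in
`model_ranges()`); propagation is fully deterministic, so identical
inputs give identical event series and a successful induction replays
exactly.

### Pacing protocols and what counts as induction

`run_induction_study()` sweeps burst trains (600 → 300 ms in 50 ms
steps, 10 beats) and then programmed extrastimulation (8 × 600 ms drive,
S2 from 500 ms decrementing by 10 ms to 200 ms). Each attempt runs on
quiescent tissue. An attempt counts as induction when at least 30
conducted ventricular beats follow the last capturing stimulus *and*, for
burst attempts, the atrium was cleanly entrained at the pacing cycle
length over the train's last beats. The second condition mirrors the
clinical inclusion requirement of a consistent atrial sequence without
pacing–tachycardia dissociation: a circuit that ignites mid-train and
free-runs against the stimuli yields an uninterpretable induction and is
discarded. Whether the tachycardia "began" during the train is
unknowable in principle; this package defines the induction indices on
the first rotation completing after the last capturing stimulus, which
the clean-entrainment requirement makes well-posed.

`run_vop()` paces at TCL − 20 ms (within the conventional 10–40 ms
window) for a fixed 35 beats and verifies entrainment post hoc as 8
consecutive atrial cycles at the pacing cycle length before cessation.
The train is long because capturing a free-running circuit takes up to
roughly TCL/offset beats of phase drift; the 8-cycle criterion itself is
the conventional one. Termination during pacing is flagged, not treated
as an error.

## Measurement conventions

* **TCL** — median of 5 consecutive apical V-V intervals, starting at the
  10th post-induction beat, all within 20 ms (early post-induction
  fluctuation is excluded by design).
* **iPPI / PPI** — last capturing stimulus of the relevant train to the
  first conducted apical V.
* **AH** — atrial to His time on the His channel, for the first induced
  beat, the stable window (mean over its 5 beats), or the first
  post-overdrive beat. Corrected differences subtract
  (AH of the measured beat − stable AH).
* **iVA sequence** — discrete atrial cycles are formed by grouping
  atrial annotations across channels with a 100 ms separation rule
  (intra-cycle activation spread is well under that; successive cycles
  are a TCL apart). Counting starts at the *last entrained* atrial
  activation: when ventriculoatrial conduction is longer than the pacing
  cycle length a wavefront is still in flight at cessation, so the first
  post-pacing A belongs to the penultimate stimulus. The entrained
  prefix is recognized by its spacing continuing the train's rhythm
  (within ±8 ms for uniform trains; up to +95 ms after a premature
  extrastimulus, whose decremental conduction stretches its atrial
  spacing). One cycle from the last entrained A to the return V is
  V-A-V, two are V-A-A-V. An atrial candidate after the His potential
  that precedes the return V is not counted (pseudo-V-A-A-V guard
  against delayed His-region ventricular electrograms).
* **Corrected iPPI − TCL** — computed by the formula
  `iPPI−TCL − (AH_induction − AH_stable)`. In the worked septal-ORT
  example this gives 58 ms from (222, 380, 216); a printed summary of
  that case quotes 86 ms, which is inconsistent with its own printed
  inputs under any beat choice we could reconstruct, so the package
  follows the formula.

## The synthetic cohort

Study-level summaries of the index distributions are available only as
per-mechanism medians and interquartile ranges. `generate_cohort()`
therefore samples each index from a monotone piecewise-cubic (Hyman)
quantile function interpolating five anchors — lower bound, q1, median,
q3, upper bound — which reproduces the published order statistics
exactly without asserting any further shape. Tail bounds default to the
Tukey fences, clipped at −50 ms for difference indices (mildly negative
values are measurement noise) and 250 ms for cycle lengths. Defaults:
10/41/41 cases (AT/AVNRT/ORT); iPPI−TCL 318 (245, 402) / 180 (150, 201)
/ 80 (50, 129) ms; TCL 405 (385, 470) / 390 (354, 433) / 365 (344, 401)
ms; PPI−TCL 165 (150, 180) / 120 (90, 156) ms and corrected PPI−TCL 150
(135, 160) / 90 (61, 100) ms in the AVNRT/ORT arms; SA−VA 144 (120, 165)
/ 71 (56, 100) ms. The corrected *induction* index has no published
summary of its own; given its near-unit rank correlation with the
corrected post-pacing index it reuses that preset — a calibration
choice, not data.

Within a case the two corrected indices share a latent Gaussian-copula
deviate with correlation 0.95, the simplest mechanism consistent with a
rank-based correlation analysis; all other indices draw independently
(their joint distribution is unreported, and independence is an explicit
assumption). Note that the Spearman correlation *within* an arm
converges to 6/π·asin(ρ/2) ≈ 0.945 at ρ = 0.95, while pooling the AVNRT
and ORT arms adds between-arm concordance and pushes the observed
coefficient near 0.98 — the familiar effect of cohort heterogeneity on
pooled correlations.

What the generator does and does not emulate: it matches the
per-mechanism marginals and one dependence, so recovery of medians,
group separation and ROC behaviour transfer to it; it does not model
measurement error correlation across indices, operator variation,
missingness patterns or atypical substrates, so passing tests on the
synthetic cohort demonstrates correctness of the analysis machinery, not
clinical performance on new patients.

### Sampling tolerances

At the study's arm sizes the sample median of a wide arm is genuinely
noisy: for the ORT iPPI−TCL calibration (IQR 79 ms) its asymptotic
standard error at n = 41 is ≈ 12 ms. Recovery tests therefore use the
principled sampling tolerance 2·SE with SE = Q′(0.5)/(2√n) computed from
the calibrated quantile function itself, rather than a fixed band.

## The evaluation stage

Group comparisons use the two-sided Mann–Whitney U test (exact
enumeration for small untied samples, normal approximation with tie
correction otherwise) or the Kruskal–Wallis test; correlation is
Spearman's. The ROC sweep treats every distinct score as an *inclusive*
threshold (score ≤ t calls the positive class), matching the clinical
"≤ cutoff" convention; the AUC is the trapezoidal area, which equals the
normalized Mann–Whitney statistic (pairwise concordance with half-credit
ties) — a property the tests verify exhaustively on all small label
arrangements, including tied scores. The Youden cutoff maximizes
sensitivity + specificity − 1, with ties broken toward the smaller
threshold (a deterministic choice; the convention is not standardized).

## Adjudication

`classify_conventional()` evaluates AT exclusions, AT inclusions, ORT
exclusions, ORT inclusions, and finally AVNRT by double exclusion, in
that order; any exclusion vetoes the corresponding diagnosis regardless
of inclusions, unknown evidence never fires a criterion, and a partial
workup degrades to `INDETERMINATE` rather than guessing. The evaluation
order is itself a design decision — the criteria are published as lists,
not as a decision procedure — and the `fired` audit trail exposes every
criterion that evaluated true so conflicting evidence is visible.
`simulate_case()` fills two flags the simulator cannot produce
(delta-VA after differential atrial overdrive; His capture during
overdrive) from the substrate definition, representing the complete,
error-free workup against which mechanisms are adjudicated in practice.

## Problem sizes and determinism

The shipped tests run 30 randomized circuits (10 per mechanism) through
induction and overdrive, 8 decrement-free circuits for the closed-form
2·d identity, cohorts of 10⁴ per arm for calibration recovery and
2⁸-scale exhaustive enumerations for the ROC oracle — sizes chosen so
the whole suite completes in well under a minute of simulation time
while leaving every law at full strength. The acceptance script
regenerates a 3 × 10⁴-case cohort and a fresh 30-circuit series from a
single seed; one seed fans out to per-stage draws (mechanism-specific
offsets), so adding an arm never perturbs earlier ones.

## Limitations

The simulator is an annotation-level lumped-element model: no waveform
morphology, no spatial wavefront curvature, no bundle-branch-block
dynamics, no isoproterenol pharmacology, no fusion beats. Its substrates
are the typical forms; superior slow-pathway variants, bystander
pathways and double atrial responses are deliberately out of scope (a
V-A-A-V response is therefore AT-specific *within this model*, which is
exactly the idealization the sequence law expresses). The worked-example
recordings are synthetic reconstructions whose annotated intervals match
the printed measurements of representative clinical tracings; they are
labelled synthetic in their metadata.
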