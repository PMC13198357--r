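Package: svtindices
Title: Induction Indices for Supraventricular Tachycardia Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying ventricular-pacing induction indices used to
    differentiate supraventricular tachycardia (SVT) mechanisms in the
    electrophysiology laboratory. Provides a discrete-event simulator of
    atrial tachycardia, AV-nodal reentry and orthodromic reciprocating
    tachycardia under programmed ventricular stimulation and overdrive
    pacing; measurement of the induction ventriculoatrial sequence, the
    induction postpacing interval (iPPI) and its AH-corrected difference
    from the tachycardia cycle length alongside conventional entrainment
    indices; rule-based diagnostic adjudication; a quantile-calibrated
    synthetic cohort generator; and the nonparametric evaluation stage
    (Mann-Whitney and Kruskal-Wallis comparisons, Spearman correlation,
    ROC curves with Youden cutoffs and 2x2 diagnostic metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
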