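Package: qeegr
Title: Quantitative EEG Recovery Analysis After Cardiac Arrest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of early post-resuscitation quantitative
    EEG in the rodent asphyxial cardiac-arrest model. Generates seeded synthetic
    two-channel EEG cohorts with planted recovery dynamics (isoelectric,
    burst-suppression and continuous-background phases), preprocesses recordings
    (zero-phase band-pass and mains notch filtering, scheduled one-minute
    segment extraction with artifact screening), operationalizes amplitude-based
    pattern annotation into an envelope classifier yielding onset time of burst
    (OTOB) and time to normal trace (TTNT), computes per-segment
    burst-suppression ratio (BSR) and weighted-permutation entropy (WPE) with
    time-weighted averages, and runs the outcome statistics battery
    (normality-gated group comparison, Spearman correlation with Fisher-z
    confidence intervals, ROC/AUC with bootstrap confidence intervals, and
    Kaplan-Meier survival with log-rank tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    survival,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
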