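Package: fmsapa
Title: Anticipatory Postural Adjustment Quantification for an
    fMRI-Compatible Force Measurement System
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation, acquisition-loop emulation and quantification of
    anticipatory postural adjustments (APAs) recorded by an MRI-compatible
    foot-force measurement system and by a conventional force platform
    during step initiation.  Provides an event-related paradigm generator
    with Poisson-grid stimulus durations, a synthetic-trial simulator for
    supine leg raises (32 Hz foot sensors) and upright step initiation
    (force platform plus malleolus marker), the real-time force-drop
    trigger rule, threshold-crossing APA onset detection, amplitude
    (N/cm) and force-magnitude (percent of whole-curve integral)
    statistics, head-motion quality control against a 1 mm criterion, and
    exact small-sample nonparametric tests (Wilcoxon signed-rank,
    Mann-Whitney U, Spearman rank correlation) by enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    pracma,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
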