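Package: qhtsflow
Title: Quantitative High-Throughput Screening Triage and Downstream
    Pharmacology Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative high-throughput screening (qHTS) of
    enzyme inhibitors with a coupled fluorescence readout: synthetic
    1536-well screen generation with planted ground truth, plate quality
    control (Z-prime, signal/background, positional effects),
    four-parameter logistic dose-response fitting with curve-response-class
    (CRC) scoring, a multi-stage hit-triage cascade with counter-screen and
    differential rescue, Michaelis-Menten and global inhibition-mode
    kinetics, non-compartmental pharmacokinetics (Cmax, Tmax, lambda-z,
    AUC), and downstream extracellular-vesicle and cytokine biomarker
    statistics (percent reduction, delta-delta-Ct, ANOVA with Tukey HSD).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
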