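Package: sipbench
Title: Simulation and Benchmarking of DNA Stable Isotope Probing Experiments
Version: 0.1.0
Authors@R:
    person("Sam", "Keller", email = "sam.keller@example.org", role = c("aut", "cre"))
Description: Physics-based simulation of genomic DNA buoyant-density
    distributions in isopycnic CsCl gradients, gradient fractionation,
    amplicon sequencing and qPCR, together with the statistical methods
    used to detect and quantify isotope incorporators in DNA stable
    isotope probing (DNA-SIP) experiments: presence-based Heavy-SIP,
    HR-SIP and multi-window HR-SIP (negative-binomial differential
    abundance in heavy buoyant-density windows), qSIP (qPCR-scaled
    weighted-mean buoyant-density shifts with bootstrap confidence
    intervals) and delta-BD (center-of-mass shifts).  Includes a
    synthetic genome generator, an end-to-end experiment simulator and
    an accuracy-evaluation harness (specificity, sensitivity, balanced
    accuracy) for benchmarking detection methods against simulation
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
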