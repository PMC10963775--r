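Package: passfec
Title: Surprisal Analysis, PaSSS Barcodes and Free-Energy Biomarkers for
    Transcriptome State Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes bulk gene-expression matrices into an invariant
    steady state plus sample-specific unbalanced processes by surprisal
    analysis (SVD of the log-expression matrix), derives ternary
    patient-specific signaling-signature (PaSSS) barcodes and a per-sample
    free-energy-change (FEC) statistic, and places each sample in a
    one-dimensional transcriptome state-space governed by a quartic
    double-well quasi-potential with critical points for the normal,
    unstable transition and leukemic states. Includes mutual-information
    feature selection for the state-space, k-means/Boltzmann-ratio
    estimation of the critical points, Langevin and Fokker-Planck engines
    for the state-transition dynamics, and a synthetic-cohort generator
    with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
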