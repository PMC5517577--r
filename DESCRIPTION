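Package: sleepstates
Title: Unsupervised Sleep Staging from Dynamic BOLD Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies wakefulness and NREM/REM sleep states from dynamic
    BOLD functional connectivity without EEG. Windowed region-by-region
    correlation matrices are clustered with k-means under correlation
    distance into dynamic connectivity states, matched to sleep stages by
    occurrence-profile and matrix-similarity criteria, and scored against
    hypnogram ground truth (volume-level accuracy, bootstrap distributions,
    label-permutation nulls, window-length and sample-size sweeps). Includes
    stage-wise network characterization (signed weighted modularity with
    Louvain maximization, node strength, structure-function coupling,
    FDR-corrected edgewise stage contrasts) and a synthetic cohort generator
    (time-inhomogeneous Markov hypnograms driving stage-switched Gaussian
    BOLD signals) that emulates the statistical structure of EEG-fMRI sleep
    cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
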