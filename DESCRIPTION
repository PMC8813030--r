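Package: dynfc
Title: Static and Dynamic Functional Connectivity Analysis of Component
    Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for static and dynamic functional
    connectivity analysis of independent-component time courses from
    resting-state fMRI. Implements time-course conditioning and motion QC,
    Fisher-z Pearson connectivity, tapered sliding-window connectivity,
    k-means connectivity states with temporal statistics (fraction rate,
    mean dwell time, transitions), per-edge temporal variance,
    sparsity-swept binary graph metrics (small-world properties and
    efficiencies) with area-under-curve summaries and across-window
    variance, and covariate-adjusted group statistics with false discovery
    rate control. A Markov-switching Gaussian cohort generator provides a
    ground-truth test bed so the whole chain is exercisable without scan
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    igraph,
    jsonlite,
    rlang,
    signal,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
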