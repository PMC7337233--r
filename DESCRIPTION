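Package: neuroreplay
Title: Detection of Learned Firing-Sequence Replay in Neural Rest Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Template-matching analysis of memory replay in binned neural
    feature recordings from a brain-controlled sequence task. Builds
    single-target and per-trial spatiotemporal templates from task blocks,
    scans pre- and post-task rest blocks with normalized 2D cross-correlation,
    extracts candidate replay events by non-maximum suppression, and
    quantifies replay via sequenced single-target hit counting (two-proportion
    chi-square) and the Replay Index with time-dilation and centile-threshold
    sweeps, a swapped-control null, and theta-envelope sleep/wake restriction.
    Includes a synthetic-session generator with ground-truth embedded replay
    events for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    signal,
    generics,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
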