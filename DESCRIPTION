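Package: nanoblock
Title: Simulation and Analysis of Peptide Blockade Events in alpha-Hemolysin Nanopore Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-molecule resistive-pulse sensing with the
    alpha-hemolysin protein nanopore. Simulates voltage-clamp ionic current
    traces with Poisson peptide-capture events, exponential residence times
    and two-level intra-event substates; detects and idealizes blockade
    events with hysteresis thresholding; recovers fractional blockades from
    pooled amplitude histograms; estimates association and dissociation rate
    constants by exponential maximum likelihood with exact chi-square
    confidence intervals and fits the exponential voltage dependence of the
    capture rate; and provides a quasi-one-dimensional excluded-volume
    conductance model of the pore (parametric or computed from atomic
    coordinates) together with the Debye screening length of the
    electrolyte.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
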