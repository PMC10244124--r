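Package: odexpand
Title: Confidence-Layered Expansion of Dynamic ODE Models to Phosphoproteome Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for growing a small, trusted ODE model of a signaling
    network into a large mechanistic model of time-resolved phosphoproteomic
    data. Candidate phosphosites adjacent to the model under a prior-knowledge
    interaction graph are attached through small kinetic motifs
    (phosphorylation, dephosphorylation, saturated and dual-input variants,
    and a secondary-state chain), each fitted to replicate time series and
    gated by a chi-squared test on the normalized sum of squared residuals.
    Accepted sites are organised into layers of decreasing confidence,
    followed by a data-driven phase. The package also simulates intervention
    scenarios (kinase-inhibitor clamps, a type-2-diabetes condition),
    estimates prediction uncertainty by constrained min/max optimization,
    and ships a synthetic ground-truth generator so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    parallel,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
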