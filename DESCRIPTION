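Package: sleeposc
Title: Sleep Oscillation Detection, Coupling and Memory Analysis for Rodent LFP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of developmental rodent sleep recordings:
    NREM staging of local field potentials by k-means on delta/theta band
    power, detection of cortical slow oscillations, thalamocortical sleep
    spindles and hippocampal sharp-wave ripples, temporal event coupling with
    a Monte-Carlo permutation null, slow-oscillation phase coupling with
    circular statistics, event-triggered multitaper time-frequency maps with
    cluster-based permutation tests, and object-place-recognition memory
    scoring. Includes a fully seeded synthetic LFP and behavior simulator
    with ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
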