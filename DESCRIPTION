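Package: ppptracer
Title: Carbon-Atom Tracing of Glycolysis and the Pentose Phosphate Pathway
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing 13C stable-isotope tracing experiments on
    glycolysis and the pentose phosphate pathway (PPP). Provides an exact
    carbon-atom-transition simulator for the trehalose/glycolysis/PPP
    network (including cyclic and nonoxidative PPP routes through
    transketolase and transaldolase), natural-abundance correction of
    measured isotopologue intensities by constrained least squares,
    reference-sample peak-area normalization, mass-isotopologue-fraction
    statistics (Welch t tests with Holm-Sidak adjustment), and inference of
    pathway contributions by deconvolving corrected mass isotopologue
    distributions against simulated regime templates. A synthetic LC-HRMS
    data generator with known ground truth makes the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
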