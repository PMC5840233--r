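Package: dareservoir
Title: Driven/Autonomous Spiking Reservoir Networks for Few-Shot Temporal
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and training of driven/autonomous (D/A) recurrent
    spiking reservoir networks for learning temporal classification tasks from
    very few labelled examples. A rate-readout driven network is trained with
    recursive least squares on a delay-apportioned copy of the desired output;
    fully spiking autonomous networks are then derived from it and their
    spiking readouts trained with a supervised spike-timing-dependent
    plasticity rule against one-hot spike targets. Includes a
    microsaccade-inspired video-to-spike encoder (frame differencing, weighted
    multi-threshold fusion, centre-of-gravity bounding-box scans with jitter
    filtering), a five-scan ensemble majority-vote classifier, dynamical
    diagnostics (eigenvalue spectra of the recurrent weight matrices,
    inter/intra-class trajectory distances), and a synthetic moving-object
    video generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    png,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
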