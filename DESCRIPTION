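Package: sealforage
Title: Fine-Scale Foraging Analysis from Head-Mounted Sonar and Motion Tags
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing fine-scale foraging behaviour of diving
    marine predators from head-mounted sonar/motion tags: prey-capture-attempt
    detection from triaxial jerk, echo-to-noise-ratio echogram analysis
    (seafloor detection, prey-trace extraction, reaction classification,
    acoustic size), functional-PCA dive-shape clustering with Gaussian-mixture
    model selection, body-orientation and dead-reckoned track estimation, and
    approach-behaviour summaries. Includes a synthetic-deployment simulator
    that generates fully labelled multi-rate sensor streams and echograms so
    the whole pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    signal,
    geosphere,
    jsonlite
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
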