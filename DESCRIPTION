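Package: cyclicdbs
Title: After-Effect Analysis of Cyclic Deep Brain Stimulation in Sensor-Space MEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for cyclic (ON/OFF) deep brain stimulation
    experiments with simultaneous magnetoencephalography: Morlet
    time-frequency power and intertrial coherence, hemispheric power
    lateralization over mirrored sensor regions of interest,
    baseline-normalized post-train after-effect spectra on the natural
    155 ms segment grid, cluster-level and tmax sign-flip permutation
    statistics, and mixed-model contracts for lateralization and
    finger-tap-rate analyses. Includes a synthetic generator of cyclic-DBS
    sensor recordings and tapping behavior with known ground truth, so
    every stage is verifiable by parameter recovery without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    signal,
    lme4,
    lmerTest,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
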