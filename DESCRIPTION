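Package: ssvepOSP
Title: Hybrid SSVEP and Omitted-Stimulus-Potential Brain-Computer Interface Toolkit
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a four-class hybrid brain-computer interface driven by
    repetitive visual flickers with missing events. Provides a frame-accurate
    stimulus scheduler for flicker trains with omitted periods, a forward-model
    simulator producing event-annotated multichannel EEG (steady-state visually
    evoked potentials plus tri-phasic omitted-stimulus potentials in 1/f noise),
    zero-phase filtering and event-locked epoching, canonical-correlation
    frequency identification, a windowed linear-SVM bank fused by a naive-Bayes
    likelihood ratio for omission-onset recognition, and accuracy/information
    transfer rate evaluation, together with EDF and CSV/JSON/YAML interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, signal, e1071, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'ssvepOSP-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'paradigm.R'
    'synthEEG.R'
    'preprocess.R'
    'cca.R'
    'ospDecoder.R'
    'metrics.R'
    'io.R'
    'workflows.R'
    'publishedResults.R'
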