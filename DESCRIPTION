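Package: vmtypes
Title: Response Types in Intracellular Recordings Under Patterned Tactile Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of intracellular membrane-potential recordings made during
    repeated presentation of spatiotemporal tactile stimulation patterns.
    Provides quality control and artifact handling for whole-cell traces,
    extraction and shape-normalisation of evoked response windows, an
    unsupervised threshold/overshoot clustering of responses into recurring
    response types, per-timepoint Kruskal-Wallis specificity tests with
    label-shuffle controls, PCA plus k-nearest-neighbour decoding of response
    type separability at several scopes, spectral segmentation of the ECoG
    into synchronized and desynchronized cortical states, and template-based
    detection and quantification of evoked excitatory postsynaptic potentials.
    Includes a seeded synthetic-session generator with planted ground truth so
    the whole pipeline can be validated end to end without recorded data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
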