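Package: glycoPGC
Title: Negative-Mode PGC-LC-MS/MS Tissue Membrane Glycomics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of N- and O-glycan alditol profiles measured by porous
    graphitized carbon liquid chromatography with negative-mode electrospray
    ion-trap tandem mass spectrometry. Provides a monosaccharide mass
    calculus for reduced glycans, GlycoMod-style composition enumeration
    from deconvoluted m/z, theoretical B/C/Y/Z/D/F fragment generation with
    diagnostic-ion motif calling (bisecting GlcNAc via the D-221 ion,
    LacdiNAc via its B and F ions, sialyl-linkage isomers), extracted-ion
    chromatogram peak integration with retention-order isomer assignment,
    relative-abundance profiling with glycan-type feature summaries, and a
    group-discrimination statistics layer (rank tests with
    Benjamini-Hochberg adjustment, penalized logistic and random-forest
    feature selection, empirical ROC/AUC, linear discriminant analysis with
    Wilks' lambda). A seeded synthetic-data generator emulates two- and
    three-group tissue cohorts, EIC traces and MS2 spectra so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'masses.R'
    'topology.R'
    'search.R'
    'fragments.R'
    'spectra-io.R'
    'chromatography.R'
    'profiling.R'
    'stats-differential.R'
    'stats-selection.R'
    'stats-roc.R'
    'stats-lda.R'
    'stats-qpcr.R'
    'presets.R'
    'synthetic.R'
    'io.R'
    'pipeline.R'
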