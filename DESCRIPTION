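Package: oplsFusion
Title: Cross-Platform Metabolic Profiling with NMR Bucketing, OPLS-DA and
    NMR/GC-MS Statistical Fusion
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-block metabolic profiling of crude drug extracts.
    Converts 1D 1H-NMR spectra into fixed-width bucket matrices (solvent
    referencing, total-integral normalization, 0.04 ppm binning with water
    exclusion), ingests GC-MS/GC-FID peak tables with internal-standard
    normalization and linear retention indices, and provides from-scratch
    NIPALS implementations of PCA, PLS, OPLS and OPLS-DA with cross-validated
    Q2, permutation-test validation and S-plots. The two blocks are fused
    through an OPLS model into a bucket-by-compound correlation heatmap that
    assigns unidentified NMR signals to chromatographically identified
    compounds, and calibration curves convert peak areas into absolute
    contents. A seeded simulator generates paired two-class cohorts with
    planted marker compounds so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bucketing.R'
    'io-nmr.R'
    'gcms.R'
    'scaling.R'
    'opls.R'
    'validate.R'
    'fusion.R'
    'oplsFusion-package.R'
    'pca.R'
    'quantify.R'
    'synthetic.R'
    'pipeline.R'
    'show-methods.R'
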