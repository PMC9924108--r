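Package: vmatQA
Title: Complexity Metrics and Gamma Passing Rate Prediction for VMAT
    Patient-Specific QA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the modulation complexity of
    volumetric-modulated arc therapy (VMAT) treatment plans and for
    predicting pretreatment-verification gamma passing rates (GPR) from
    those complexity metrics.  Computes per-control-point aperture area,
    perimeter and irregularity from multileaf-collimator and jaw geometry,
    MU-weighted beam- and plan-level aggregates (plan-averaged beam area
    and irregularity), leaf travel per arc length, and mean dose-rate and
    gantry-speed variation.  Provides random-forest and linear
    support-vector regression of GPR with a bounded logit rescaling of the
    target, repeated hold-out evaluation with permutation importance,
    Pearson correlation and one-way ANOVA reporting, percent-error checks
    of expected versus actual delivery parameters, and a synthetic
    VMAT-cohort generator spanning four treatment-site archetypes for
    end-to-end testing without clinical data.  Reads DICOM RT Plan files
    and a plain JSON plan dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'vmatQA-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'machine.R'
    'plan-model.R'
    'plan-io.R'
    'dicom.R'
    'aperture.R'
    'complexity.R'
    'synthetic.R'
    'transform.R'
    'models.R'
    'evaluate.R'
    'delivery-log.R'
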