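Package: visref
Title: Reference Intervals for Clinical Visual Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for establishing, transferring, verifying and monitoring
    reference intervals for clinical physiological measurements such as
    electroretinogram (ERG), visual evoked potential (VEP) and
    electrooculogram (EOG) parameters.  Implements nonparametric
    (order-statistic), parametric (with normalising transforms) and
    subject-level bootstrap estimation of reference limits with 90%
    confidence intervals; explicit strategies for correlated bilateral
    (two-eye) measurements; Tukey-fence, Grubbs and Dixon outlier handling
    with robust location/scale estimation and continuous age compensation;
    partitioning rules for demographic subgroups; transference and
    two-stage verification of externally established intervals;
    repeatability coefficients and delta checks for serial measurements;
    and a simulation engine for bilateral cohorts and Monte-Carlo studies
    of limit uncertainty.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    MASS,
    nortest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
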