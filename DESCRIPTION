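Package: mammoscatter
Title: Monte Carlo Scatter Dosimetry for Mammographic Thyroid Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kilovoltage Monte Carlo photon transport in a stylized female
    voxel phantom for mammography scatter dosimetry: a tungsten-anode
    rhodium-filtered tube spectrum model, Woodcock delta-tracking transport
    with kerma tallies and scatter-provenance tagging, organ doses and
    ICRP 103 effective dose, analytic shielding transmission, a synthetic
    patient cohort generator, and the accompanying statistical analyses
    (paired t-test, one-way ANOVA with Tukey-Kramer contrasts, exponential
    and linear least-squares fits of surface air kerma against compression
    thickness and BMI).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
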