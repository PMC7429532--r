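Package: izbench
Title: Benchmarking Automatic MEG Source Localization of the Epileptic
    Irritative Zone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate automatic magnetoencephalography (MEG) source
    localization of the epileptic irritative zone against expert equivalent
    current dipole (ECD) fitting. Provides an analytic spherical-conductor
    forward model with planar-gradiometer arrays, four inverse procedures
    (nonlinear ECD fitting, an exact and a sequential Monte Carlo Bayesian
    single-dipole posterior map, one-dipole MUSIC subspace scanning, and
    depth-weighted minimum-norm estimation), the discrepancy metrics used to
    compare them (dipole localization discrepancy, map localization
    discrepancy, spatial dispersion, ROC area under the curve), a synthetic
    interictal-spike cohort generator with surgical plans and Engel outcomes,
    and the lobar-concordance analysis that relates localization to
    post-surgical outcome. Bundles the per-patient summary tables of a
    published 22-patient clinical validation study as plain-text fixtures and
    recomputes every downstream statistic of that study from them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
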