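Package: survmap
Title: Survival Path Mapping for Longitudinal Clinical Cohorts
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts irregular longitudinal clinical measurements into
    fixed-interval time slices and recursively bifurcates a cohort at each
    slice through Cox-based feature selection (Kaplan-Meier log-rank
    screening at a slice-corrected significance level, multivariable Cox
    fitting, backward elimination by likelihood-ratio tests, and
    likelihood-drop variable importance).  The result is a cascading
    prognostic tree (a "survival map") with per-slice node medians,
    bifurcation hazard ratios, dynamic concordance-index evaluation against
    comparator staging systems, and treatment-transition contingency
    analysis.  Includes a synthetic longitudinal cohort generator with
    planted prognostic structure, piecewise-exponential event times,
    censoring, and surveillance dropout, so the whole pipeline can be
    exercised and validated without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
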