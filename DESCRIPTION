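Package: mfhrv
Title: Multifractal Spectrum Shape Analysis of Heartbeat RR Tachograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Direct estimation of the Chhabra-Jensen multifractal singularity
    spectrum f(alpha) from heartbeat RR-interval series (tachograms), and its
    reduction to shape statistics that discriminate healthy subjects from
    congestive heart failure (CHF) patients: the spectrum width, the symmetry
    ratio r of the right and left half-widths about the spectrum maximum, and
    the finite-difference curvature profile K(q) with its maximum around q = 0.
    Includes group-level aggregation (skew counts, mean curvature profiles,
    maximum of the average curvature, Welch tests, NYHA stratification), a
    deterministic/randomised multiplicative-cascade generator with closed-form
    analytic spectra for validation, surrogate RR cohorts with healthy-like and
    CHF-like multifractal structure, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'cascade.R'
    'spectrum.R'
    'tachogram-io.R'
    'shape-metrics.R'
    'group-stats.R'
    'cohort.R'
    'cli.R'
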