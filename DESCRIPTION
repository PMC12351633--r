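Package: tesgroup
Title: Group-Level Dose Optimization for Transcranial Electrical Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning transcranial electrical stimulation (tES)
    montages at the group level. Implements the NERNI (normalized error
    relative to no intervention) fitness for the normal component of the
    cortical electric field, constrained quadratic current solving under
    safety limits, genetic-algorithm electrode-subset search for
    single-subject and group-mean objectives, leave-one-out group protocol
    evaluation, cross-subject montage transfer analysis with paired and
    nonparametric statistics, and regression of targeting outcomes on
    scalp-geodesic and tissue-volume anatomical features. A multi-shell
    spherical head model with an analytic forward solution generates
    synthetic cohorts with controllable anatomical and conductivity
    variability for method development and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    igraph,
    quadprog,
    jsonlite,
    yaml,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
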