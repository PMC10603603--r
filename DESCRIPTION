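Package: xltrigger
Title: MS3-Trigger Decision Algorithm for MS-Cleavable Cross-Linkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a four-step MS3-trigger decision algorithm for
    cross-linking mass spectrometry with MS-cleavable cross-linkers such as
    DSSO: isotope-envelope deconvolution with charge assignment, charge-aware
    stub-doublet matching at ppm tolerance, an intensity-rank filter, a
    second-peptide-mass filter, and capped MS3 target selection. Ships peak
    list readers and writers (MGF, mzML via 'mzR'), peptide b/y fragment and
    stub-fragment mass calculation and spectrum annotation, trigger
    sensitivity and specificity evaluation with bootstrap confidence
    intervals, and a seeded synthetic spectrum generator that plants
    cross-link stub doublets, isotope envelopes and noise so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mzR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
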