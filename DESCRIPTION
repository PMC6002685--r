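Package: soaesupp
Title: Contralateral Suppression Analysis of Spontaneous Otoacoustic Emissions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting spontaneous otoacoustic emissions (SOAEs) in
    sealed ear-canal recordings and quantifying their trial-locked suppression
    during contralateral speech stimulation, an index of medial olivocochlear
    efferent activity. Implements short-time Fourier transform peak tracking,
    baseline SOAE identification with stability and line-noise exclusion
    filters, test-ear selection, per-trial suppression measurement, factor
    loading composite scores, and the linear-model and residualization
    analyses relating suppression to cognitive composites and language-group
    membership. Includes a synthetic-cohort generator with known ground truth
    so every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
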