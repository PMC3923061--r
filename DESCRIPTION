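Package: growthexpr
Title: Coupling Gene Expression to Growth Phenotype in Yeast Strain Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for linking transcriptional profiles to growth phenotypes
    across panels of budding-yeast strains grown on contrasting carbon
    sources. Implements probe-level normalization for custom two-colour
    microarrays (replicate medians, Lowess correction of 3'-positional probe
    bias, per-gene median summarization, percentile normalization),
    log-linear growth-rate estimation from optical-density time series,
    gene-group mean-expression profiling with a minimum-strain filter,
    Pearson correlation scans of group expression against phenotypes,
    pentose-phosphate-pathway sign classification, and a synthetic-cohort
    generator with known ground truth for validating every stage end to end.
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
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
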