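Package: saponinbias
Title: Quantifying Host-DNA-Depletion Bias in Shotgun Metagenomic Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess how saponin-based host DNA depletion distorts
    shotgun metagenomic taxonomic profiles. Provides read-filtering
    accounting (percent host reads removed), the taxonomic variation index
    (TVI, an L1 divergence between relative-abundance profiles on the
    percent scale, 0 to 200), lost/gained-taxon reports, fixed-depth
    subsampling comparability checks, Gram-stratified abundance summaries
    with saponin dose-response statistics, compositional log-ratio
    estimation of differential survival rates, and a synthetic
    differential-lysis community simulator used as the test bed for the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
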