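Package: ladco
Title: Differential Lamina-Associated Domain and Pioneer-Factor
    Co-Occupancy Analysis for ChIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for two-condition ChIP-seq comparisons of broad
    lamina-associated domains (LADs) and punctate pioneer-factor binding.
    Provides tag-level preprocessing (deduplication, downsampling, fragment
    extension, binned coverage, replicate correlation), SICER-style
    island calling for broad lamin B1/H3K9me3 domains, a Poisson/binomial
    peak caller for transcription-factor sites, condition-exclusive versus
    shared region classification, overlap enrichment against length- and
    chromosome-matched random backgrounds with Fisher's exact test,
    site-anchored coverage profiles and windowed-sum statistics,
    nearest-gene assignment with TSS-distance binning and fold-change
    direct-target calling, a ground-truth synthetic data generator, and a
    config-driven pipeline orchestrating all stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
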