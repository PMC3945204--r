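Package: kdbind
Title: Integrating Transcription-Factor Knockdown Expression with Binding Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-styled pipeline for inferring functional
    transcription-factor binding from siRNA knockdown expression
    experiments. Provides a ground-truthed simulator of a knockdown study
    (regulatory network, synthetic genome annotation, batch-confounded
    expression arrays), quantile normalization with removal of unwanted
    variation anchored on control genes, per-gene likelihood-ratio tests
    with Storey q-values, binding-map construction from ChIP-style peaks
    and footprint-style sites, window- and distal-link-based target
    assignment, and downstream classification of functional binding with
    chromatin-state enrichment, co-occupancy, and direction-of-effect
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    limma,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
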