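Package: wormnet
Title: Keystone Taxa Inference for Paired Soil and Earthworm Gut Microbiome
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for inferring potential keystone taxa
    in paired soil and earthworm gut bacterial communities. Covers rarefaction
    and alpha diversity (Shannon, Chao1, richness, Pielou evenness), shared and
    unique OTU partitions, prevalence-filtered Spearman co-occurrence networks
    with Benjamini-Hochberg false discovery control, Newman modularity with
    deterministic greedy module detection, within-module degree (Zi) and
    participation coefficient (Pi) role classification, keystone-removal
    network stability testing, Biolog average well color development (AWCD)
    scoring, and keystone-environment correlation. Ships a synthetic community
    generator that plants recoverable module, hub, and environmental-coupling
    ground truth so that every stage of the pipeline is testable without
    sequencing data.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
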