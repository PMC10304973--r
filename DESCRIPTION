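Package: kitchencore
Title: Core Microbiota Analysis for Multi-Country Household Surface Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for 16S sOTU count tables from household
    (kitchen) surface and cleaning-utensil surveys: organelle and low-count
    filtering, genus-level taxonomic collapse, relative-abundance conversion,
    rarefaction, centred log-ratio transformation, alpha and beta diversity
    (observed features, Shannon, Faith's phylogenetic diversity, Jaccard,
    Bray-Curtis, weighted and unweighted UniFrac) with principal-coordinate
    analysis, a three-criterion core-microbiota definition (mean abundance,
    mean-or-max abundance, per-household occurrence) with Venn partitioning
    and occurrence summaries, country and sample-type comparisons (PERMANOVA,
    per-taxon permutation F screening with false-discovery-rate control,
    linear mixed models with household random effects), and a
    Dirichlet-multinomial study simulator with planted ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    phyloseq,
    picante,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
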