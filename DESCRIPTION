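Package: kinvar
Title: Subdomain Enrichment, Hotspot Clustering and Mobility Analysis of
    Protein Kinase Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of disease- and cancer-associated amino-acid variants in
    the protein kinase catalytic domain. Segments kinase sequences into
    Hanks-Hunter subdomains by catalytic-motif anchoring, tests per-region
    variant enrichment with a weighted-length two-tailed binomial test,
    characterises position-specific clustering against a Monte Carlo
    random-assignment null, detects cross-kinase mutational hotspots, and maps
    per-residue mobility from principal component analysis of C-alpha
    trajectories to contrast activating versus inactivating mutation sites on
    rigid and flexible regions. Includes simulators for kinase families,
    variant tables and trajectories with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
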