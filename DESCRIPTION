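Package: finescan
Title: Congenic Fine-Mapping and Variant Triage for Introgressed Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fine-mapping a recessive mutation carried on an
    introgressed chromosomal segment in a congenic line, and for triaging the
    sequence variants found inside the mapped region. Infers per-individual and
    consensus causative intervals from marker genotype matrices, computes
    recombination-fraction and two-point LOD statistics, runs a
    hemizygosity/uniqueness/region elimination cascade over SNPs, micro-indels
    and capture gaps, assigns gene-feature categories and six-reading-frame
    coding consequences, scans 3' UTRs for microRNA seed sites, and predicts
    junction-spanning PCR amplicons to accept or refute putative
    rearrangements. A synthetic-data generator emulating a Z-linked congenic
    design makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
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
    utils
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
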