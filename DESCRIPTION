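Package: varprior
Title: Recessive Variant Prioritisation for Single-Proband Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for nominating the causal recessive variant from a single
    affected genome, as used in rare-disease gene discovery: VCF ingestion
    with indel left-alignment, transcript-aware coding consequence prediction
    (frameshift anatomy, premature stop, truncated protein length),
    enumeration of equivalent indel placements in repetitive sequence,
    HGVS-style c. and g. rendering on either strand, and an auditable
    filtration cascade combining control-panel allele-frequency subtraction,
    high-impact filtering under two annotation sources, homozygous and
    phase-aware compound-heterozygous recessive logic, assembly-error gene
    exclusion and candidate-gene intersection. A deterministic synthetic-data
    generator plants a causal frameshift insertion amid structured decoy
    variants for end-to-end validation.
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
    stringr,
    tibble,
    tidyr,
    rtracklayer,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
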