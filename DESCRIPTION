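Package: ffpeconcord
Title: Concordance of Whole-Exome Variant Calls from Fresh-Frozen and
    FFPE Tumour Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing whether whole-exome sequencing of
    formalin-fixed, paraffin-embedded (FFPE) tumour tissue reproduces the
    variant calls obtained from matched fresh-frozen (FF) tissue. Scores
    FFPE DNA integrity from qPCR amplicon concentration ratios (Q-ratios)
    and gates samples into high-/low-quality classes; computes sequencing
    run and coverage metrics (PCR-duplicate, mapped and trimmed-base
    fractions, depth and breadth over capture targets, off-target rate);
    filters calls by quality criteria and classifies the FF/FFPE union
    into Shared, False Positive, False Negative and Not Determined;
    selects somatic variants against a matched normal with a population
    frequency filter; and quantifies formalin deamination artifacts via
    strand-collapsed substitution spectra and transition/transversion
    enrichment. A seeded synthetic-data generator emulates paired
    FF/FFPE/normal callsets with germline polymorphisms, clonal somatic
    mutations, low-allele-fraction C>T/G>A artifacts, degraded-DNA qPCR
    panels and read-count summaries, so the whole pipeline is testable
    without external data.
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
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
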