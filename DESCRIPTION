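Package: mpnpanel
Title: Validation and Somatic Variant Triage for a Targeted Myeloid Amplicon Panel
Version: 0.1.0
Authors@R:
    person("Panel", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-variant-calling analysis for targeted amplicon myeloid gene
    panels (myeloproliferative neoplasm screening): reconciliation of
    small-variant and structural caller call sets via trim-based indel
    normalization, a multi-stage somatic variant triage cascade (region class,
    population allele frequency, low-VAF/recurrent artifact removal with a
    pathogenic rescue lane, novelty classification, Sanger-confirmability
    flagging), reference-standard panel validation metrics (sensitivity,
    specificity, PPV, replicate concordance, limit of detection), per-amplicon
    coverage QC with GC-content window analysis, and a fully parameterised
    synthetic-data generator so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    VariantAnnotation,
    rtracklayer,
    GenomicRanges,
    SummarizedExperiment,
    S4Vectors,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
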