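Package: hcmtriage
Title: Rare-Variant Triage for Hypertrophic Cardiomyopathy Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Filtering, classification and cohort accounting for rare variants
    detected by targeted gene-panel sequencing in hypertrophic cardiomyopathy
    (HCM) probands. Reads germline VCFs and tab-separated annotation tables,
    applies the candidate-selection filter cascade (panel membership, PASS
    calls, protein-coding consequence, population allele frequency below 0.1%),
    classifies molecular consequence from HGVS descriptors, aggregates ClinVar
    assertions into a class with conflicting-interpretation subtypes, flags
    novel variants, assigns a five-tier (B/LB/VUS/LP/P) label with provenance,
    categorizes probands as positive, inconclusive or negative, and summarizes
    diagnostic yield. Ships a 45-proband reference cohort fixture (95 rare
    variants over a 47-gene panel) and a seeded synthetic cohort generator
    with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
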