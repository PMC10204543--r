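Package: plasmatrace
Title: Pathogenicity Annotation, Patient Matching and Longitudinal Tracking
    for Anonymous Liquid-Biopsy Variant Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processes tabular circulating tumor DNA (ctDNA) variant reports
    from targeted gene-panel sequencing of blood plasma. Variants are joined
    against a COSMIC-style reference of known mutations (gene, protein change,
    pathogenic/neutral class, FATHMM score) to assign pathogenicity tiers,
    report-level quality-control flags, and germline / low allele-frequency
    flags. Anonymous reports are grouped into patients by cosine similarity
    over their germline and non-pathogenic allele-frequency vectors, with
    k-means pre-clustering and a rescue pass for samples left unmatched
    within their cluster. Grouped reports are assembled into per-patient,
    time-ordered pathogenic variant-allele-frequency tables for longitudinal
    monitoring of progression, remission and recurrence. A synthetic cohort
    simulator generates panel reports, a matching reference and ground-truth
    patient labels so the whole pipeline runs offline.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
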