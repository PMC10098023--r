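Package: lipivar
Title: Gene-Panel Variant Prioritization for Dyslipidemia Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for prioritizing variants in lipid-metabolism genes from
    multi-sample VCFs: gene-panel subsetting with flank extension,
    per-sample quality metrics (Ti/Tv, Het/non-ref-Hom), allele-frequency
    contrasts against reference populations via Fisher's exact tests with
    Bonferroni correction, a multi-source consensus pathogenicity
    classifier (SIFT, PolyPhen2, REVEL, ClinPred, lipid phenotype),
    pharmacogenomic and protective flagging, prior-report matching,
    per-individual variant-burden profiles, and PCA of ancestry-informative
    markers. Includes a Hardy-Weinberg cohort simulator so every stage is
    testable without access-controlled genomes, plus bundled reference
    tables of variants reported in a Costa Rican whole-genome study of 69
    lipid-metabolism genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
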