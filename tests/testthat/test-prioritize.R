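test_that("impact classing takes the most severe consequence", {
  expect_equal(impact_of("stop_gained"), "HIGH")
  expect_equal(impact_of("start_lost"), "HIGH")
  expect_equal(impact_of("missense_variant"), "MODERATE")
  expect_equal(impact_of("intron_variant"), "MODIFIER")
  terms <- c("intron_variant", "synonymous_variant", "3_prime_UTR_variant",
             "downstream_gene_variant", "splice_region_variant")
  expect_equal(impact_of(terms), "LOW")
  # order-invariant and idempotent on & separated strings
  expect_equal(impact_of(rev(terms)), "LOW")
  expect_equal(impact_of("synonymous_variant&intron_variant"), "LOW")
  expect_warning(u <- impact_of("not_a_term"), "unknown")
  expect_equal(u, "MODIFIER")
  expect_error(impact_of("not_a_term", strict = TRUE), "unknown")
})

test_that("lipid phenotype lexicon matches trait strings case-insensitively", {
  expect_true(lipid_phenotype_match("Familial hypertriglyceridemia"))
  expect_true(lipid_phenotype_match("SITOSTEROLEMIA"))
  expect_true(lipid_phenotype_match("Low density lipoprotein cholesterol levels"))
  expect_false(lipid_phenotype_match("Warfarin response"))
  expect_false(lipid_phenotype_match(character(0)))
  expect_false(lipid_phenotype_match(""))
  expect_true(lipid_phenotype_match("abc | HDL levels | xyz"))
  expect_error(lipid_phenotype_match("x", lexicon = character(0)))
})

test_that("consensus filter counts criteria and applies both thresholds", {
  ann <- data.frame(
    rsid = c("rsA", "rsB", "rsC", "rsD"),
    gene = c("G1", "G2", "G3", "G4"),
    consequence = "missense_variant",
    sift_score = c(0.01, 0.2, NA, 0.01),
    sift_call = c(NA, NA, "deleterious", NA),
    polyphen_category = c("P", "B", "D", "D"),
    revel = c(NA, 0.3, NA, 0.9),
    clinpred = c(NA, 0.2, NA, 0.9),
    traits = c("Sitosterolemia", "", "", ""),
    stringsAsFactors = FALSE
  )
  alt <- c(rsA = 5L, rsB = 5L, rsC = 5L, rsD = 1L)
  rc <- consensus_filter(ann, alt)
  expect_equal(rc$n_criteria, c(3L, 0L, 2L, 4L))
  # rsA passes; rsB fails criteria; rsC has 2 sources; rsD fails alt count
  expect_equal(rc$qualifies, c(TRUE, FALSE, FALSE, FALSE))
  # missing scores count as criterion-false, never as errors
  expect_equal(rc$n_criteria[3], 2L)
})

test_that("non-missense records are not scored by the consensus filter", {
  ann <- data.frame(
    rsid = c("rs1", "rs2"), gene = "G",
    consequence = c("missense_variant", "intron_variant"),
    sift_score = 0.01, polyphen_category = "D", revel = 0.9, clinpred = 0.9,
    traits = "LDL cholesterol", alt_count = 10L,
    stringsAsFactors = FALSE
  )
  rc <- consensus_filter(ann)
  expect_equal(rc$rsid, "rs1")
})

test_that("consensus on the bundled reported variants reproduces the study rule", {
  ann <- fixture_annotation_records()
  rc <- consensus_filter(ann)
  expect_true(all(rc$qualifies))
  # rows supported by exactly three sources drop out at min_sources = 4
  rc4 <- consensus_filter(ann, min_sources = 4)
  expect_lt(sum(rc4$qualifies), nrow(ann))
  expect_gt(sum(rc4$qualifies), 0)
})

test_that("pharmacogenomic and protective flags derive from ClinVar classes", {
  ann <- data.frame(
    rsid = c("rs1", "rs2", "rs3", "rs4"),
    clin_sig = c("drug response", "protective", "", "drug response"),
    traits = c("Warfarin response", "Metabolic syndrome, potection against",
               "LDL cholesterol levels", "protection against X"),
    stringsAsFactors = FALSE
  )
  flags <- pharmaco_protective_flags(ann)
  expect_equal(flags$category, c("drug_response", "protective", "none", "both"))
})

test_that("prior-report matching deduplicates and attributes sources", {
  hits <- prior_report_match(c("rs9282541", "rs9282541", "rs328", "rsXYZ"))
  expect_equal(sort(hits$rsid), c("rs328", "rs9282541"))
  expect_true(all(nzchar(hits$source)))
  expect_equal(nrow(prior_report_match("rs0")), 0L)
  custom <- data.frame(rsid = c("rsA", "rsB"), source = "study X")
  expect_equal(prior_report_match(c("rsB"), custom)$rsid, "rsB")
})

test_that("VOI assembly is a deduplicated union with route provenance", {
  voi <- assemble_voi(consensus = c("rs1", "rs2"),
                      high_impact = c("rs3", "rs2"),
                      pharmaco = "rs4",
                      prior_report = "rs5")
  expect_equal(nrow(voi), 5L)
  expect_equal(sort(voi$routes[voi$rsid == "rs2"]),
               "consensus_risk,high_impact")
  expect_equal(voi$n_routes[voi$rsid == "rs2"], 2L)

  disjoint <- assemble_voi(consensus = c("a", "b"), high_impact = c("c", "d", "e"))
  expect_equal(nrow(disjoint), 5L)

  # union size never exceeds the sum of route sizes
  expect_lte(nrow(voi), 2 + 2 + 1 + 1)
  expect_false(anyDuplicated(voi$rsid) > 0)
})

test_that("VOI assembly orders by genomic position when provided", {
  pos <- data.frame(rsid = c("rs1", "rs2", "rs3"),
                    chrom = c("chr2", "chr1", "chr1"),
                    pos = c(50L, 500L, 100L))
  voi <- assemble_voi(consensus = c("rs1", "rs2", "rs3"), positions = pos)
  expect_equal(voi$rsid, c("rs3", "rs2", "rs1"))
})
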