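test_that("variant classification covers SNV, indel, multiallelic and mixed", {
  expect_equal(classify_variant("A", "G"),
               list(variant_class = "SNV", allelism = "biallelic"))
  expect_equal(classify_variant("A", "AT"),
               list(variant_class = "indel", allelism = "biallelic"))
  expect_equal(classify_variant("C", c("T", "G")),
               list(variant_class = "SNV", allelism = "multiallelic"))
  expect_equal(classify_variant("C", c("T", "CA"))$variant_class, "mixed")
  expect_error(classify_variant("A", "<DEL>"), "unsupported allele")
  expect_error(classify_variant("A", "A"), "identical")
})

test_that("multiallelic decomposition counts copies of each alternate", {
  codes <- decompose_genotypes(c("1/2", "1/1", "0/2", "./.", "./1", "0|1"),
                               n_alt = 2)
  expect_equal(codes[1, ], c(1L, 1L))          # one copy of each alt
  expect_equal(codes[2, ], c(2L, 0L))
  expect_equal(codes[3, ], c(0L, 1L))
  expect_true(all(is.na(codes[4, ])))          # fully missing
  expect_true(all(is.na(codes[5, ])))          # half-call treated as missing
  expect_equal(codes[6, ], c(1L, 0L))          # phase ignored
})

test_that("decomposition conserves alternate-allele copies", {
  gts <- c("0/0", "0/1", "1/1", "1/2", "2/2", "0/2", "1|2", "2|1")
  codes <- decompose_genotypes(gts, n_alt = 2)
  alt_copies <- vapply(strsplit(gts, "[/|]"),
                       function(a) sum(as.integer(a) > 0), integer(1))
  expect_equal(rowSums(codes), alt_copies)
  recomposed <- recompose_genotypes(codes)
  expect_equal(decompose_genotypes(recomposed, 2), codes)
})

test_that("cohort VCF reading subsets to the panel and splits multiallelics", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t1500\trs10\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1",
    "1\t1600\t.\tC\tT,G\t.\tPASS\t.\tGT\t1/2\t0/0",
    "1\t99999\trs99\tA\tC\t.\tPASS\t.\tGT\t0/1\t0/0",
    "1\t1700\trs77\tG\tA\t.\tq10\t.\tGT\t0/1\t0/1"
  ), vcf)
  panel <- gene_panel(genomic_intervals("chr1", 1000, 2000, "GENE"), flank = 0)
  gm <- read_cohort_vcf(vcf, panel)
  # outside-panel site and non-PASS site dropped; multiallelic split in two
  expect_equal(nrow(gm$sites), 3L)
  expect_equal(gm$sites$chrom, rep("chr1", 3))   # chr prefix normalized
  expect_equal(sum(gm$sites$allelism == "multiallelic"), 2L)
  expect_true(is.na(gm$sites$rsid[gm$sites$pos == 1600][1]))
  multi <- gm$codes["S1", gm$sites$pos == 1600]
  expect_equal(unname(multi), c(1L, 1L))
  # keep_filtered retains the q10 site
  gm2 <- read_cohort_vcf(vcf, panel, keep_filtered = TRUE)
  expect_equal(nrow(gm2$sites), 4L)
})

test_that("VCF round trip reproduces sites and codes exactly", {
  cfg <- sim_config(n_samples = 6, n_sites = 80, seed = 5)
  gm <- simulate_genotypes(simulate_sites(synthetic_panel(), cfg), cfg)
  path <- tempfile(fileext = ".vcf")
  write_cohort_vcf(gm, path)
  gm2 <- read_cohort_vcf(path)
  o1 <- order(colnames(gm$codes))
  o2 <- order(colnames(gm2$codes))
  expect_identical(unname(gm$codes[, o1]), unname(gm2$codes[, o2]))
  cols <- c("chrom", "pos", "ref", "alt", "rsid", "variant_class", "allelism")
  s1 <- gm$sites[o1, cols]
  s2 <- gm2$sites[o2, cols]
  rownames(s1) <- rownames(s2) <- NULL
  expect_identical(s1, s2)
})

test_that("reference frequency tables validate on read", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("rsid\tpopulation\talt_freq\tn_diploid",
               "rs328\tAMR\t0.06340\t347",
               "rs328\tEUR\t0.13021\t503"), path)
  panel <- read_reference_frequencies(path)
  expect_s3_class(panel, "pop_freq_panel")
  expect_equal(panel$alt_freq[panel$population == "AMR"], 0.0634)
  expect_equal(panel_populations(panel), c("AMR", "EUR"))

  writeLines("rsid\tpopulation\talt_freq\tn_diploid", path)
  expect_warning(empty <- read_reference_frequencies(path), "empty")
  expect_equal(nrow(empty), 0L)

  writeLines(c("rsid\tpopulation\talt_freq\tn_diploid",
               "rs1\tAMR\t0.5\t10", "rs1\tAMR\t0.6\t10"), path)
  expect_error(read_reference_frequencies(path), "rs1 AMR")

  writeLines(c("rsid\tpopulation\talt_freq\tn_diploid",
               "rs1\tAMR\t1.5\t10"), path)
  expect_error(read_reference_frequencies(path), "outside")
})
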