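test_that("simulation is byte-for-byte deterministic under a fixed seed", {
  cfg <- sim_config(n_samples = 20, n_sites = 200, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$sites, b$sites)
  expect_identical(a$genotypes$codes, b$genotypes$codes)
  expect_identical(a$annotations, b$annotations)
  expect_identical(as.data.frame(a$reference$panel),
                   as.data.frame(b$reference$panel))
  # stages can be regenerated in isolation from the same config
  expect_identical(simulate_sites(synthetic_panel(), cfg)$sites, a$sites)
})

test_that("site composition follows the configured fractions", {
  panel <- synthetic_panel()
  all_indel <- simulate_sites(panel, sim_config(n_sites = 300, seed = 1,
                                                indel_fraction = 1))
  expect_true(all(all_indel$sites$variant_class == "indel"))

  no_multi <- simulate_sites(panel, sim_config(n_sites = 300, seed = 1,
                                               multiallelic_fraction = 0))
  expect_true(all(no_multi$sites$allelism == "biallelic"))

  expect_error(
    simulate_sites(gene_panel(genomic_intervals("chr1", 1, 100, "G"), 0),
                   sim_config(n_sites = 500, seed = 1)),
    "exceeds"
  )
})

test_that("realized Ti/Tv of simulated SNV sites matches the target odds", {
  cfg <- sim_config(n_sites = 10000, titv_target = 2.0, indel_fraction = 0,
                    multiallelic_fraction = 0, seed = 31)
  sim <- simulate_sites(synthetic_panel(), cfg)
  ti <- mapply(function(r, a) {
    (r == "A" & a == "G") | (r == "G" & a == "A") |
      (r == "C" & a == "T") | (r == "T" & a == "C")
  }, sim$sites$ref, sim$sites$alts)
  realized <- sum(ti) / sum(!ti)
  expect_gt(realized, 1.9)
  expect_lt(realized, 2.1)
})

test_that("genotypes follow Hardy-Weinberg sampling at the designed frequency", {
  cfg <- sim_config(n_samples = 10000, missing_rate = 0, seed = 3)
  gm0 <- simulate_genotypes(c(0, 1, 0.5), cfg)
  expect_true(all(gm0$codes[, 1] == 0L))
  expect_true(all(gm0$codes[, 2] == 2L))
  het <- mean(gm0$codes[, 3] == 1L)
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(het - 0.5), 3 * se)
})

test_that("HWE goodness of fit holds for nearly all sites", {
  cfg <- sim_config(n_samples = 400, n_sites = 1000, missing_rate = 0,
                    indel_fraction = 0, multiallelic_fraction = 0,
                    freq_shape1 = 2, freq_shape2 = 2, seed = 17)
  gm <- simulate_genotypes(simulate_sites(synthetic_panel(), cfg), cfg)
  pvals <- apply(gm$codes, 2, function(col) {
    n <- length(col)
    p_hat <- mean(col) / 2
    if (p_hat == 0 || p_hat == 1) return(1)
    expected <- n * c((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
    observed <- tabulate(col + 1L, 3L)
    stat <- sum((observed - expected)^2 / expected)
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  })
  expect_gte(mean(pvals > 0.001), 0.99)
})

test_that("realized frequencies converge to designed frequencies", {
  mae <- vapply(c(50, 500, 5000), function(n) {
    cfg <- sim_config(n_samples = n, n_sites = 300, missing_rate = 0,
                      indel_fraction = 0, multiallelic_fraction = 0,
                      seed = 23)
    sim <- simulate_sites(synthetic_panel(), cfg)
    gm <- simulate_genotypes(sim, cfg)
    realized <- colMeans(gm$codes) / 2
    mean(abs(realized - unlist(sim$freqs)))
  }, numeric(1))
  expect_true(all(diff(mae) < 0))
  expect_lt(mae[3], 0.01)
})

test_that("annotation generator respects the designed criterion counts", {
  panel <- synthetic_panel()
  cfg0 <- sim_config(n_sites = 200, risk_fraction = 0, seed = 8)
  gm0 <- simulate_genotypes(simulate_sites(panel, cfg0), cfg0)
  ann0 <- simulate_annotations(gm0, cfg0)
  rc0 <- consensus_filter(ann0, alt_counts = setNames(rep(10L, nrow(ann0)),
                                                      ann0$rsid))
  expect_true(all(rc0$n_criteria <= 2))
  expect_false(any(rc0$qualifies))

  cfg1 <- sim_config(n_sites = 200, risk_fraction = 1, seed = 8)
  gm1 <- simulate_genotypes(simulate_sites(panel, cfg1), cfg1)
  ann1 <- simulate_annotations(gm1, cfg1)
  rc1 <- consensus_filter(ann1, alt_counts = setNames(rep(10L, nrow(ann1)),
                                                      ann1$rsid))
  expect_true(all(rc1$n_criteria >= 3))
  expect_true(all(rc1$qualifies))
  # the filter recovers the designed labels exactly on mixed cohorts
  cfg <- sim_config(n_sites = 500, risk_fraction = 0.1, seed = 8)
  gm <- simulate_genotypes(simulate_sites(panel, cfg), cfg)
  ann <- simulate_annotations(gm, cfg)
  rc <- consensus_filter(ann, alt_counts = setNames(rep(10L, nrow(ann)),
                                                    ann$rsid))
  expect_identical(rc$n_criteria, ann$designed_n_criteria)
  expect_identical(rc$qualifies, ann$designed_n_criteria >= 3L)
})

test_that("reference panel equals cohort truth with no divergence or shifts", {
  freqs <- setNames(c(0.1, 0.4, 0.9), c("rs1", "rs2", "rs3"))
  cfg <- sim_config(divergence = 0, n_differential = 0, seed = 2,
                    populations = c(ALL = 2504L, AMR = 347L))
  ref <- simulate_reference_panel(freqs, cfg)
  expect_length(ref$differential, 0L)
  for (p in c("ALL", "AMR")) {
    expect_equal(ref$panel$alt_freq[ref$panel$population == p],
                 unname(freqs))
  }
})

test_that("reference panel frequencies stay in [0, 1] under perturbation", {
  set.seed(1)
  freqs <- setNames(stats::runif(200), paste0("rs", 1:200))
  cfg <- sim_config(divergence = 2, n_differential = 50,
                    differential_delta = 0.3, seed = 12)
  ref <- simulate_reference_panel(freqs, cfg)
  expect_true(all(ref$panel$alt_freq >= 0 & ref$panel$alt_freq <= 1))
  expect_length(ref$differential, 50L)
  # shifted sites moved by the configured delta relative to the truth
  shifted <- ref$panel[ref$panel$population == "ALL" &
                         ref$panel$rsid %in% ref$differential, ]
  expect_equal(abs(shifted$alt_freq - freqs[shifted$rsid]),
               rep(0.3, 50), ignore_attr = TRUE, tolerance = 1e-12)
})
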