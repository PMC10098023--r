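make_cohort <- function(ids, codes, rsids) {
  sites <- data.frame(chrom = "chr1", pos = seq_along(rsids) * 100L,
                      ref = "A", alt = "G", rsid = rsids,
                      stringsAsFactors = FALSE)
  rownames(codes) <- ids
  genotype_matrix(codes, sites)
}

test_that("AIM matrix keeps only complete-case markers across cohorts", {
  rsids <- paste0("aim", 1:10)
  c1 <- make_cohort(c("A1", "A2"),
                    matrix(1L, 2, 10), rsids)
  codes2 <- matrix(0L, 2, 10)
  codes2[1, 4] <- NA_integer_
  c2 <- make_cohort(c("B1", "B2"), codes2, rsids)
  am <- build_aim_matrix(list(POP_A = c1, POP_B = c2), rsids)
  expect_equal(ncol(am$codes), 9L)
  expect_equal(am$dropped, "aim4")
  expect_equal(am$populations, c("POP_A", "POP_A", "POP_B", "POP_B"))
  expect_false(anyNA(am$codes))

  # requesting AIMs absent everywhere fails loudly
  expect_error(build_aim_matrix(list(X = c1), paste0("other", 1:3)),
               "complete genotypes")
  # AIM list intersects with available sites
  am2 <- build_aim_matrix(list(X = c1), c(rsids[1:3], "missing1"))
  expect_equal(ncol(am2$codes), 3L)
})

test_that("PCA separates two clusters of identical rows on PC1", {
  codes <- rbind(matrix(0L, 4, 6), matrix(2L, 4, 6))
  rownames(codes) <- paste0("S", 1:8)
  fit <- pca_genotypes(codes, k = 2)
  expect_equal(fit$var_fraction[1], 1)
  expect_true(all(fit$scores[1:4, 1] * fit$scores[5:8, 1] < 0))
  expect_equal(unname(fit$scores[, 2]), rep(0, 8))
})

test_that("variance fractions sum to one at full rank and match eigen", {
  set.seed(5)
  codes <- matrix(sample(0:2, 15 * 8, replace = TRUE), 15, 8)
  k <- qr(scale(codes, center = TRUE, scale = FALSE))$rank
  fit <- pca_genotypes(codes, k = k)
  expect_equal(sum(fit$var_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(fit$var_fraction) <= 1e-12))
  # brute-force covariance eigendecomposition oracle
  ev <- eigen(stats::cov(codes), symmetric = TRUE)$values
  expect_equal(fit$var_fraction, (ev / sum(ev))[seq_len(k)],
               tolerance = 1e-9)
})

test_that("constant matrices give zero coordinates without an exception", {
  codes <- matrix(1L, 5, 4)
  fit <- pca_genotypes(codes, k = 2)
  expect_equal(unname(fit$scores), matrix(0, 5, 2))
  expect_equal(fit$var_fraction, c(0, 0))
})

test_that("PCA coordinates are invariant to sample ordering up to sign", {
  set.seed(6)
  codes <- matrix(sample(0:2, 20 * 10, replace = TRUE), 20, 10)
  rownames(codes) <- paste0("S", 1:20)
  fit1 <- pca_genotypes(codes, k = 3)
  perm <- sample(20)
  fit2 <- pca_genotypes(codes[perm, ], k = 3)
  for (j in 1:3) {
    a <- fit1$scores[perm, j]
    b <- fit2$scores[, j]
    expect_true(isTRUE(all.equal(a, b, check.attributes = FALSE)) ||
                  isTRUE(all.equal(a, -b, check.attributes = FALSE)))
  }
})

test_that("samples from divergent populations cluster in PC space", {
  set.seed(33)
  n_aim <- 60
  pops <- list(
    AFR = stats::rbeta(n_aim, 0.5, 0.5),
    EUR = stats::rbeta(n_aim, 0.5, 0.5),
    EAS = stats::rbeta(n_aim, 0.5, 0.5)
  )
  cohorts <- lapply(pops, function(p) {
    codes <- sapply(p, function(f) stats::rbinom(30, 2, f))
    storage.mode(codes) <- "integer"
    rownames(codes) <- paste0("S", seq_len(30), sample(1e6, 1))
    make_cohort(rownames(codes), codes, paste0("aim", seq_len(n_aim)))
  })
  am <- build_aim_matrix(cohorts, paste0("aim", seq_len(n_aim)))
  fit <- pca_genotypes(am, k = 2)
  expect_gt(mean_silhouette(fit$scores, am$populations), 0.5)
})

test_that("population frequency export matches direct counting", {
  rsids <- paste0("aim", 1:4)
  c1 <- make_cohort("A1", matrix(c(2L, 1L, 0L, 2L), 1, 4), rsids)
  c2 <- make_cohort(c("B1", "B2"),
                    rbind(c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 2L)), rsids)
  am <- build_aim_matrix(list(P1 = c1, P2 = c2), rsids)
  freqs <- export_population_frequencies(am)
  p1 <- freqs[freqs$population == "P1", -1]
  expect_equal(unlist(p1, use.names = FALSE), c(1, 0.5, 0, 1))
  p2 <- freqs[freqs$population == "P2", -1]
  expect_equal(unlist(p2, use.names = FALSE), c(0, 0.5, 1, 0.5))
  expect_true(all(freqs[, -1] >= 0 & freqs[, -1] <= 1))
  # identical genotypes give identical frequency rows
  c3 <- make_cohort("C1", matrix(c(2L, 1L, 0L, 2L), 1, 4), rsids)
  am2 <- build_aim_matrix(list(P1 = c1, P3 = c3), rsids)
  f2 <- export_population_frequencies(am2)
  expect_equal(unlist(f2[1, -1], use.names = FALSE),
               unlist(f2[2, -1], use.names = FALSE))
})
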