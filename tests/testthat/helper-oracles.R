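# brute-force two-sided Fisher p by enumerating all tables with the observed
# margins; probabilities via log binomial coefficients, independent of the
# dhyper-based implementation
oracle_fisher_p <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  if (n == 0) return(1)
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  k <- lo:hi
  logp <- lchoose(r1, k) + lchoose(n - r1, c1 - k) - lchoose(n, c1)
  probs <- exp(logp)
  p_obs <- probs[k == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# small hand-built genotype matrix: 4 samples, SNVs + one indel
toy_genotypes <- function() {
  sites <- data.frame(
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    pos = c(100L, 200L, 100L, 300L),
    ref = c("A", "C", "A", "AT"),
    alt = c("G", "T", "C", "A"),
    rsid = c("rs1", "rs2", NA, "rs4"),
    stringsAsFactors = FALSE
  )
  codes <- rbind(
    S1 = c(1L, 1L, 0L, 2L),
    S2 = c(2L, 0L, 1L, 0L),
    S3 = c(0L, 2L, NA, 1L),
    S4 = c(0L, 0L, 0L, 0L)
  )
  genotype_matrix(codes, sites)
}

# mean silhouette width of labelled points (euclidean), no cluster package
mean_silhouette <- function(coords, labels) {
  d <- as.matrix(stats::dist(coords))
  labs <- unique(labels)
  s <- vapply(seq_len(nrow(coords)), function(i) {
    own <- labels[i]
    a <- mean(d[i, labels == own & seq_along(labels) != i])
    b <- min(vapply(setdiff(labs, own),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
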