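#' Alternate-allele frequency of one genotype column
#'
#' Missing genotypes are excluded from both numerator and denominator; the
#' denominator is twice the number of fully called diploid samples.
#'
#' @param codes Integer vector of dosage codes in `{0, 1, 2, NA}`.
#' @return List with `alt_count`, `called_alleles` and `freq` (`NA` when all
#'   genotypes are missing).
#' @examples
#' allele_frequency(c(0, 1, 2, NA))  # 3 alt copies of 6 called alleles
#' @export
allele_frequency <- function(codes) {
  codes <- as.integer(codes)
  ok <- !is.na(codes)
  if (length(codes[ok]) && (any(codes[ok] < 0L) || any(codes[ok] > 2L))) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  alt <- sum(codes[ok])
  called <- 2L * sum(ok)
  list(
    alt_count = alt,
    called_alleles = called,
    freq = if (called > 0L) alt / called else NA_real_
  )
}

#' Per-site allele frequencies for a cohort
#'
#' @param x A `genotype_matrix`.
#' @return Data frame with one row per site: `rsid`, `chrom`, `pos`, `ref`,
#'   `alt`, `alt_count`, `called_alleles`, `freq`.
#' @export
cohort_allele_frequencies <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  alt <- colSums(x$codes, na.rm = TRUE)
  called <- 2L * colSums(!is.na(x$codes))
  data.frame(
    rsid = x$sites$rsid,
    chrom = x$sites$chrom, pos = x$sites$pos,
    ref = x$sites$ref, alt = x$sites$alt,
    alt_count = as.integer(alt),
    called_alleles = as.integer(called),
    freq = ifelse(called > 0L, alt / called, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The p-value sums hypergeometric probabilities of all tables (with the
#' observed margins) whose probability does not exceed that of the observed
#' table, the usual two-sided convention with a `1 + 1e-7` relative tie
#' tolerance.
#'
#' @param a,b,c,d Non-negative integer cell counts, laid out as rows
#'   `(a, b)` / `(c, d)` (e.g. cohort alt/ref over reference alt/ref).
#' @return The two-sided exact p-value.
#' @examples
#' fisher_exact_2x2(5, 5, 5, 5)   # symmetric table, p = 1
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers")
  }
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  if (n == 0) return(1)
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  k <- lo:hi
  probs <- stats::dhyper(k, c1, n - c1, r1)
  p_obs <- probs[k == a]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Compare cohort allele frequencies against reference populations
#'
#' Runs one two-sided Fisher's exact test per (variant, population) pair for
#' variants with a reference frequency in that population, using integer
#' counts reconstructed from the reference frequencies
#' ([reconstruct_reference_counts()]). Significance uses a Bonferroni
#' threshold `alpha / m`. By default `m` is the number of variants tested
#' against the given population; `family = "all_tests"` uses the total
#' number of tests across populations instead.
#'
#' @param cohort Data frame with columns `rsid`, `alt_count`,
#'   `called_alleles` (e.g. from [cohort_allele_frequencies()]).
#' @param panel A `pop_freq_panel`.
#' @param alpha Family-wise significance level (default 0.05).
#' @param family `"per_population"` (default) or `"all_tests"`.
#' @param m Optional explicit Bonferroni family size overriding `family`
#'   (e.g. when the panel is a subset of a larger tested family).
#' @return Data frame of class `fisher_comparisons`: one row per test with
#'   the 2x2 counts, `p`, `alpha_adjusted` and `significant`. Per-population
#'   significant-variant counts are available via [significant_counts()].
#' @export
compare_to_reference <- function(cohort, panel, alpha = 0.05,
                                 family = c("per_population", "all_tests"),
                                 m = NULL) {
  family <- match.arg(family)
  stopifnot(is.data.frame(cohort),
            all(c("rsid", "alt_count", "called_alleles") %in% names(cohort)))
  panel <- pop_freq_panel(as.data.frame(panel))
  cohort <- cohort[!is.na(cohort$rsid) & cohort$called_alleles > 0L, ]
  rows <- list()
  for (popn in panel_populations(panel)) {
    sub <- panel[panel$population == popn & !is.na(panel$alt_freq), ]
    hit <- match(cohort$rsid, sub$rsid)
    idx <- which(!is.na(hit))
    if (!length(idx)) {
      stop(sprintf("no shared rsids between cohort and population %s", popn))
    }
    ref <- reconstruct_reference_counts(sub$alt_freq[hit[idx]],
                                        sub$n_diploid[hit[idx]])
    rows[[popn]] <- data.frame(
      rsid = cohort$rsid[idx],
      population = popn,
      cohort_alt = cohort$alt_count[idx],
      cohort_ref = cohort$called_alleles[idx] - cohort$alt_count[idx],
      ref_alt = ref$alt_count,
      ref_ref = ref$ref_count,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p <- mapply(fisher_exact_2x2,
                  out$cohort_alt, out$cohort_ref, out$ref_alt, out$ref_ref)
  if (!is.null(m)) {
    out$m <- m
  } else if (family == "per_population") {
    per_pop <- table(out$population)
    out$m <- as.integer(per_pop[out$population])
  } else {
    out$m <- nrow(out)
  }
  out$alpha_adjusted <- alpha / out$m
  out$significant <- out$p < out$alpha_adjusted
  class(out) <- c("fisher_comparisons", "data.frame")
  out
}

#' Count significantly different variants per population
#'
#' @param comparisons Output of [compare_to_reference()].
#' @return Named integer vector, one entry per population.
#' @export
significant_counts <- function(comparisons) {
  stopifnot(all(c("population", "significant") %in% names(comparisons)))
  tab <- tapply(comparisons$significant, comparisons$population, sum)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
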