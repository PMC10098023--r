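#' Per-sample variant-calling quality metrics
#'
#' For every sample, counts the variant sites the sample carries (dosage 1
#' or 2) and derives the standard exome QC ratios: Ti/Tv over carried SNVs
#' (transitions are A<->G and C<->T) and Het/non-ref-Hom over all carried
#' sites. Ratios with a zero denominator are returned as `NA` rather than
#' raising an error. Metrics can be computed exome-wide or separately per
#' chromosome, and optionally restricted to dbSNP-known sites (those with an
#' rsID).
#'
#' @param x A `genotype_matrix`.
#' @param scope `"exome"` (one row per sample) or `"chromosome"` (one row
#'   per sample and chromosome).
#' @param known_only Restrict to sites with an rsID (default FALSE).
#' @return Data frame with columns `sample_id`, `grouping`, `n_snv`,
#'   `n_indel`, `n_het`, `n_hom_alt`, `n_transitions`, `n_transversions`,
#'   `titv`, `het_hom`.
#' @export
sample_qc <- function(x, scope = c("exome", "chromosome"),
                      known_only = FALSE) {
  stopifnot(inherits(x, "genotype_matrix"))
  scope <- match.arg(scope)
  sites <- x$sites
  codes <- x$codes
  if (nrow(sites) == 0L || nrow(codes) == 0L) stop("empty genotype matrix")
  if (known_only) {
    keep <- !is.na(sites$rsid)
    sites <- sites[keep, , drop = FALSE]
    codes <- codes[, keep, drop = FALSE]
    if (!ncol(codes)) stop("no dbSNP-known sites to evaluate")
  }
  groups <- if (scope == "exome") {
    list(exome = seq_len(nrow(sites)))
  } else {
    split(seq_len(nrow(sites)), sites$chrom)
  }
  is_snv <- sites$variant_class == "SNV"
  is_ti <- is_snv & is_transition(sites$ref, sites$alt)
  out <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    sub <- codes[, idx, drop = FALSE]
    carried <- !is.na(sub) & sub > 0L
    n_het <- rowSums(sub == 1L, na.rm = TRUE)
    n_hom <- rowSums(sub == 2L, na.rm = TRUE)
    n_snv <- rowSums(carried & rep(is_snv[idx], each = nrow(sub)))
    n_indel <- rowSums(carried &
                         rep(sites$variant_class[idx] == "indel",
                             each = nrow(sub)))
    n_ti <- rowSums(carried & rep(is_ti[idx], each = nrow(sub)))
    n_tv <- n_snv - n_ti
    out[[g]] <- data.frame(
      sample_id = x$sample_ids,
      grouping = g,
      n_snv = as.integer(n_snv), n_indel = as.integer(n_indel),
      n_het = as.integer(n_het), n_hom_alt = as.integer(n_hom),
      n_transitions = as.integer(n_ti), n_transversions = as.integer(n_tv),
      titv = ifelse(n_tv > 0, n_ti / n_tv, NA_real_),
      het_hom = ifelse(n_hom > 0, n_het / n_hom, NA_real_),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare a QC metric between two cohorts
#'
#' Two-sided Welch (unequal-variance) t-test of per-sample metric values.
#' When both groups are essentially constant the test statistic is computed
#' with a small variance floor so that identical groups give `p = 1` and
#' clearly separated constant groups give a p-value near zero instead of an
#' error.
#'
#' @param metrics_a,metrics_b Numeric vectors of per-sample values
#'   (length >= 2 each; `NA`s dropped).
#' @return List with `t`, `df` and `p`.
#' @export
compare_cohort_metrics <- function(metrics_a, metrics_b) {
  a <- stats::na.omit(as.numeric(metrics_a))
  b <- stats::na.omit(as.numeric(metrics_b))
  if (length(a) < 2L || length(b) < 2L) {
    stop("each cohort needs at least two samples")
  }
  if (stats::var(a) > 0 || stats::var(b) > 0) {
    fit <- stats::t.test(a, b, var.equal = FALSE)
    return(list(t = unname(fit$statistic), df = unname(fit$parameter),
                p = fit$p.value))
  }
  eps <- 1e-12
  se <- sqrt(eps / length(a) + eps / length(b))
  t <- (mean(a) - mean(b)) / se
  df <- length(a) + length(b) - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Concordance between observed and previously reported allele frequencies
#'
#' Fits a linear model of observed on reference frequencies over the shared
#' rsIDs and reports the Pearson correlation with its p-value.
#'
#' @param observed,reference Named numeric vectors (names are rsIDs).
#' @return List with `r`, `p`, `slope`, `intercept`, `n_shared`.
#' @export
frequency_concordance <- function(observed, reference) {
  shared <- intersect(names(observed), names(reference))
  if (length(shared) < 3L) {
    stop("need at least 3 shared rsids to assess concordance")
  }
  x <- as.numeric(reference[shared])
  y <- as.numeric(observed[shared])
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(
    r = unname(ct$estimate),
    p = ct$p.value,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    n_shared = length(shared)
  )
}
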