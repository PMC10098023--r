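#' Per-individual variant burden by class
#'
#' Counts, for each sample and variant class (e.g. VEP impact class or the
#' variants-of-interest set), the sites carried heterozygous and homozygous
#' for the alternate allele. Missing genotypes contribute nothing. Sites in
#' the matrix without a class assignment are counted under an explicit
#' `"unclassified"` bucket.
#'
#' @param x A `genotype_matrix`.
#' @param classes Named character vector mapping rsid (or site id
#'   `chrom:pos:ref:alt` for variants without an rsID) to class label, or a
#'   data frame with columns `rsid` and `class`.
#' @return Data frame with `sample_id`, `class`, `n_het`, `n_hom_alt`,
#'   `n_total` for every sample x class combination.
#' @export
burden_per_sample <- function(x, classes) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.data.frame(classes)) {
    stopifnot(all(c("rsid", "class") %in% names(classes)))
    classes <- stats::setNames(as.character(classes$class),
                               as.character(classes$rsid))
  }
  key <- ifelse(is.na(x$sites$rsid), site_ids(x$sites), x$sites$rsid)
  site_class <- unname(classes[key])
  site_class[is.na(site_class)] <- "unclassified"
  out <- list()
  for (cl in unique(site_class)) {
    idx <- which(site_class == cl)
    sub <- x$codes[, idx, drop = FALSE]
    n_het <- as.integer(rowSums(sub == 1L, na.rm = TRUE))
    n_hom <- as.integer(rowSums(sub == 2L, na.rm = TRUE))
    out[[cl]] <- data.frame(
      sample_id = x$sample_ids, class = cl,
      n_het = n_het, n_hom_alt = n_hom, n_total = n_het + n_hom,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cohort-level summary of burden profiles
#'
#' @param profiles Output of [burden_per_sample()].
#' @param probs Quantile probabilities for the total-burden distribution.
#' @return Data frame with one row per class: mean het/hom/total burden and
#'   the requested quantiles of `n_total`.
#' @export
cohort_burden_summary <- function(profiles,
                                  probs = c(0, 0.25, 0.5, 0.75, 1)) {
  stopifnot(is.data.frame(profiles), nrow(profiles) >= 1L,
            all(c("class", "n_het", "n_hom_alt", "n_total") %in%
                  names(profiles)))
  out <- lapply(split(profiles, profiles$class), function(p) {
    q <- stats::quantile(p$n_total, probs = probs, names = FALSE)
    row <- data.frame(
      class = p$class[1L],
      n_samples = nrow(p),
      mean_het = mean(p$n_het),
      mean_hom_alt = mean(p$n_hom_alt),
      mean_total = mean(p$n_total),
      stringsAsFactors = FALSE
    )
    for (i in seq_along(probs)) {
      row[[sprintf("q%g", 100 * probs[i])]] <- q[i]
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
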