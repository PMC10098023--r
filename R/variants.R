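#' Classify a variant site by allele composition
#'
#' @param ref Reference allele (non-empty string over A/C/G/T).
#' @param alts Character vector of alternate alleles (>= 1).
#' @return A list with `variant_class` (`"SNV"`, `"indel"` or `"mixed"`) and
#'   `allelism` (`"biallelic"` or `"multiallelic"`).
#' @details A site is an SNV when the reference and every alternate allele
#'   have length 1; an indel when every alternate differs in length from the
#'   reference; `mixed` otherwise (e.g. an SNV alt alongside an indel alt, or
#'   a same-length multi-nucleotide substitution). Symbolic and breakend
#'   alleles are rejected.
#' @examples
#' classify_variant("A", "G")
#' classify_variant("C", c("T", "G"))
#' @export
classify_variant <- function(ref, alts) {
  ref <- toupper(as.character(ref))
  alts <- toupper(as.character(alts))
  stopifnot(length(ref) == 1L, length(alts) >= 1L)
  ok <- grepl("^[ACGT]+$", c(ref, alts))
  if (!all(ok)) {
    stop(sprintf(
      "unsupported allele(s): %s (symbolic/breakend alleles are not handled)",
      paste(c(ref, alts)[!ok], collapse = ", ")
    ))
  }
  if (any(alts == ref)) {
    stop("alternate allele identical to reference")
  }
  len_ok <- nchar(alts) == nchar(ref)
  variant_class <- if (nchar(ref) == 1L && all(nchar(alts) == 1L)) {
    "SNV"
  } else if (all(!len_ok)) {
    "indel"
  } else {
    "mixed"
  }
  allelism <- if (length(alts) > 1L) "multiallelic" else "biallelic"
  list(variant_class = variant_class, allelism = allelism)
}

is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

#' Decompose genotype calls at a (possibly multiallelic) site
#'
#' Splits diploid GT strings into one dosage column per alternate allele:
#' each column counts copies of that alternate only. Samples missing at the
#' parent site (including half-calls such as `./1`) are missing in every
#' child column. Phase separators `|` and `/` are treated identically.
#'
#' @param gt Character vector of GT strings (`"0/1"`, `"1|2"`, `"./."`, ...);
#'   `NA` is treated as missing.
#' @param n_alt Number of alternate alleles at the site.
#' @return Integer matrix `length(gt) x n_alt` with entries in `{0, 1, 2, NA}`.
#' @examples
#' decompose_genotypes(c("1/2", "0/1", "./."), n_alt = 2)
#' @export
decompose_genotypes <- function(gt, n_alt) {
  n_alt <- as.integer(n_alt)
  stopifnot(n_alt >= 1L)
  gt <- as.character(gt)
  out <- matrix(NA_integer_, nrow = length(gt), ncol = n_alt)
  alleles <- strsplit(gt, "[/|]")
  for (i in seq_along(gt)) {
    a <- alleles[[i]]
    if (is.na(gt[i]) || length(a) != 2L || any(a == ".") || any(is.na(a))) {
      next
    }
    ai <- suppressWarnings(as.integer(a))
    if (any(is.na(ai)) || any(ai < 0L) || any(ai > n_alt)) next
    for (k in seq_len(n_alt)) {
      out[i, k] <- sum(ai == k)
    }
  }
  out
}

#' Recompose a diploid GT string from per-alternate dosage codes
#'
#' Inverse of [decompose_genotypes()] for diploid calls: a row of child codes
#' summing to at most 2 maps back to a unique unphased genotype.
#'
#' @param codes Integer matrix `n_samples x n_alt` of per-alternate dosages.
#' @return Character vector of GT strings.
#' @export
recompose_genotypes <- function(codes) {
  codes <- as.matrix(codes)
  apply(codes, 1L, function(row) {
    if (anyNA(row)) return("./.")
    total <- sum(row)
    if (total > 2L) stop("alt dosages exceed diploid ploidy")
    alleles <- c(rep(0L, 2L - total), rep(seq_along(row), row))
    paste(sort(alleles), collapse = "/")
  })
}

site_ids <- function(sites) {
  paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
}

#' Construct a genotype matrix
#'
#' The central cohort container: biallelic (post-decomposition) sites by
#' samples, with dosage codes 0 (hom-ref), 1 (het), 2 (hom-alt) and `NA`
#' (missing).
#'
#' @param codes Integer matrix `n_samples x n_sites` with entries in
#'   `{0, 1, 2, NA}`.
#' @param sites Data frame with one row per site and columns `chrom`, `pos`,
#'   `ref`, `alt`, `rsid` (NA when unknown), `variant_class`, `allelism`
#'   (of the parent record; children of a split multiallelic record keep
#'   `"multiallelic"`) and `parent_id` (shared key of children split from
#'   one VCF record).
#' @param sample_ids Unique sample identifiers; defaults to
#'   `rownames(codes)`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, sites, sample_ids = rownames(codes)) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(sample_ids)) {
    sample_ids <- paste0("S", seq_len(nrow(codes)))
  }
  stopifnot(
    is.data.frame(sites),
    all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
    nrow(codes) == length(sample_ids),
    ncol(codes) == nrow(sites),
    !anyDuplicated(sample_ids)
  )
  vals <- codes[!is.na(codes)]
  if (length(vals) && (any(vals < 0L) || any(vals > 2L))) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  if (!"rsid" %in% names(sites)) sites$rsid <- NA_character_
  if (!"variant_class" %in% names(sites) || !"allelism" %in% names(sites)) {
    cls <- lapply(seq_len(nrow(sites)),
                  function(i) classify_variant(sites$ref[i], sites$alt[i]))
    if (!"variant_class" %in% names(sites)) {
      sites$variant_class <- vapply(cls, `[[`, "", "variant_class")
    }
    if (!"allelism" %in% names(sites)) {
      sites$allelism <- vapply(cls, `[[`, "", "allelism")
    }
  }
  if (!"parent_id" %in% names(sites)) {
    sites$parent_id <- paste(sites$chrom, sites$pos, sites$ref, sep = ":")
  }
  rownames(codes) <- sample_ids
  colnames(codes) <- site_ids(sites)
  rownames(sites) <- NULL
  structure(
    list(codes = codes, sites = sites, sample_ids = sample_ids),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d biallelic sites (%d SNV, %d indel, %d mixed); %.2f%% missing\n",
    length(x$sample_ids), nrow(x$sites),
    sum(x$sites$variant_class == "SNV"),
    sum(x$sites$variant_class == "indel"),
    sum(x$sites$variant_class == "mixed"),
    100 * mean(is.na(x$codes))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Subset a genotype matrix by samples and/or sites
#'
#' @param x A `genotype_matrix`.
#' @param samples Sample index/logical/name vector (optional).
#' @param sites Site index or logical vector (optional).
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(x, samples = NULL, sites = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  codes <- x$codes
  st <- x$sites
  ids <- x$sample_ids
  if (!is.null(samples)) {
    codes <- codes[samples, , drop = FALSE]
    ids <- rownames(codes)
  }
  if (!is.null(sites)) {
    codes <- codes[, sites, drop = FALSE]
    st <- st[sites, , drop = FALSE]
  }
  genotype_matrix(codes, st, ids)
}
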