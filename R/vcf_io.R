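#' Read a multi-sample cohort VCF restricted to a gene panel
#'
#' Sites whose position falls inside a panel interval are retained,
#' multiallelic records are decomposed into biallelic children (dosages per
#' alternate allele), and rsIDs are taken from the ID column when present
#' (`"."` means absent). Contig names are normalized to the panel's
#' `chr`-prefix dialect. Records whose FILTER is neither `PASS` nor `.` are
#' dropped unless `keep_filtered = TRUE` (site-level filtering is assumed to
#' have been applied upstream). Symbolic/breakend alleles and `*` spanning
#' alleles are skipped with a warning. Half-calls and phased separators are
#' handled per [decompose_genotypes()].
#'
#' @param path Path to a VCF 4.x file (plain or bgzip/gzip compressed) with
#'   GT in FORMAT.
#' @param panel A `gene_panel` (already flank-extended) or an interval data
#'   frame; `NULL` keeps all sites.
#' @param keep_filtered Keep records with a non-PASS FILTER (default FALSE).
#' @return A `genotype_matrix`.
#' @export
read_cohort_vcf <- function(path, panel = NULL, keep_filtered = FALSE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no variant records")
  if (ncol(vcf@gt) < 2L) stop("VCF has no sample genotype columns")
  fmt <- strsplit(vcf@gt[, 1L], ":")
  if (!all(vapply(fmt, function(f) "GT" %in% f, logical(1L)))) {
    stop("every VCF record must carry a GT FORMAT field")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- matrix(as.character(gt), nrow = nrow(fix),
               dimnames = dimnames(gt))
  samples <- colnames(vcf@gt)[-1L]

  fix$POS <- as.integer(fix$POS)
  keep <- rep(TRUE, nrow(fix))
  if (!keep_filtered) {
    keep <- keep & (is.na(fix$FILTER) | fix$FILTER %in% c(".", "PASS"))
  }
  if (!is.null(panel)) {
    iv <- if (inherits(panel, "gene_panel")) panel$intervals else panel
    chrom <- normalize_chroms(fix$CHROM, iv$chrom)
    fix$CHROM <- chrom
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(chrom, IRanges::IRanges(fix$POS, fix$POS)),
      panel_granges(iv)
    )
    keep <- keep & seq_len(nrow(fix)) %in% S4Vectors::queryHits(hits)
  }

  site_rows <- list()
  code_cols <- list()
  for (i in which(keep)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    cls <- tryCatch(classify_variant(fix$REF[i], alts), error = function(e) e)
    if (inherits(cls, "error")) {
      warning(sprintf("skipping %s:%s: %s", fix$CHROM[i], fix$POS[i],
                      conditionMessage(cls)), call. = FALSE)
      next
    }
    codes <- decompose_genotypes(gt[i, samples], n_alt = length(alts))
    rsid <- fix$ID[i]
    if (is.na(rsid) || rsid == ".") rsid <- NA_character_
    parent <- paste(fix$CHROM[i], fix$POS[i], fix$REF[i], sep = ":")
    for (k in seq_along(alts)) {
      kcls <- classify_variant(fix$REF[i], alts[k])
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = fix$POS[i], ref = fix$REF[i],
        alt = alts[k], rsid = rsid,
        variant_class = kcls$variant_class,
        allelism = cls$allelism, parent_id = parent,
        stringsAsFactors = FALSE
      )
      code_cols[[length(code_cols) + 1L]] <- codes[, k]
    }
  }
  if (!length(site_rows)) stop("no usable sites after panel subsetting")
  sites <- do.call(rbind, site_rows)
  codes <- do.call(cbind, code_cols)
  ord <- order(sites$chrom, sites$pos, sites$ref, sites$alt)
  genotype_matrix(codes[, ord, drop = FALSE], sites[ord, , drop = FALSE],
                  sample_ids = samples)
}

# match the "chr" prefix dialect of `target` names
normalize_chroms <- function(chrom, target) {
  target_chr <- any(grepl("^chr", target))
  has_chr <- grepl("^chr", chrom)
  if (target_chr) {
    chrom[!has_chr] <- paste0("chr", chrom[!has_chr])
  } else {
    chrom[has_chr] <- sub("^chr", "", chrom[has_chr])
  }
  chrom
}

#' Write a genotype matrix as VCF 4.2
#'
#' Children that were decomposed from one multiallelic record (shared
#' `parent_id`) are re-joined into a single multiallelic line, so that
#' reading the file back reproduces sites and codes exactly.
#'
#' @param x A `genotype_matrix`.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  sites <- x$sites
  groups <- split(seq_len(nrow(sites)), sites$parent_id)
  # order records by genome position of the first child
  first <- vapply(groups, `[`, integer(1L), 1L)
  groups <- groups[order(sites$chrom[first], sites$pos[first], sites$ref[first])]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=lipivar",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", x$sample_ids), collapse = "\t")
  )
  lines <- vapply(groups, function(idx) {
    st <- sites[idx, , drop = FALSE]
    gts <- recompose_genotypes(x$codes[, idx, drop = FALSE])
    rsid <- st$rsid[1L]
    paste(c(
      st$chrom[1L], st$pos[1L],
      if (is.na(rsid)) "." else rsid,
      st$ref[1L], paste(st$alt, collapse = ","),
      ".", "PASS", ".", "GT", gts
    ), collapse = "\t")
  }, character(1L))
  writeLines(c(header, lines), path)
  invisible(path)
}
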