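#' Build a table of genomic intervals
#'
#' Intervals are 1-based and inclusive at both ends (VCF convention).
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 1-based inclusive; `end >= start`.
#' @param label Optional labels (gene symbols, AIM set names); recycled.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `label`.
#' @examples
#' genomic_intervals("chr1", 1000, 2000, "LPL")
#' @export
genomic_intervals <- function(chrom, start, end, label = NA_character_) {
  n <- max(length(chrom), length(start), length(end))
  out <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    label = rep_len(as.character(label), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(out)
  out
}

validate_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    stop("interval chromosome names must be non-empty")
  }
  if (any(x$start < 1L)) {
    stop("interval start positions must be >= 1")
  }
  bad <- which(x$end < x$start)
  if (length(bad)) {
    b <- x[bad[1L], ]
    stop(sprintf(
      "malformed interval (end < start): %s:%d-%d%s",
      b$chrom, b$start, b$end,
      if (!is.null(b$label) && !is.na(b$label)) paste0(" [", b$label, "]") else ""
    ))
  }
  invisible(x)
}

#' Extend intervals by a flank and merge overlaps
#'
#' Each interval is grown by `flank` bp on both sides (clipped at position 1),
#' then overlapping or book-ended intervals on the same chromosome are merged.
#' Labels of merged intervals are concatenated (unique, comma-separated).
#'
#' @param intervals A data frame as returned by [genomic_intervals()].
#' @param flank Non-negative integer, bp added upstream and downstream.
#' @return A sorted interval data frame with disjoint intervals per chromosome.
#' @examples
#' extend_and_merge_intervals(genomic_intervals("chr1", 1000, 2000), flank = 300)
#' @export
extend_and_merge_intervals <- function(intervals, flank = 0L) {
  validate_intervals(intervals)
  flank <- as.integer(flank)
  stopifnot(length(flank) == 1L, !is.na(flank), flank >= 0L)
  if (nrow(intervals) == 0L) {
    return(intervals)
  }
  if (!"label" %in% names(intervals)) intervals$label <- NA_character_
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(
      start = pmax(1L, intervals$start - flank),
      end = intervals$end + flank
    ),
    label = intervals$label
  )
  merged <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  labs <- vapply(merged$revmap, function(i) {
    l <- unique(intervals$label[i])
    l <- l[!is.na(l)]
    if (length(l)) paste(l, collapse = ",") else NA_character_
  }, character(1L))
  merged <- GenomicRanges::sort(merged)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged),
    end = GenomicRanges::end(merged),
    label = labs,
    stringsAsFactors = FALSE
  )
}

#' Construct a gene panel
#'
#' A gene panel is a set of gene symbols with genomic intervals, plus a flank
#' (default 300 bp) applied upstream and downstream of every interval before
#' merging. After construction the panel's intervals are disjoint and sorted
#' within each chromosome.
#'
#' @param intervals Interval data frame; the `label` column carries the gene
#'   symbol each interval belongs to.
#' @param flank Non-negative flank in bp (default 300).
#' @return An object of class `gene_panel` with elements `genes` (unique
#'   symbols), `intervals` (the merged, extended intervals) and `flank`.
#' @export
gene_panel <- function(intervals, flank = 300L) {
  validate_intervals(intervals)
  if (!"label" %in% names(intervals) || all(is.na(intervals$label))) {
    stop("gene_panel requires a 'label' column with gene symbols")
  }
  genes <- unique(intervals$label[!is.na(intervals$label)])
  merged <- extend_and_merge_intervals(intervals, flank = flank)
  structure(
    list(genes = genes, intervals = merged, flank = as.integer(flank)),
    class = "gene_panel"
  )
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf(
    "gene_panel: %d genes, %d merged intervals (flank %d bp), %.1f kb covered\n",
    length(x$genes), nrow(x$intervals), x$flank,
    sum(x$intervals$end - x$intervals$start + 1) / 1000
  ))
  invisible(x)
}

panel_granges <- function(panel) {
  iv <- if (inherits(panel, "gene_panel")) panel$intervals else panel
  GenomicRanges::GRanges(
    seqnames = iv$chrom,
    ranges = IRanges::IRanges(iv$start, iv$end)
  )
}

#' Read a panel definition from BED or TSV
#'
#' BED input (`.bed`) is 0-based half-open and converted to 1-based inclusive
#' coordinates on read; the 4th column, when present, is taken as the gene
#' symbol. TSV input must have a header with columns `chrom`, `start`, `end`
#' and optionally `gene`, already 1-based inclusive.
#'
#' @param path File path.
#' @param flank Flank passed to [gene_panel()].
#' @return A `gene_panel`.
#' @export
read_panel <- function(path, flank = 300L) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    raw <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, quote = "")
    iv <- genomic_intervals(
      chrom = raw[[1L]],
      start = as.integer(raw[[2L]]) + 1L,
      end = as.integer(raw[[3L]]),
      label = if (ncol(raw) >= 4L) raw[[4L]] else NA_character_
    )
  } else {
    raw <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
    need <- c("chrom", "start", "end")
    if (!all(need %in% names(raw))) {
      stop("panel TSV must have columns chrom, start, end (and optionally gene)")
    }
    iv <- genomic_intervals(
      chrom = raw$chrom, start = raw$start, end = raw$end,
      label = if ("gene" %in% names(raw)) raw$gene else NA_character_
    )
  }
  gene_panel(iv, flank = flank)
}

#' The 69 lipid-metabolism gene symbols of the bundled panel
#'
#' Gene symbols for the dyslipidemia panel: ABC transporters, the
#' apolipoprotein family, lipases, lipid-sensing receptors and regulators.
#'
#' @return Character vector of 69 gene symbols.
#' @export
lipid_panel_genes <- function() {
  c(
    "ABCA1", "ABCG1", "ABCG4", "ABCG5", "ABCG8", "ABHD5", "ANGPTL3",
    "APOA1", "APOA2", "APOA4", "APOA5", "APOB", "APOC1", "APOC2",
    "APOC3", "APOC4", "APOD", "APOE", "APOF", "APOH", "APOL1", "APOL2",
    "APOL3", "APOL4", "APOL5", "APOL6", "APOM", "APOO", "CD36",
    "CELSR2", "CETP", "CILP2", "CREB3L3", "CYP26A1", "FADS1", "FADS2",
    "FADS3", "GALNT2", "GCKR", "GPD1", "GPIHBP1", "HMGCR", "KLHL8",
    "LCAT", "LDLR", "LDLRAP1", "LIPA", "LIPC", "LIPE", "LIPG", "LMF1",
    "LPL", "LRP1", "MLXIPL", "MTTP", "MYLIP", "NCAN", "NPC1L1",
    "PCSK9", "PLA2G7", "PLIN1", "PLTP", "PNPLA2", "PPARA", "SCARB1",
    "SORT1", "STAP1", "TRIB1", "USF1"
  )
}

#' Deterministic synthetic coordinates for a gene panel
#'
#' Real panel coordinates come from a genome annotation; for simulation and
#' testing this helper lays the requested genes out on synthetic chromosomes
#' with fixed arithmetic spacing, so the result is reproducible without any
#' annotation resource. The coordinates are synthetic and carry no relation
#' to the genes' true positions.
#'
#' @param genes Character vector of gene symbols (default the 69-gene lipid
#'   panel).
#' @param interval_length Length of each gene interval in bp.
#' @param flank Flank passed to [gene_panel()].
#' @return A `gene_panel` with one interval per gene.
#' @export
synthetic_panel <- function(genes = lipid_panel_genes(),
                            interval_length = 5000L,
                            flank = 300L) {
  n <- length(genes)
  stopifnot(n >= 1L)
  chrom_i <- ((seq_len(n) - 1L) %% 22L) + 1L
  row_i <- (seq_len(n) - 1L) %/% 22L
  start <- 1e6L + row_i * 10L * interval_length
  iv <- genomic_intervals(
    chrom = paste0("chr", chrom_i),
    start = start,
    end = start + interval_length - 1L,
    label = genes
  )
  gene_panel(iv, flank = flank)
}
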