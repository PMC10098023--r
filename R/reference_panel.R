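#' Construct a reference population frequency panel
#'
#' Holds per-population alternate-allele frequencies together with diploid
#' sample sizes, the shape in which 1000-Genomes-style super-population
#' frequencies are published.
#'
#' @param df Data frame with columns `rsid`, `population`, `alt_freq`
#'   (in `[0, 1]`) and `n_diploid` (> 0).
#' @return An object of class `pop_freq_panel` (a validated data frame).
#' @export
pop_freq_panel <- function(df) {
  need <- c("rsid", "population", "alt_freq", "n_diploid")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  df <- df[, need]
  df$rsid <- as.character(df$rsid)
  df$population <- as.character(df$population)
  df$alt_freq <- as.numeric(df$alt_freq)
  df$n_diploid <- as.integer(df$n_diploid)
  bad <- which(!is.na(df$alt_freq) & (df$alt_freq < 0 | df$alt_freq > 1))
  if (length(bad)) {
    stop(sprintf("allele frequency outside [0, 1] for %s/%s",
                 df$rsid[bad[1L]], df$population[bad[1L]]))
  }
  if (any(!is.na(df$n_diploid) & df$n_diploid <= 0L)) {
    stop("n_diploid must be positive")
  }
  key <- paste(df$rsid, df$population)
  dup <- key[duplicated(key)]
  if (length(dup)) {
    stop(sprintf("duplicate (rsid, population) entries: %s", dup[1L]))
  }
  rownames(df) <- NULL
  class(df) <- c("pop_freq_panel", "data.frame")
  df
}

#' Read reference population allele frequencies from TSV
#'
#' @param path TSV with header columns `rsid`, `population`, `alt_freq`,
#'   `n_diploid`.
#' @return A `pop_freq_panel`. An empty file yields an empty panel with a
#'   warning.
#' @export
read_reference_frequencies <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  if (nrow(df) == 0L) {
    warning("reference frequency file is empty")
  }
  pop_freq_panel(df)
}

#' Populations present in a frequency panel
#' @param panel A `pop_freq_panel`.
#' @return Character vector of population names.
#' @export
panel_populations <- function(panel) unique(panel$population)

#' Reconstruct integer allele counts from a published frequency
#'
#' Reference panels publish frequencies, not counts; since the published
#' frequencies are exact rationals of allele counts over `2 * n_diploid`
#' chromosomes, rounding `freq * 2 * n_diploid` recovers the original
#' integers.
#'
#' @param freq Alternate-allele frequency in `[0, 1]` (vectorized).
#' @param n_diploid Number of diploid samples.
#' @return Data frame with `alt_count` and `ref_count`.
#' @examples
#' reconstruct_reference_counts(0.27976, 504)  # 282 alt copies of 1008
#' @export
reconstruct_reference_counts <- function(freq, n_diploid) {
  stopifnot(all(freq >= 0 & freq <= 1, na.rm = TRUE), all(n_diploid > 0))
  total <- 2L * as.integer(n_diploid)
  alt <- as.integer(round(freq * total))
  data.frame(alt_count = alt, ref_count = total - alt)
}

#' Recover the allele count behind a printed cohort frequency
#'
#' Cohort tables print a rounded frequency whose denominator (called allele
#' count) varies site to site with missingness. Given candidate denominators,
#' this picks the one whose nearest integer count reproduces the printed
#' frequency best.
#'
#' @param freq Printed frequency (vectorized).
#' @param candidates Candidate called-allele totals (even integers); default
#'   500 to 516, bracketing a 258-sample cohort with a few missing calls.
#' @return Data frame with `alt_count`, `called_alleles` and the implied
#'   `freq`.
#' @export
recover_allele_count <- function(freq, candidates = seq(500L, 516L, by = 2L)) {
  stopifnot(all(candidates %% 2L == 0L), all(candidates > 0L))
  out <- lapply(freq, function(f) {
    counts <- round(f * candidates)
    err <- abs(f - counts / candidates)
    best <- which.min(err)
    data.frame(alt_count = as.integer(counts[best]),
               called_alleles = as.integer(candidates[best]),
               freq = counts[best] / candidates[best])
  })
  do.call(rbind, out)
}
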