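fixture_files <- c(
  table2 = "reported_panel_counts.tsv",
  table3 = "reported_high_impact.tsv",
  table4 = "reported_pharmaco.tsv",
  table5 = "reported_consensus.tsv",
  table6 = "reported_prior.tsv"
)
fixture_aliases <- c(
  panel_counts = "table2",
  high_impact = "table3",
  pharmaco = "table4",
  consensus = "table5",
  prior_reports = "table6"
)

#' Load a bundled reported-variant table
#'
#' The package bundles transcriptions of the variant tables reported by a
#' whole-genome study of 69 lipid-metabolism genes in 258 Costa Rican
#' genomes: panel-wide variant class counts (`"table2"`/`"panel_counts"`),
#' the eight high-impact variants (`"table3"`/`"high_impact"`), the nine
#' pharmacogenomic/protective variants (`"table4"`/`"pharmaco"`), the 18
#' multi-source consensus risk variants (`"table5"`/`"consensus"`), and the
#' eight variants previously reported in Costa Rican or Latin American lipid
#' studies (`"table6"`/`"prior_reports"`). Frequency columns use `NA` where
#' the printed table shows no data; `sig_*` columns carry the printed
#' significance marks (1 = flagged as significantly different from the
#' cohort frequency).
#'
#' @param name One of `"table2"` ... `"table6"` or the aliases above.
#' @return A data frame.
#' @examples
#' nrow(load_fixture_table("table5"))  # 18 consensus risk variants
#' @export
load_fixture_table <- function(name) {
  if (name %in% names(fixture_aliases)) name <- fixture_aliases[[name]]
  if (!name %in% names(fixture_files)) {
    stop(sprintf(
      "unknown fixture '%s'; valid names: %s", name,
      paste(c(names(fixture_files), names(fixture_aliases)), collapse = ", ")
    ))
  }
  path <- system.file("extdata", fixture_files[[name]], package = "lipivar",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          na.strings = c("NA", "-"))
  if ("traits" %in% names(df)) df$traits[is.na(df$traits)] <- ""
  df
}

#' Frequency columns of a fixture as a reference panel
#'
#' Reshapes the per-population frequency columns of a reported-variant table
#' into a [pop_freq_panel()], attaching the standard 1000-Genomes phase-3
#' super-population diploid sizes.
#'
#' @param fixture A data frame from [load_fixture_table()] (`table4`,
#'   `table5` or `table6`).
#' @param sizes Named diploid sample sizes per population.
#' @return A `pop_freq_panel`.
#' @export
fixture_reference_panel <- function(fixture, sizes = kgp_sizes()) {
  pops <- sub("^freq_", "", grep("^freq_[A-Z]+$", names(fixture), value = TRUE))
  rows <- lapply(pops, function(p) {
    data.frame(
      rsid = fixture$rsid,
      population = p,
      alt_freq = fixture[[paste0("freq_", p)]],
      n_diploid = unname(sizes[p]),
      stringsAsFactors = FALSE
    )
  })
  pop_freq_panel(do.call(rbind, rows))
}

#' 1000 Genomes phase-3 super-population diploid sample sizes
#' @return Named integer vector (ALL, AFR, EUR, EAS, AMR).
#' @export
kgp_sizes <- function() {
  c(ALL = 2504L, AFR = 661L, EUR = 503L, EAS = 504L, AMR = 347L)
}

#' Annotation records from the consensus-variant fixture
#'
#' Expands the per-variant source flags (S = SIFT deleterious, P = PolyPhen2
#' possibly/probably damaging, R = REVEL > 0.5, C = ClinPred > 0.5) of the
#' bundled consensus table into annotation records usable by
#' [consensus_filter()]. Flags are represented by categorical calls (SIFT,
#' PolyPhen2) or representative scores just inside the qualifying range
#' (REVEL, ClinPred), since the study reports the calls, not the underlying
#' scores. Alternate-allele counts are recovered from the printed cohort
#' frequencies via [recover_allele_count()].
#'
#' @param fixture Defaults to `load_fixture_table("table5")`.
#' @return Annotation data frame with columns `rsid`, `gene`, `consequence`,
#'   `sift_score`, `sift_call`, `polyphen_category`, `revel`, `clinpred`,
#'   `traits`, `alt_count`.
#' @export
fixture_annotation_records <- function(fixture = load_fixture_table("table5")) {
  flags <- strsplit(gsub(" ", "", fixture$sources), ",", fixed = TRUE)
  has <- function(f) vapply(flags, function(x) f %in% x, logical(1L))
  counts <- recover_allele_count(fixture$freq_cohort)
  data.frame(
    rsid = fixture$rsid,
    gene = fixture$gene,
    consequence = "missense_variant",
    sift_score = NA_real_,
    sift_call = ifelse(has("S"), "deleterious", NA_character_),
    polyphen_category = ifelse(has("P"), "D", NA_character_),
    revel = ifelse(has("R"), 0.9, NA_real_),
    clinpred = ifelse(has("C"), 0.9, NA_real_),
    traits = fixture$traits,
    alt_count = counts$alt_count,
    stringsAsFactors = FALSE
  )
}

#' Check printed significance marks against recomputed Fisher tests
#'
#' For each (variant, population) cell of a reported-variant fixture with a
#' reference frequency, reconstructs integer allele counts (cohort counts
#' from the printed cohort frequency, reference counts from the printed
#' population frequency and its diploid size), reruns the two-sided Fisher
#' test, and compares the Bonferroni call against the printed significance
#' mark under each candidate family size. Cells that no candidate family
#' size reproduces are reported in the result rather than dropped.
#'
#' @param fixture A fixture from [load_fixture_table()] with `freq_*`/`sig_*`
#'   columns (`table4`, `table5`, `table6`).
#' @param m_options Candidate Bonferroni family sizes; defaults to the
#'   number of panel variants tested in the source study (2174) and that
#'   number times the five populations.
#' @param alpha Family-wise level before correction.
#' @param sizes Population diploid sizes.
#' @return Data frame with one row per cell: the reconstructed counts, `p`,
#'   printed and recomputed significance per family size, and
#'   `reproduced_any`.
#' @export
check_significance_marks <- function(fixture,
                                     m_options = c(2174L, 2174L * 5L),
                                     alpha = 0.05,
                                     sizes = kgp_sizes()) {
  pops <- sub("^freq_", "", grep("^freq_[A-Z]+$", names(fixture), value = TRUE))
  cohort <- recover_allele_count(fixture$freq_cohort)
  rows <- list()
  for (i in seq_len(nrow(fixture))) {
    for (p in pops) {
      f <- fixture[[paste0("freq_", p)]][i]
      if (is.na(f)) next
      ref <- reconstruct_reference_counts(f, sizes[[p]])
      pval <- fisher_exact_2x2(
        cohort$alt_count[i], cohort$called_alleles[i] - cohort$alt_count[i],
        ref$alt_count, ref$ref_count
      )
      calls <- pval < alpha / m_options
      printed <- fixture[[paste0("sig_", p)]][i] == 1L
      row <- data.frame(
        rsid = fixture$rsid[i], population = p,
        cohort_alt = cohort$alt_count[i],
        cohort_alleles = cohort$called_alleles[i],
        ref_alt = ref$alt_count, ref_alleles = ref$alt_count + ref$ref_count,
        p = pval, printed = printed,
        stringsAsFactors = FALSE
      )
      for (k in seq_along(m_options)) {
        row[[paste0("call_m", m_options[k])]] <- calls[k]
      }
      row$reproduced_any <- any(calls == printed)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
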