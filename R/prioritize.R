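#' Sequence Ontology consequence terms by impact severity
#'
#' The standard VEP severity table (Ensembl consequence ordering), embedded
#' so impact assignment does not depend on a live annotation service.
#'
#' @return Named character vector mapping SO term to impact
#'   (`HIGH`, `MODERATE`, `LOW`, `MODIFIER`).
#' @export
so_impact_table <- function() {
  impacts <- list(
    HIGH = c(
      "transcript_ablation", "splice_acceptor_variant", "splice_donor_variant",
      "stop_gained", "frameshift_variant", "stop_lost", "start_lost",
      "transcript_amplification", "feature_elongation", "feature_truncation"
    ),
    MODERATE = c(
      "inframe_insertion", "inframe_deletion", "missense_variant",
      "protein_altering_variant"
    ),
    LOW = c(
      "splice_donor_5th_base_variant", "splice_region_variant",
      "splice_donor_region_variant", "splice_polypyrimidine_tract_variant",
      "incomplete_terminal_codon_variant", "start_retained_variant",
      "stop_retained_variant", "synonymous_variant"
    ),
    MODIFIER = c(
      "coding_sequence_variant", "mature_miRNA_variant",
      "5_prime_UTR_variant", "3_prime_UTR_variant",
      "non_coding_transcript_exon_variant", "intron_variant",
      "NMD_transcript_variant", "non_coding_transcript_variant",
      "coding_transcript_variant", "upstream_gene_variant",
      "downstream_gene_variant", "TFBS_ablation", "TFBS_amplification",
      "TF_binding_site_variant", "regulatory_region_ablation",
      "regulatory_region_amplification", "regulatory_region_variant",
      "intergenic_variant", "sequence_variant"
    )
  )
  out <- unlist(lapply(names(impacts), function(i) {
    stats::setNames(rep(i, length(impacts[[i]])), impacts[[i]])
  }))
  out
}

#' Impact class of a variant from its consequence terms
#'
#' A variant annotated against several transcripts carries several
#' consequence terms; its impact is the most severe across them
#' (HIGH > MODERATE > LOW > MODIFIER).
#'
#' @param consequence_terms Character vector of SO consequence names, or a
#'   single `&`/comma-separated string.
#' @param strict Error on unknown terms instead of warning and treating them
#'   as MODIFIER.
#' @return One of `"HIGH"`, `"MODERATE"`, `"LOW"`, `"MODIFIER"`.
#' @examples
#' impact_of("stop_gained")
#' impact_of(c("intron_variant", "synonymous_variant"))  # LOW
#' @export
impact_of <- function(consequence_terms, strict = FALSE) {
  terms <- unlist(strsplit(as.character(consequence_terms), "[,&]"))
  terms <- trimws(terms)
  terms <- terms[nzchar(terms)]
  if (!length(terms)) return("MODIFIER")
  tab <- so_impact_table()
  unknown <- setdiff(terms, names(tab))
  if (length(unknown)) {
    msg <- sprintf("unknown consequence term(s): %s",
                   paste(unknown, collapse = ", "))
    if (strict) stop(msg)
    warning(msg, call. = FALSE)
  }
  got <- tab[intersect(terms, names(tab))]
  levels <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
  if (!length(got)) return("MODIFIER")
  levels[min(match(got, levels))]
}

#' Default lipid-phenotype keyword lexicon
#'
#' Keywords whose case-insensitive presence in a ClinVar/GWAS trait string
#' marks the trait as related to lipid metabolism or dyslipidemia risk.
#'
#' @return Character vector of keywords.
#' @export
lipid_trait_lexicon <- function() {
  c(
    "cholesterol", "triglycerid", "lipoprotein", "lipoproteinemia",
    "hyperlipid", "dyslipid", "hdl", "ldl", "sitosterol", "lcat",
    "apolipoprotein", "lipid"
  )
}

#' Does any trait string match the lipid-phenotype lexicon?
#'
#' @param traits Character vector of trait strings, or one `|`-separated
#'   string; empty/`NA` traits never match.
#' @param lexicon Non-empty keyword vector (default
#'   [lipid_trait_lexicon()]).
#' @return Logical scalar.
#' @examples
#' lipid_phenotype_match("Familial hypertriglyceridemia")
#' lipid_phenotype_match("Warfarin response")
#' @export
lipid_phenotype_match <- function(traits, lexicon = lipid_trait_lexicon()) {
  stopifnot(length(lexicon) >= 1L)
  traits <- unlist(strsplit(as.character(traits), "|", fixed = TRUE))
  traits <- trimws(traits)
  traits <- traits[!is.na(traits) & nzchar(traits)]
  if (!length(traits)) return(FALSE)
  any(vapply(lexicon, function(k) {
    any(grepl(k, traits, ignore.case = TRUE, fixed = FALSE))
  }, logical(1L)))
}

criterion_matrix <- function(annotations, lexicon) {
  sift_score_ok <- !is.na(annotations$sift_score) & annotations$sift_score < 0.05
  sift_call_ok <- if ("sift_call" %in% names(annotations)) {
    is.na(annotations$sift_score) & !is.na(annotations$sift_call) &
      annotations$sift_call == "deleterious"
  } else FALSE
  cbind(
    sift = sift_score_ok | sift_call_ok,
    polyphen = !is.na(annotations$polyphen_category) &
      annotations$polyphen_category %in% c("P", "D"),
    revel = !is.na(annotations$revel) & annotations$revel > 0.5,
    clinpred = !is.na(annotations$clinpred) & annotations$clinpred > 0.5,
    phenotype = vapply(annotations$traits, lipid_phenotype_match,
                       logical(1L), lexicon = lexicon, USE.NAMES = FALSE)
  )
}

#' Multi-source consensus risk filter
#'
#' Scores each annotated missense variant against five evidence criteria:
#' SIFT deleterious (score < 0.05, or a deleterious call when no score is
#' given), PolyPhen2 possibly/probably damaging (P or D), REVEL > 0.5,
#' ClinPred > 0.5, and a ClinVar/GWAS trait matching the lipid-phenotype
#' lexicon. A variant qualifies when at least `min_sources` criteria hold
#' and its cohort alternate-allele count is at least `min_alt_count`.
#' Missing scores count as criterion-false.
#'
#' @param annotations Data frame keyed by `rsid` with columns `sift_score`,
#'   `polyphen_category`, `revel`, `clinpred`, `traits` (optionally
#'   `sift_call`, `gene`, `consequence`, `alt_count`). When a `consequence`
#'   column is present only rows containing `missense_variant` are scored.
#' @param alt_counts Named vector of alternate-allele counts by rsid; may be
#'   omitted when `annotations` carries an `alt_count` column.
#' @param min_sources Minimum satisfied criteria (default 3).
#' @param min_alt_count Minimum cohort alternate-allele count (default 2,
#'   i.e. more than a single observed copy).
#' @param lexicon Lipid-phenotype keyword lexicon.
#' @return Data frame of risk calls: per-criterion logicals, `n_criteria`,
#'   `alt_count` and `qualifies`.
#' @export
consensus_filter <- function(annotations, alt_counts = NULL,
                             min_sources = 3L, min_alt_count = 2L,
                             lexicon = lipid_trait_lexicon()) {
  stopifnot(is.data.frame(annotations), "rsid" %in% names(annotations))
  if (!"traits" %in% names(annotations)) annotations$traits <- ""
  for (col in c("sift_score", "revel", "clinpred")) {
    if (!col %in% names(annotations)) annotations[[col]] <- NA_real_
  }
  if (!"polyphen_category" %in% names(annotations)) {
    annotations$polyphen_category <- NA_character_
  }
  if ("consequence" %in% names(annotations)) {
    annotations <- annotations[grepl("missense_variant",
                                     annotations$consequence), , drop = FALSE]
  }
  crit <- criterion_matrix(annotations, lexicon)
  alt <- if (!is.null(alt_counts)) {
    as.integer(alt_counts[annotations$rsid])
  } else if ("alt_count" %in% names(annotations)) {
    as.integer(annotations$alt_count)
  } else {
    stop("provide alt_counts or an alt_count column")
  }
  out <- data.frame(
    rsid = annotations$rsid,
    gene = if ("gene" %in% names(annotations)) annotations$gene else NA_character_,
    crit, stringsAsFactors = FALSE
  )
  out$n_criteria <- as.integer(rowSums(crit))
  out$alt_count <- alt
  out$qualifies <- out$n_criteria >= min_sources &
    !is.na(alt) & alt >= min_alt_count
  rownames(out) <- NULL
  out
}

#' Flag pharmacogenomic and protective variants
#'
#' Categories derive from the ClinVar significance classes and trait
#' strings: a `drug response` class or a trait mentioning a drug response
#' flags `drug_response`; a `protective` class or a protection-against
#' trait (including the common "potection" transcription) flags
#' `protective`; variants with both get `both`.
#'
#' @param annotations Data frame with `rsid`, `traits` and optionally
#'   `clin_sig` (one or more `|`-separated significance classes).
#' @return Data frame with `rsid` and `category` in
#'   `{drug_response, protective, both, none}`.
#' @export
pharmaco_protective_flags <- function(annotations) {
  stopifnot(is.data.frame(annotations), "rsid" %in% names(annotations))
  traits <- if ("traits" %in% names(annotations)) annotations$traits else ""
  sig <- if ("clin_sig" %in% names(annotations)) annotations$clin_sig else ""
  traits[is.na(traits)] <- ""
  sig[is.na(sig)] <- ""
  drug <- grepl("drug response", sig, ignore.case = TRUE) |
    grepl("response", traits, ignore.case = TRUE)
  prot <- grepl("protective", sig, ignore.case = TRUE) |
    grepl("protect|potection", traits, ignore.case = TRUE)
  category <- ifelse(drug & prot, "both",
                     ifelse(drug, "drug_response",
                            ifelse(prot, "protective", "none")))
  data.frame(rsid = annotations$rsid, category = category,
             stringsAsFactors = FALSE)
}

#' Match cohort variants against previously reported variants
#'
#' Intersects cohort rsIDs with a curated list of variants previously
#' reported in the region's lipid/dyslipidemia literature, with source
#' attribution. The bundled default is the prior-report fixture table.
#'
#' @param rsids Character vector of cohort rsIDs (duplicates collapse to one
#'   match).
#' @param curated Data frame with columns `rsid` and `source`; defaults to
#'   the bundled prior-report table.
#' @return Data frame of matched `rsid`/`source` pairs (zero rows when
#'   nothing matches).
#' @export
prior_report_match <- function(rsids, curated = NULL) {
  if (is.null(curated)) {
    curated <- load_fixture_table("table6")[, c("rsid", "source")]
  }
  stopifnot(all(c("rsid", "source") %in% names(curated)))
  hits <- curated[curated$rsid %in% unique(stats::na.omit(rsids)), , drop = FALSE]
  hits <- hits[!duplicated(hits$rsid), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

route_rsids <- function(x) {
  if (is.null(x)) return(character(0L))
  if (is.data.frame(x)) as.character(x$rsid) else as.character(x)
}

#' Assemble the deduplicated variants-of-interest table
#'
#' Takes the four selection routes — consensus risk, high VEP impact,
#' pharmacogenomic/protective, prior report — and returns their union,
#' deduplicated by rsID, recording every route that selected each variant.
#' For the consensus route only qualifying calls are used. Variants without
#' an rsID should be keyed as `chrom:pos:ref:alt` before assembly.
#'
#' @param consensus Risk calls from [consensus_filter()] (rows with
#'   `qualifies = TRUE` are used), or an rsid vector.
#' @param high_impact rsIDs (or data frame with `rsid`) of HIGH-impact
#'   variants.
#' @param pharmaco Output of [pharmaco_protective_flags()] (rows with a
#'   category other than `none` are used), or an rsid vector.
#' @param prior_report Output of [prior_report_match()], or an rsid vector.
#' @param positions Optional data frame with `rsid`, `chrom`, `pos` used to
#'   order the result by genomic position.
#' @return Data frame with `rsid`, `routes` (comma-separated), `n_routes`.
#' @export
assemble_voi <- function(consensus = NULL, high_impact = NULL,
                         pharmaco = NULL, prior_report = NULL,
                         positions = NULL) {
  if (is.data.frame(consensus) && "qualifies" %in% names(consensus)) {
    consensus <- consensus[consensus$qualifies, , drop = FALSE]
  }
  if (is.data.frame(pharmaco) && "category" %in% names(pharmaco)) {
    pharmaco <- pharmaco[pharmaco$category != "none", , drop = FALSE]
  }
  routes <- list(
    consensus_risk = unique(route_rsids(consensus)),
    high_impact = unique(route_rsids(high_impact)),
    pharmaco_protective = unique(route_rsids(pharmaco)),
    prior_report = unique(route_rsids(prior_report))
  )
  all_ids <- unique(unlist(routes))
  if (!length(all_ids)) {
    return(data.frame(rsid = character(0L), routes = character(0L),
                      n_routes = integer(0L)))
  }
  route_str <- vapply(all_ids, function(id) {
    paste(names(routes)[vapply(routes, function(r) id %in% r, logical(1L))],
          collapse = ",")
  }, character(1L))
  out <- data.frame(
    rsid = all_ids,
    routes = route_str,
    n_routes = lengths(strsplit(route_str, ",", fixed = TRUE)),
    stringsAsFactors = FALSE
  )
  if (!is.null(positions) && all(c("rsid", "chrom", "pos") %in% names(positions))) {
    idx <- match(out$rsid, positions$rsid)
    out <- out[order(positions$chrom[idx], positions$pos[idx],
                     is.na(idx), out$rsid), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
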