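#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the cohort the pipeline was designed around: 258 diploid
#' samples and 2,600 variant sites in the 69-gene panel, with 140/2600
#' indels, 2.9% multiallelic records, a 2.33 transition:transversion odds
#' target among SNVs, 2553/2600 dbSNP-known sites, a rare-skewed beta
#' allele-frequency spectrum, light missingness matching per-site called
#' denominators of 514-516 of 516 alleles, and 18/2600 consensus-risk
#' variants.
#'
#' @param n_samples Number of diploid samples.
#' @param n_sites Number of variant sites to place in the panel.
#' @param titv_target Transition:transversion odds among simulated SNV
#'   alternate alleles.
#' @param indel_fraction,multiallelic_fraction,missing_rate,known_rate
#'   Probabilities in `[0, 1]` (`missing_rate < 1`).
#' @param freq_shape1,freq_shape2 Beta parameters of the alternate-allele
#'   frequency distribution.
#' @param risk_fraction Fraction of sites given >= 3 qualifying annotation
#'   criteria.
#' @param divergence Logit-scale standard deviation of per-population
#'   frequency perturbations in the simulated reference panel.
#' @param n_differential Number of sites given a fixed frequency shift of
#'   `differential_delta` in every reference population (the true
#'   differential set).
#' @param differential_delta Absolute frequency shift of differential sites.
#' @param populations Named diploid sizes of the simulated reference
#'   populations.
#' @param seed Integer seed; fixes the full output. Stage-specific
#'   substreams derive from it so stages can be regenerated in isolation.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 258L, n_sites = 2600L,
                       titv_target = 2.33,
                       indel_fraction = 140 / 2600,
                       multiallelic_fraction = 0.029,
                       missing_rate = 0.004,
                       known_rate = 2553 / 2600,
                       freq_shape1 = 0.3, freq_shape2 = 2.7,
                       risk_fraction = 18 / 2600,
                       divergence = 0.3,
                       n_differential = 0L,
                       differential_delta = 0.3,
                       populations = kgp_sizes(),
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_sites = as.integer(n_sites),
    titv_target = titv_target, indel_fraction = indel_fraction,
    multiallelic_fraction = multiallelic_fraction,
    missing_rate = missing_rate, known_rate = known_rate,
    freq_shape1 = freq_shape1, freq_shape2 = freq_shape2,
    risk_fraction = risk_fraction, divergence = divergence,
    n_differential = as.integer(n_differential),
    differential_delta = differential_delta,
    populations = populations, seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_samples >= 1L, cfg$n_sites >= 1L, cfg$titv_target > 0,
    cfg$indel_fraction >= 0, cfg$indel_fraction <= 1,
    cfg$multiallelic_fraction >= 0, cfg$multiallelic_fraction <= 1,
    cfg$missing_rate >= 0, cfg$missing_rate < 1,
    cfg$known_rate >= 0, cfg$known_rate <= 1,
    cfg$freq_shape1 > 0, cfg$freq_shape2 > 0,
    cfg$risk_fraction >= 0, cfg$risk_fraction <= 1,
    cfg$divergence >= 0, cfg$n_differential >= 0,
    cfg$differential_delta >= 0, cfg$differential_delta <= 1,
    length(cfg$populations) >= 1L, !is.null(names(cfg$populations)),
    !is.na(cfg$seed), abs(cfg$seed) < 2^31 - 1000
  )
  class(cfg) <- "sim_config"
  cfg
}

# run code under a stage-specific seed, leaving the caller's RNG untouched
with_substream <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# one key per decomposed child: the rsID where it is unambiguous, the full
# chrom:pos:ref:alt id for novel sites and for children of multiallelic
# records (which share the parent rsID)
decomposed_site_keys <- function(sites) {
  if (!"alt" %in% names(sites)) {
    return(ifelse(is.na(sites$rsid),
                  paste(sites$chrom, sites$pos, sites$ref, sep = ":"),
                  sites$rsid))
  }
  ifelse(is.na(sites$rsid) | sites$allelism == "multiallelic",
         site_ids(sites), sites$rsid)
}

BASES <- c("A", "C", "G", "T")
TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

draw_snv_alt <- function(ref, titv_odds, exclude = character(0L)) {
  ti <- TRANSITION_PARTNER[[ref]]
  tv <- setdiff(BASES, c(ref, ti))
  ti <- setdiff(ti, exclude)
  tv <- setdiff(tv, exclude)
  if (!length(ti)) return(sample(tv, 1L))
  if (!length(tv)) return(ti)
  if (stats::runif(1L) < titv_odds / (1 + titv_odds)) ti else sample(tv, 1L)
}

random_seq <- function(len) paste(sample(BASES, len, replace = TRUE),
                                  collapse = "")

draw_indel_alleles <- function(n_alt) {
  anchor <- sample(BASES, 1L)
  if (stats::runif(1L) < 0.5) {
    ref <- anchor
    alts <- character(n_alt)
    repeat {
      alts <- vapply(seq_len(n_alt),
                     function(i) paste0(anchor, random_seq(sample(1:3, 1L))),
                     character(1L))
      if (!anyDuplicated(alts)) break
    }
  } else {
    ref <- paste0(anchor, random_seq(sample(1:3, 1L)))
    alts <- anchor
    if (n_alt > 1L) {
      alts <- c(alts, paste0(anchor, random_seq(nchar(ref) + 1L)))
    }
  }
  list(ref = ref, alts = alts)
}

#' Simulate variant sites within a gene panel
#'
#' Positions are drawn uniformly without collision from the panel intervals;
#' SNV substitution types are drawn so the expected transition:transversion
#' odds equals `titv_target`; indel and multiallelic fractions, dbSNP-known
#' fraction and the beta allele-frequency spectrum follow the
#' configuration.
#'
#' @param panel A `gene_panel`.
#' @param cfg A `sim_config`.
#' @return List with `sites` (parent-level data frame: `chrom`, `pos`,
#'   `ref`, `alts` comma-separated, `rsid`, `variant_class`, `allelism`)
#'   and `freqs` (list of per-alternate true frequencies, one element per
#'   site).
#' @export
simulate_sites <- function(panel, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  iv <- if (inherits(panel, "gene_panel")) panel$intervals else panel
  stopifnot(nrow(iv) >= 1L)
  widths <- iv$end - iv$start + 1L
  total <- sum(widths)
  if (cfg$n_sites > total) {
    stop(sprintf("n_sites (%d) exceeds available panel positions (%d)",
                 cfg$n_sites, total))
  }
  with_substream(cfg$seed + 101L, {
    offsets <- sort(sample.int(total, cfg$n_sites))
    cum <- cumsum(widths)
    ividx <- findInterval(offsets - 1L, c(0L, cum), rightmost.closed = FALSE)
    pos <- iv$start[ividx] + (offsets - c(0L, cum)[ividx] - 1L)
    chrom <- iv$chrom[ividx]
    is_indel <- stats::runif(cfg$n_sites) < cfg$indel_fraction
    is_multi <- stats::runif(cfg$n_sites) < cfg$multiallelic_fraction
    known <- stats::runif(cfg$n_sites) < cfg$known_rate
    refs <- character(cfg$n_sites)
    alts <- vector("list", cfg$n_sites)
    for (i in seq_len(cfg$n_sites)) {
      n_alt <- if (is_multi[i]) 2L else 1L
      if (is_indel[i]) {
        al <- draw_indel_alleles(n_alt)
        refs[i] <- al$ref
        alts[[i]] <- al$alts
      } else {
        refs[i] <- sample(BASES, 1L)
        a1 <- draw_snv_alt(refs[i], cfg$titv_target)
        alts[[i]] <- if (n_alt == 2L) {
          c(a1, draw_snv_alt(refs[i], cfg$titv_target, exclude = a1))
        } else a1
      }
    }
    freqs <- lapply(alts, function(a) {
      p <- stats::rbeta(length(a), cfg$freq_shape1, cfg$freq_shape2)
      if (length(a) > 1L) p[2L] <- p[2L] * (1 - p[1L])
      p
    })
    cls <- lapply(seq_len(cfg$n_sites),
                  function(i) classify_variant(refs[i], alts[[i]]))
    sites <- data.frame(
      chrom = chrom, pos = pos, ref = refs,
      alts = vapply(alts, paste, character(1L), collapse = ","),
      rsid = ifelse(known,
                    sprintf("rs9%08d", seq_len(cfg$n_sites)),
                    NA_character_),
      variant_class = vapply(cls, `[[`, "", "variant_class"),
      allelism = vapply(cls, `[[`, "", "allelism"),
      stringsAsFactors = FALSE
    )
    list(sites = sites, freqs = freqs)
  })
}

#' Simulate diploid genotypes under Hardy-Weinberg equilibrium
#'
#' For a biallelic site at alternate frequency `p`, dosages are drawn
#' i.i.d. across samples with probabilities `((1-p)^2, 2p(1-p), p^2)`;
#' multiallelic sites draw two alleles per sample from the allele
#' frequencies and are decomposed into per-alternate children. A missing
#' mask is applied per (sample, parent site) at `missing_rate`.
#'
#' @param sim Output of [simulate_sites()], or a plain numeric vector of
#'   biallelic alternate frequencies (sites then get synthetic SNV alleles).
#' @param cfg A `sim_config`.
#' @return A `genotype_matrix` of decomposed biallelic sites.
#' @export
simulate_genotypes <- function(sim, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.numeric(sim)) {
    stopifnot(all(sim >= 0 & sim <= 1))
    sim <- list(
      sites = data.frame(
        chrom = "chr1", pos = seq_along(sim) * 10L, ref = "A", alts = "G",
        rsid = sprintf("rs9%08d", seq_along(sim)),
        variant_class = "SNV", allelism = "biallelic",
        stringsAsFactors = FALSE
      ),
      freqs = as.list(sim)
    )
  }
  sites <- sim$sites
  freqs <- sim$freqs
  n <- cfg$n_samples
  with_substream(cfg$seed + 202L, {
    child_sites <- list()
    child_codes <- list()
    for (i in seq_len(nrow(sites))) {
      p <- freqs[[i]]
      alts <- strsplit(sites$alts[i], ",", fixed = TRUE)[[1L]]
      if (length(alts) == 1L) {
        codes <- matrix(stats::rbinom(n, 2L, p), ncol = 1L)
      } else {
        probs <- c(1 - sum(p), p)
        a1 <- sample.int(3L, n, replace = TRUE, prob = probs) - 1L
        a2 <- sample.int(3L, n, replace = TRUE, prob = probs) - 1L
        codes <- cbind((a1 == 1L) + (a2 == 1L), (a1 == 2L) + (a2 == 2L))
      }
      if (cfg$missing_rate > 0) {
        miss <- stats::runif(n) < cfg$missing_rate
        codes[miss, ] <- NA_integer_
      }
      parent <- paste(sites$chrom[i], sites$pos[i], sites$ref[i], sep = ":")
      for (k in seq_along(alts)) {
        cls <- classify_variant(sites$ref[i], alts[k])
        child_sites[[length(child_sites) + 1L]] <- data.frame(
          chrom = sites$chrom[i], pos = sites$pos[i], ref = sites$ref[i],
          alt = alts[k], rsid = sites$rsid[i],
          variant_class = cls$variant_class,
          allelism = sites$allelism[i], parent_id = parent,
          stringsAsFactors = FALSE
        )
        child_codes[[length(child_codes) + 1L]] <- codes[, k]
      }
    }
    gm <- genotype_matrix(
      do.call(cbind, child_codes),
      do.call(rbind, child_sites),
      sample_ids = sprintf("SIM%04d", seq_len(n))
    )
    attr(gm, "true_freq") <- stats::setNames(
      unlist(freqs),
      site_ids(gm$sites)
    )
    gm
  })
}

lipid_trait_pool <- function() {
  c("LDL cholesterol levels", "Total cholesterol levels",
    "Hypertriglyceridemia", "Familial hypercholesterolemia",
    "HDL cholesterol levels", "Triglyceride levels",
    "Apolipoprotein B levels", "Dyslipidemia risk")
}

neutral_trait_pool <- function() {
  c("", "", "", "Asthma", "Body height", "Eye color")
}

#' Simulate annotation records with known risk labels
#'
#' A `risk_fraction` subset of sites receives 3 to 5 satisfied criteria
#' among SIFT < 0.05, PolyPhen2 in {P, D}, REVEL > 0.5, ClinPred > 0.5 and
#' a lipid-related trait; all other sites receive at most 2. Unsatisfied
#' numeric scores fall outside the qualifying range or are missing. All
#' records are marked `missense_variant` so the consensus filter scores
#' every one. The designed labels are returned alongside for
#' parameter-recovery checks.
#'
#' @param sites A `genotype_matrix`, or its decomposed `sites` data frame.
#' @param cfg A `sim_config`.
#' @return Annotation data frame with the columns consumed by
#'   [consensus_filter()] plus `designed_n_criteria` and `designed_risk`.
#' @export
simulate_annotations <- function(sites, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (inherits(sites, "genotype_matrix")) sites <- sites$sites
  stopifnot(nrow(sites) >= 1L)
  key <- decomposed_site_keys(sites)
  n <- nrow(sites)
  with_substream(cfg$seed + 303L, {
    risk <- stats::runif(n) < cfg$risk_fraction
    n_crit <- ifelse(risk, sample(3:5, n, replace = TRUE),
                     sample(0:2, n, replace = TRUE))
    sift <- rep(NA_real_, n)
    poly <- rep(NA_character_, n)
    revel <- rep(NA_real_, n)
    clinp <- rep(NA_real_, n)
    traits <- character(n)
    for (i in seq_len(n)) {
      on <- rep(FALSE, 5L)
      if (n_crit[i] > 0L) on[sample.int(5L, n_crit[i])] <- TRUE
      sift[i] <- if (on[1L]) stats::runif(1, 0, 0.049)
        else if (stats::runif(1) < 0.7) stats::runif(1, 0.06, 1) else NA_real_
      poly[i] <- if (on[2L]) sample(c("P", "D"), 1L)
        else if (stats::runif(1) < 0.7) "B" else NA_character_
      revel[i] <- if (on[3L]) stats::runif(1, 0.51, 0.99)
        else if (stats::runif(1) < 0.7) stats::runif(1, 0, 0.49) else NA_real_
      clinp[i] <- if (on[4L]) stats::runif(1, 0.51, 0.99)
        else if (stats::runif(1) < 0.7) stats::runif(1, 0, 0.49) else NA_real_
      traits[i] <- if (on[5L]) sample(lipid_trait_pool(), 1L)
        else sample(neutral_trait_pool(), 1L)
    }
    data.frame(
      rsid = key,
      gene = NA_character_,
      consequence = "missense_variant",
      sift_score = sift, sift_call = NA_character_,
      polyphen_category = poly, revel = revel, clinpred = clinp,
      traits = traits,
      designed_n_criteria = as.integer(n_crit),
      designed_risk = risk,
      stringsAsFactors = FALSE
    )
  })
}

#' Deterministic decoy annotation records
#'
#' Builds `n` annotation records that satisfy at most two of the five
#' consensus criteria (cycling through 0, 1 and 2 satisfied criteria over
#' the five criterion slots) with a generous alternate-allele count, for use
#' as negative controls alongside fixture records.
#'
#' @param n Number of decoys (default 20).
#' @return Annotation data frame compatible with [consensus_filter()].
#' @export
decoy_annotations <- function(n = 20L) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  out <- data.frame(
    rsid = sprintf("rsDECOY%03d", seq_len(n)),
    gene = sprintf("DECOYGENE%02d", seq_len(n)),
    consequence = "missense_variant",
    sift_score = NA_real_, sift_call = NA_character_,
    polyphen_category = NA_character_,
    revel = NA_real_, clinpred = NA_real_,
    traits = "", alt_count = 10L,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    k <- (i - 1L) %% 3L            # 0, 1 or 2 criteria satisfied
    slots <- ((i + seq_len(5L)) %% 5L)[seq_len(k)] + 1L
    if (1L %in% slots) out$sift_score[i] <- 0.01
    if (2L %in% slots) out$polyphen_category[i] <- "D"
    if (3L %in% slots) out$revel[i] <- 0.8
    if (4L %in% slots) out$clinpred[i] <- 0.8
    if (5L %in% slots) out$traits[i] <- "LDL cholesterol levels"
    if (!1L %in% slots) out$sift_score[i] <- 0.5
    if (!2L %in% slots) out$polyphen_category[i] <- "B"
  }
  out
}

#' Simulate a reference population frequency panel
#'
#' Starts from the cohort's true site frequencies, perturbs each population
#' on the logit scale with noise of standard deviation `divergence`, then
#' applies a fixed shift of `differential_delta` (upward when the base
#' frequency is below 0.5, downward otherwise, clipped to `[0, 1]`) to a
#' designated differential subset of `n_differential` sites shared by all
#' populations. The differential site keys are returned as ground truth.
#'
#' @param freqs Named numeric vector of true alternate-allele frequencies
#'   (names are rsIDs/site keys), e.g. `attr(gm, "true_freq")` renamed by
#'   rsid.
#' @param cfg A `sim_config`.
#' @return List with `panel` (a `pop_freq_panel`) and `differential`
#'   (character vector of shifted keys).
#' @export
simulate_reference_panel <- function(freqs, cfg) {
  stopifnot(inherits(cfg, "sim_config"), !is.null(names(freqs)),
            all(freqs >= 0 & freqs <= 1))
  n <- length(freqs)
  if (cfg$n_differential > n) {
    stop("n_differential exceeds the number of sites")
  }
  with_substream(cfg$seed + 404L, {
    diff_idx <- if (cfg$n_differential > 0L) {
      sort(sample.int(n, cfg$n_differential))
    } else integer(0L)
    rows <- lapply(names(cfg$populations), function(popn) {
      p <- freqs
      if (cfg$divergence > 0) {
        z <- stats::qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6))
        p <- stats::plogis(z + stats::rnorm(n, 0, cfg$divergence))
        p[freqs == 0] <- 0
        p[freqs == 1] <- 1
      }
      if (length(diff_idx)) {
        base <- freqs[diff_idx]
        p[diff_idx] <- ifelse(base <= 0.5,
                              pmin(1, base + cfg$differential_delta),
                              pmax(0, base - cfg$differential_delta))
      }
      data.frame(
        rsid = names(freqs), population = popn, alt_freq = unname(p),
        n_diploid = unname(cfg$populations[popn]),
        stringsAsFactors = FALSE
      )
    })
    list(
      panel = pop_freq_panel(do.call(rbind, rows)),
      differential = names(freqs)[diff_idx]
    )
  })
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper chaining [simulate_sites()], [simulate_genotypes()],
#' [simulate_annotations()] and [simulate_reference_panel()] under one
#' configuration.
#'
#' @param cfg A `sim_config`.
#' @param panel A `gene_panel` (default: the synthetic 69-gene layout).
#' @return List with `config`, `sites`, `freqs`, `genotypes`,
#'   `annotations`, `reference` (panel + differential keys).
#' @export
simulate_cohort <- function(cfg = sim_config(), panel = synthetic_panel()) {
  sim <- simulate_sites(panel, cfg)
  gm <- simulate_genotypes(sim, cfg)
  ann <- simulate_annotations(gm, cfg)
  key <- decomposed_site_keys(gm$sites)
  true_freq <- stats::setNames(unname(attr(gm, "true_freq")), key)
  ref <- simulate_reference_panel(true_freq, cfg)
  list(config = cfg, sites = sim$sites, freqs = true_freq,
       genotypes = gm, annotations = ann, reference = ref)
}
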