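---
title: "Methods: gene-panel variant prioritization for dyslipidemia cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-panel variant prioritization for dyslipidemia cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipivar)
```

# The problem and the data model

Dyslipidemia genetics concentrates on a panel of genes whose variants shift
blood lipid levels: lipases (*LPL*, *LIPC*, *LCAT*), the apolipoprotein
family, ABC sterol transporters (*ABCA1*, *ABCG5/8*), receptors and
regulators (*LDLR*, *PCSK9*, *GCKR*, ...). Given a called multi-sample VCF
for a cohort, the pipeline subsets it to such a panel, computes quality
metrics, contrasts allele frequencies with reference populations, and
prioritizes variants of interest through four complementary routes.

Internally everything runs on two containers. A `gene_panel` holds 1-based
inclusive intervals per gene, extended by a flank (default 300 bp, the
margin used when the panel's transcript coordinates were extracted) and
merged so intervals per chromosome are disjoint and sorted; BED input is
converted from 0-based half-open coordinates on read, and contig names are
normalized to the panel's `chr`-prefix dialect. A `genotype_matrix` holds
samples × biallelic sites with dosage codes 0/1/2/`NA`. Multiallelic VCF
records are decomposed into one child per alternate allele, each child
counting copies of that alternate only; the decomposition conserves
alternate-allele copies, half-calls (`./1`) are conservatively treated as
missing, and phase is ignored since only dosage enters any downstream
statistic. Children remember their parent record, so writing a cohort back
to VCF re-joins them and the write/read round trip is exact. Records whose
FILTER is neither `PASS` nor `.` are dropped by default (site-level
recalibration is assumed applied upstream by the caller's pipeline), with a
flag to retain them.

# Population frequency contrasts

For each variant and reference population the test is Fisher's exact test
on the 2×2 table (cohort alt/ref counts vs reference alt/ref counts),
two-sided by the standard convention: the p-value sums hypergeometric
probabilities of all tables with the observed margins whose probability
does not exceed the observed table's, with a `1 + 1e-7` relative tolerance
for ties. Two-sidedness is the right default because the question is
whether frequencies *differ*, with no direction privileged.

Reference panels publish frequencies, not counts. Because published
frequencies are exact rationals (allele count over `2 × n_diploid`
chromosomes), `reconstruct_reference_counts()` recovers the integers
exactly by rounding `freq × 2N`. On the cohort side, the per-site
denominator varies with missingness; `recover_allele_count()` inverts a
printed frequency by searching candidate even denominators (default
500–516, bracketing a 258-sample cohort) for the best-reproducing count.

Significance uses a Bonferroni threshold `α / m`. The family size is
genuinely ambiguous in this kind of analysis: one can count variants tested
per population or variants × populations. `compare_to_reference()` defaults
to the per-population family (each population's comparison is its own
family), exposes `family = "all_tests"`, and accepts an explicit `m` for
when the tested panel is a subset of a larger family — the bundled reported
tables were tested within a family of 2,174 panel variants, and
`check_significance_marks()` verifies that recomputed calls reproduce every
printed significance mark of the bundled tables under that family. Variants
absent from a population (`NA` frequency) are skipped for that population
rather than imputed at zero frequency.

# The consensus risk rule and companion routes

A missense variant is a *consensus risk variant* when at least
`min_sources = 3` of five criteria hold:

1. SIFT score < 0.05 (or a "deleterious" call when only the call is
   available);
2. PolyPhen2 category P (possibly damaging) or D (probably damaging);
3. REVEL > 0.5;
4. ClinPred > 0.5;
5. a ClinVar or GWAS-catalog trait related to lipid metabolism or
   dyslipidemia risk;

and the cohort carries the alternate allele at least `min_alt_count = 2`
times (more than a single observed copy, screening out singletons that
cannot be distinguished from call errors). Missing scores count as
criterion-false rather than shrinking the denominator: the rule counts
satisfied criteria, not available ones. Criterion 5 uses a configurable
keyword lexicon (`lipid_trait_lexicon()`: cholesterol, triglycerid,
lipoprotein, hyperlipid, dyslipid, HDL, LDL, sitosterol, LCAT,
apolipoprotein, lipid) because no closed enumeration of "lipid-related"
trait strings exists; case-insensitive substring matching is deliberate so
that composite GWAS trait names match. Either ClinVar or GWAS traits
satisfy the criterion.

The companion routes are: impact classing (`impact_of()`, the embedded
Sequence Ontology severity table, taking the most severe consequence
across a variant's transcript annotations — HIGH variants such as
stop-gained/start-lost form their own route); pharmacogenomic/protective
flagging from ClinVar significance classes with trait-string fallbacks
(including the "potection" spelling that occurs in circulating annotation
text); and matching against a curated list of variants previously reported
in regional lipid studies (bundled: `load_fixture_table("table6")`).
`assemble_voi()` unions the four routes deduplicated by rsID, recording
route provenance; variants without an rsID should be keyed
`chrom:pos:ref:alt` — the same fallback key the rest of the package uses.

One annotation ambiguity is worth recording: among the nine bundled
pharmacogenomic/protective variants, the trait strings support eight
drug-response and one protective variant (only the *MTTP* variant carries a
protection-against trait; the *HMGCR* statin-attenuation trait is a drug
response). Narrative descriptions of this split vary; the route total of
nine is the stable quantity and is what the tests pin down.

# The synthetic cohort generator

Real cohorts of this kind are access-controlled, so the generator
(`sim_config()`, `simulate_cohort()`) emulates the statistical structure
the analysis assumes. Defaults are fixed to the emulated study conditions:
258 diploid samples; 2,600 sites across the panel; 140/2600 indels; 2.9%
multiallelic records; 2553/2600 dbSNP-known sites; transition:transversion
odds 2.33 (the reported cohort mean); missingness 0.004 per genotype,
matching per-site called denominators of 514–516 out of 516 alleles;
alternate-allele frequencies from Beta(0.3, 2.7), rare-skewed because most
panel variants sit below frequency 0.1; and 18/2600 sites designed to meet
three or more consensus criteria. Genotypes are drawn per site i.i.d.
across samples with Hardy–Weinberg probabilities ((1−p)², 2p(1−p), p²);
multiallelic sites draw two alleles per sample from the allele-frequency
vector and are decomposed like VCF input. Reference panels perturb the
true frequencies per population on the logit scale (sd = `divergence`,
default 0.3 — roughly the spread separating continental super-populations
at common variants) and optionally shift a designated differential subset
by a fixed `differential_delta` (default 0.3), returning the shifted keys
as ground truth. One global seed drives fixed per-stage substreams
(sites +101, genotypes +202, annotations +303, reference +404), so any
stage can be regenerated in isolation and the full output is reproducible
byte for byte.

Two design notes. First, a reference base has exactly one transition
partner, so a two-alternate SNV can contribute at most one transition
child; with multiallelic records present, the realized Ti/Tv of decomposed
children therefore sits slightly below the per-draw target (≈1.89 for a
2.0 target at 2.9% multiallelics). The target governs each substitution
draw; convergence checks of the Ti/Tv estimator use SNV-only biallelic
cohorts, where the estimand is clean. Second, children of simulated
multiallelic records are keyed by `chrom:pos:ref:alt` rather than the
shared parent rsID wherever a unique per-child key is required
(annotations, reference panels).

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: linkage disequilibrium (sites are
independent), relatedness and population substructure within the cohort,
genotype-dependent missingness, sequencing or calling error (genotypes are
exact draws from the design frequencies), and correlated annotation scores
(real SIFT/PolyPhen2/REVEL/ClinPred scores are strongly correlated;
simulated criteria are assigned independently given the designed count).
Tests on synthetic cohorts validate the *estimators and rules*, not the
upstream calling quality of any real dataset.

# Quality metrics

`sample_qc()` counts, per sample, the variant sites carried (dosage 1
or 2) — site-carrying rather than allele-copy counting, the standard exome
QC semantics — splitting SNVs into transitions (A↔G, C↔T) and
transversions, exome-wide or per chromosome (the per-chromosome counts sum
exactly to exome-wide), optionally restricted to dbSNP-known sites; both
restriction modes are provided since either may be wanted when comparing
against published per-individual figures. Ratios with zero denominators
(no transversions, no hom-alt calls) are flagged `NA`, never errors.
Cohort comparisons use Welch's two-sided t-test — the unequal-variance
form is the safe default when only "a t-test" is specified — with a
variance floor of 1e-12 so degenerate constant inputs yield p = 1
(identical) or a near-zero p (separated) instead of an error. Under
Hardy–Weinberg at frequency p the per-sample Het/non-ref-Hom ratio has
expectation 2(1−p)/p, which the tests verify at p = 0.5. Context only, not
test targets: whole-exome studies of this kind report cohort means around
Ti/Tv 2.33 and Het/non-ref-Hom 1.66 — both depend on the real data's
region definition and ancestry and cannot be reproduced from synthetic
cohorts.

# Burden and ancestry

`burden_per_sample()` counts heterozygous and homozygous-alternate sites
per sample within each class of a site→class assignment (impact classes,
or the VOI set); each variant belongs to exactly one class (its most
severe impact), which preserves the identity `n_total = n_het + n_hom_alt`
and makes class-wise burden sum to union burden over a partition.
Unassigned sites land in an explicit `unclassified` bucket rather than
vanishing.

`build_aim_matrix()` merges labeled cohorts over a requested AIM list and
keeps only markers with complete genotypes everywhere — complete-case by
construction, with dropped markers reported. `pca_genotypes()` centers the
dosage columns without unit-variance scaling (the analysis operates on raw
alternate-allele counts; scaling would up-weight rare markers), pools all
cohorts into one decomposition rather than projecting the cohort onto
reference-only axes (pooling is the simplest defensible choice when the
cohort is not tiny relative to the references), and fixes each component's
sign by forcing its largest-magnitude loading positive so plots are
reproducible across platforms. A constant matrix returns all-zero
coordinates. `export_population_frequencies()` emits per-population AIM
frequencies in the shape external tree/admixture tools consume. Admixture
inference itself (STRUCTURE-style MCMC, TreeMix likelihoods) is out of
scope: those tools consume this package's exports.

# Numerical choices and validation scale

- Fisher ties use the conventional `1 + 1e-7` relative tolerance; the
  implementation is checked exhaustively against brute-force hypergeometric
  enumeration over all 2×2 tables with margins ≤ 30 (about 164,000 tables)
  at 1e-12, and spot-checked against `stats::fisher.test`.
- Bonferroni significant-counts are monotone non-increasing in the family
  size, which the tests assert directly.
- The validation suite's problem sizes are chosen to make sampling error
  negligible relative to the tolerances while keeping the default test run
  fast: 10,000-site cohorts for Ti/Tv convergence (binomial composition
  error ±3 SE ≈ 0.13 on the ratio); 5,000 sites × 250 samples with 250
  differential sites at |Δp| = 0.3 against a 2,504-diploid reference for
  power/size recovery; 1,000 sites × 400 samples for Hardy–Weinberg
  goodness of fit; 1,000 replicates for the t-test type-I error rate.
- Seeds are fixed throughout the suite; the generator is deterministic per
  seed, and stage substreams keep regenerated stages identical.

# Known limitations

- The consensus rule consumes annotation scores as inputs; it never
  recomputes SIFT/PolyPhen2/REVEL/ClinPred, and no live annotation service
  is queried.
- The lipid-phenotype lexicon is substring-based; exotic trait phrasings
  outside the lexicon produce criterion-false, and over-broad keywords
  could over-match — the lexicon is a tunable argument for exactly this
  reason.
- Count reconstruction from printed frequencies assumes the publisher
  rounded a true rational; frequencies printed with too few digits for
  their denominator could reconstruct off by one count at large N.
- The generator's independence assumptions (no LD, no relatedness) make
  synthetic power estimates optimistic relative to structured real
  cohorts.
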