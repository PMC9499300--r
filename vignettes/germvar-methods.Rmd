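---
title: "Methods: germline predisposition-variant screening with germvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline predisposition-variant screening with germvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germvar)
```

germvar implements a screening pipeline for rare germline
cancer-predisposition variants in a sequenced case cohort compared against
a population allele-frequency reference. This vignette documents the
statistical model behind each stage, every tunable parameter with its
default and rationale, the synthetic-data generator and its limits, and
the numerical choices that make results reproducible to the digit.

## The screening model

The pipeline treats discovery as a funnel over the cohort's variant call
set:

1. **Quality filtering** retains variants that simultaneously satisfy
   five criteria.
2. **Panel intersection** restricts to a curated predisposition gene
   panel annotated with pathway labels and a DNA-damage-repair (DDR)
   flag.
3. **ACMG/AMP classification** assigns each variant a five-tier label
   from its evidence codes, then triages to three screening bins:
   deleterious (pathogenic or likely pathogenic), uncertain significance
   (VUS), benign (benign or likely benign).
4. **Enrichment** tests each deleterious variant's allele count in cases
   against the population reference with Fisher's exact test,
   Benjamini–Hochberg (BH) false-discovery control, and
   continuity-corrected odds ratios.
5. **Replication and novel-gene calling** intersect two cohorts'
   deleterious gene sets and call genes that are significantly enriched,
   non-DDR, and not previously reported.
6. **Cohort summaries and clinical modeling** report carrier structure,
   mutation spectrum and pathway burden; test carrier status against
   clinical characteristics; and fit a logistic metastasis model.

## Quality filtering

`filter_config()` exposes the five criteria. A variant is retained only
if it passes all of them; the final set is therefore independent of
criterion order, while `qc_report()` presents the stage-wise funnel in
the canonical order (MAF, exonic, depth, strand, VAF).

* `maf_max = 0.01`: maximum East Asian population minor allele
  frequency. Under the default `maf_rule = "every_source"` the maximum
  over the available frequency sources (ExAC, 1000 Genomes, gnomAD East
  Asian columns) must be below the cutoff; a missing source contributes
  0 (absence of evidence of commonness). `"any_source"` requires only
  one source below the cutoff; `maf_require_all_sources = TRUE` drops
  variants lacking any source.
* `require_exonic = TRUE`: restrict to exonic calls.
* `depth_min = 20`, strict: coverage must exceed 20 reads. The boundary
  value 20 fails.
* `strand_bias_threshold = 60` with `strand_bias_mode = "retain_le"`:
  retain variants whose Phred-scaled Fisher strand-bias score (FS) is at
  most 60, following the convention that FS > 60 marks a strand-biased
  artifact. The alternative mode `"retain_gt_literal"` inverts the
  comparison for compatibility with pipelines that phrase the rule as a
  lower bound; it is exposed because published methods sections are
  sometimes ambiguous on the direction, and the default is the
  artifact-removing reading.
* `vaf_min = 0.25`, inclusive: at least one carrier's variant allele
  fraction must reach 0.25, the conventional lower bound for a germline
  heterozygote after allowing for capture noise.

Records missing a field required by an active criterion fail that
criterion; a screening pipeline must not pass variants it cannot
evaluate.

## ACMG/AMP classification

`combine_evidence()` implements the standard evidence-combining rule
table over the 28 codes (PVS1, PS1–PS4, PM1–PM6, PP1–PP5, BA1, BS1–BS4,
BP1–BP7). Evidence is *contradictory* when a qualifying combination in
one direction coexists with any evidence code from the opposite
direction; contradictory evidence resolves to VUS. This conflict rule
keeps the classifier directionally monotone: adding a
pathogenic-direction code never moves the label toward benign, and vice
versa — a property the test suite checks on randomized evidence sets.

Because published studies rarely disclose per-variant evidence
assignments, `assign_default_evidence()` is deliberately minimal and
swappable: PVS1 for null variants (stop-gain, frameshift, splicing) in
genes flagged as having loss of function as their disease mechanism; PM2
when the variant is absent or below 1e-4 in both the reference and all
population sources; BA1 above 5% in any source; PP3/BP4 passed through
from the annotation when present. Acceptance-grade guarantees therefore
target the combiner, which is fully specified, rather than the assigner.

## Enrichment statistics

For each deleterious variant, the default allele-mode 2×2 table is

|                | alt alleles | other alleles |
|----------------|------------:|--------------:|
| cases          | a = case allele count | b = 2·n − a |
| reference      | c = reference AC      | d = AN − c  |

Carrier mode (one row per person rather than per allele) is available
via `build_contingency(mode = "carrier")`; allele mode is the default
because population references report allele counts, not carrier counts.
Variants absent from the reference are treated as observed zero times at
a default allele number of 18,394 (2 × 9,197 diploid individuals, the
size of the emulated reference population); this "absence means AC = 0"
convention matches how population databases omit unobserved variants.

* **Fisher's exact two-sided p** is computed in-package by summing
  hypergeometric point probabilities not exceeding that of the observed
  table, with a relative tolerance of 1e-7 on the probability comparison
  to absorb floating-point noise at ties (the same tolerance
  `stats::fisher.test` uses). The test suite checks it against an
  independent binomial-coefficient enumeration oracle on every 2×2 table
  with row margins up to 30, and against `stats::fisher.test`.
* **Odds ratio**: OR = (a/b)/(c/d). When any cell is zero the
  Haldane–Anscombe correction adds 0.5 to *all four* cells for the OR
  and its Wald 95% CI (`exp(log OR ± 1.96·sqrt(1/a'+1/b'+1/c'+1/d'))`),
  and the result is flagged `corrected`. The correction is never applied
  to the p-value, which is exact and needs none.
* **Multiplicity**: BH step-up (`stats::p.adjust`) across the
  deleterious variants of a cohort, significance at q ≤ 0.05, with a
  direction filter requiring the case frequency to exceed the reference
  frequency so that significant calls are enrichments (OR ≥ 1), not
  depletions. Bonferroni is available. The VUS screen deliberately uses
  raw p ≤ 0.05 without FDR control — it is an exploratory pass over a
  much larger set, reported as such.

## Replication, novel genes, summaries

`intersect_cohorts()` reports shared deleterious genes and variants with
each cohort's shared fraction. `call_novel_genes()` calls a gene novel
when some variant in it is significant (q ≤ 0.05, OR ≥ 1), the gene is
not DDR, and it is absent from the supplied list of previously reported
predisposition genes; `require_both = TRUE` demands significance in both
cohorts instead of either.

`summarize_carriers()` counts distinct carriers and dual carriers
(patients with ≥ 2 deleterious variants); `mutation_spectrum()` and
`pathway_burden()` report composition percentages. All printed
percentages use half-up rounding to one decimal (`percent_round()`), the
convention used when reporting e.g. 25.1% for 42/167 — round-half-even
would print some published-style values differently.

`associate_clinical()` compares carriers with non-carriers: Wilcoxon
rank-sum for continuous or ordinal characteristics (age, PSA, ISUP
grade), exact when the combined sample is ≤ 12 without ties, otherwise
the normal approximation with continuity correction; Fisher's exact test
(the package's own implementation) for binary outcomes (metastasis,
early castration resistance).

## The metastasis model

`build_model_frame()` encodes, per patient, `log10(PSA + 1)` (the +1
guards the transform at PSA 0), ISUP grade as an ordinal integer, and a
0/1 indicator per model gene for carrying any qualifying variant in that
gene. `fit_logistic()` is an in-package iteratively reweighted least
squares (IRLS) maximum-likelihood fit: convergence when the largest
coefficient update falls below 1e-8, at most 100 iterations, and a ridge
fallback (penalty 1e-4 on non-intercept terms) that is triggered — and
flagged — when coefficients exceed 15 in absolute value (the signature
of complete separation) or the unpenalized Hessian is singular
(collinear designs). The log-likelihood uses a stable `log(1+exp(η))`
evaluation to avoid overflow. The suite verifies agreement with
`stats::glm` to 1e-6 and coefficient recovery on synthetic cohorts.

`evaluate_auc()` computes the area under the ROC curve by the rank
formula (concordant pairs plus half the ties over n₁·n₀), which is
invariant to strictly increasing score transforms and cross-checked
against pROC. `cross_cohort_evaluate()` trains the full model and a
PSA+ISUP control on one cohort and compares held-out AUCs on the other,
the relevant comparison for claiming that gene status adds predictive
information.

`ora_test()` is hypergeometric overrepresentation of a query gene set
against a GMT collection over an explicit universe, with BH adjustment
across sets; the query is intersected with the universe first, and a
query gene outside the universe is an error rather than silently
dropped.

## The synthetic generator

`generate_cohort()` draws, deterministically from a single seed:

* **Planted deleterious variants** — per-patient Bernoulli carriers at
  each variant's `carrier_probability`, with QC fields guaranteed to
  pass the default filters and evidence codes realizing the planted
  tier. Two planted tables ship with the package, and the difference is
  deliberate:
  * `default_planted_variants()` (the default) emulates a realistic
    discovery cohort: 36 variants over 25 genes, aggregate carrier
    prevalence near 29% of a 100-patient cohort, one recurrent variant
    at probability 0.04, a 12/11/7/6 consequence mix and a pathway mix
    led by DNA methylation (12/36) and DDR (7/36). Signals this weak are
    *not* reliably recoverable at n = 100 — which is realistic, and why
    this table is not used for recovery benchmarks.
  * `recovery_planted_variants()` is the benchmarking table: 15 strong
    signal variants (probability 0.04, absent from the reference; 3 DDR
    genes and 12 non-DDR genes so novel-gene calls have a known answer)
    plus 21 frequency-matched null variants whose case carrier rate
    equals the rate implied by their reference frequency (0.003). Nulls
    are frequency-matched so false-positive behavior is measured against
    genuinely unenriched variants, not against easy strawmen.
* **Model-gene variants** — uncertain-significance variants in six genes
  (carrier probability 0.15 each) whose indicators enter the metastasis
  logit with coefficient 1.5; population frequency 0.002 so they survive
  the MAF filter, consistent with case-enriched VUS.
* **Background variants** — population allele frequencies from
  Beta(0.5, 2000) truncated below 1%, allele counts Binomial(2n, af),
  about 40 per patient by default; a mix of benign and VUS evidence.
  Only variants actually observed in the cohort are emitted, as in a
  real call set.
* **Clinical covariates** — age ~ round(Normal(69, 8)) clamped to
  45–90; PSA ~ LogNormal(μ = 3, σ = 1.2) ng/mL; ISUP grade categorical
  with probabilities (15, 1, 1, 33, 50)/100, mirroring a high-risk
  cohort; metastasis ~ Bernoulli(logit⁻¹(−4.5 + 0.8·log10(PSA+1) +
  0.5·ISUP + 1.5·Σ gene indicators)). Under these defaults roughly half
  the patients are M1 — a deliberate middle ground between the two
  cohort compositions the generator emulates (about 28% and 63%), chosen
  so both outcome classes are always well populated for model fitting.
* **Reference** — AN = 2 × 9,197 = 18,394 for every row; planted
  variants get AC = round(af·AN), others Binomial(AN, af); AC = 0 rows
  are omitted, as population databases do not list unobserved variants.

All randomness flows from the config seed through named sub-streams
(variants, background, clinical, reference, panel), so adding one
artifact never perturbs another, and identical seeds produce
byte-identical written outputs.

**Realism limits.** The generator has no linkage disequilibrium, no
sequence context or mutational signatures, no relatedness, no batch
effects, and independence between variants within a patient; carrier
counts are exactly Bernoulli. It is designed to make pipeline behavior
testable against known truth, not to fool a population geneticist.

## Problem sizes

The sizes used throughout the tests and the acceptance script are the
package's own choices: discovery/validation cohorts of 100 and 167
patients (typical of single-center WES studies), a 1,166-gene panel with
decoy genes, a 9,197-individual reference, 200-seed recovery runs,
n = 2,000 cohorts for coefficient-recovery checks (large enough that
sampling error in a logistic fit is small against a ±0.2 band), and
paired n = 500 cohorts with replication in both required for the
exact novel-gene recovery demonstration (at n = 100 the null
false-positive noise makes exact recovery a coin flip; requiring
two-cohort replication at n = 500 makes it near certain without touching
any threshold).

## Numerical conventions

* Percentages: half-up rounding at one decimal with a 1e-9 epsilon
  before flooring, so values like 0.05 round up deterministically.
* Fisher tie tolerance 1e-7, matching the reference implementation.
* Result tables serialize doubles at 15 significant digits
  (`write_result_table()`), sufficient for lossless re-reading at
  12-digit comparison; whole numbers re-read as exact-valued doubles.
* JSON output (`jsonlite::write_json(auto_unbox = TRUE, digits = NA)`)
  writes full-precision bare numbers.
* Seeds are plain integers kept below 2^31; derived seeds use small
  affine maps of the base seed.
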