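# germvar

Screening for rare germline cancer-predisposition variants in a sequenced
case cohort, compared against a population allele-frequency reference.

Prostate-cancer (and other cancer) whole-exome studies repeatedly find
that a substantial minority of patients — often around a quarter to a
third — carry rare deleterious germline variants in predisposition
genes, many outside the classical DNA-damage-repair (DDR) set. germvar
implements the full analysis such a study needs, end to end and
reproducibly:

* **Five-criterion quality filtering** of cohort variants: population
  minor allele frequency < 1% (East Asian sources), exonic location,
  depth > 20, strand-bias score FS ≤ 60, variant allele fraction ≥ 0.25.
* **Panel intersection** against a curated predisposition gene panel
  with pathway labels and DDR flags.
* **ACMG/AMP classification** of each variant into
  pathogenic / likely pathogenic / VUS / likely benign / benign from its
  evidence codes, triaged to deleterious / VUS / benign screening bins.
  Contradictory evidence (a qualifying combination in one direction plus
  any code from the other) resolves to VUS.
* **Per-variant enrichment** of case allele counts against reference
  allele counts: exact two-sided Fisher test
  (p = Σ Pr(tables as or less probable than observed) over fixed
  margins), Benjamini–Hochberg FDR across the cohort's deleterious
  variants (significance at q ≤ 0.05, enrichment direction only), and
  odds ratios OR = (a/b)/(c/d) with the Haldane–Anscombe correction
  (+0.5 to all four cells, OR and Wald 95% CI only, never the p-value)
  whenever a cell is zero. A variant absent from the reference counts as
  AC = 0 at AN = 18,394.
* **Replication and novel-gene calling** across a discovery and a
  validation cohort: shared deleterious genes/variants, and genes that
  are significantly enriched, non-DDR, and not previously reported.
* **Cohort reporting**: carriers and dual carriers, mutation spectrum,
  pathway burden, recurrent variants, carrier-versus-clinical
  association (Wilcoxon rank-sum for continuous/ordinal, Fisher exact
  for binary characteristics).
* **Gene-set overrepresentation** (hypergeometric upper tail over an
  explicit universe, BH across sets) and a **logistic metastasis model**
  (in-package IRLS fit; log10(PSA+1), ISUP grade and per-gene carrier
  indicators; held-out-cohort AUC against a PSA+ISUP control).
* A **seeded synthetic-cohort generator** with known ground truth
  (planted carriers, reference counts, clinical coefficients), so every
  stage is testable without access to protected sequencing data.

See the methods vignette (`vignettes/germvar-methods.Rmd`) for the
statistical model, all parameter defaults and rationale, and the
generator's design and limits.

## Worked example

Simulate a paired discovery (n = 100) / validation (n = 167) study and
run the whole pipeline:

```r
library(germvar)

study <- simulate_study(seed = 7)
res <- run_study(study, known_genes = c("BRCA2", "ATM"))
#> input: 3810 variants, 100 samples
#> after QC filters: 3810 variants
#> in panel: 23 variants
#> classified: 17 deleterious, 6 VUS, 0 benign
#> enriched at FDR <= 0.05: 17 of 17 deleterious variants
#> input: 6276 variants, 167 samples
#> ...

res$discovery$report
#> <cohort_report>
#>   17 deleterious variants in 15 genes; 21/100 carriers (21.0%), 2 with two or more
#>   5 recurrent variant(s)

dplyr::select(
  dplyr::filter(res$discovery$enrichment, significant)[1:5, ],
  gene, a, c, p, q, or, ci_low, ci_high
)
#> # A tibble: 5 × 8
#>   gene       a     c        p        q    or ci_low ci_high
#>   <chr>  <int> <int>    <dbl>    <dbl> <dbl>  <dbl>   <dbl>
#> 1 KMT2C      1     0 0.0108   0.0114    277.   11.2   6811.
#> 2 KMT2C      2     0 0.000115 0.000489  463.   22.2   9682.
#> 3 MYH7       1     0 0.0108   0.0114    277.   11.2   6811.
#> 4 PABPC1     1     0 0.0108   0.0114    277.   11.2   6811.
#> 5 KDM5A      1     0 0.0108   0.0114    277.   11.2   6811.

res$replication
#> <replication_report>
#>   12 shared genes (80.0% of 15 discovery, 48.0% of 25 validation)
#>   14 shared variant(s)

head(res$novel_genes)
#> [1] "ADGRG1" "CHD4"   "DNMT3A" "EGFR"   "ERBB2"  "ERBB3"
```

The OR of 277 for a singleton (1 case allele, 0 reference alleles) is
the continuity-corrected (1.5/199.5)/(0.5/18394.5). `tidy()` and
`glance()` methods (from the generics package) are available on reports,
model fits and cross-cohort evaluations; `plot_filter_funnel()`,
`plot_spectrum()`, `plot_enrichment_or()` and `plot_roc()` give ggplot2
views of the corresponding results.

Real data enter through the same shapes: `read_cohort()` (VCF +
annotation TSV), `read_panel()`, `read_reference()`, `read_clinical()`,
`read_gene_sets()` (GMT), then `run_pipeline()` or the individual
stages.

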