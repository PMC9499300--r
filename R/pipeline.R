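#' Run the full discovery pipeline on one cohort
#'
#' Chains the stages: QC filtering, panel intersection, ACMG
#' classification, per-variant enrichment of the deleterious subset
#' against the population reference, and the cohort report.  Stage-wise
#' record counts are logged to stderr, mirroring the analysis funnel.
#'
#' @param variants Annotated variant tibble (from [read_cohort()] or
#'   [generate_cohort()]).
#' @param samples Cohort roster.
#' @param panel Panel tibble.
#' @param reference Reference tibble.
#' @param clinical Optional clinical tibble.
#' @param cfg QC [filter_config()].
#' @param default_an Reference AN for absent variants.
#' @param fdr_cutoff Enrichment significance cutoff.
#' @param mode Contingency construction mode (see [build_contingency()]).
#' @param adjust Multiplicity adjustment (`"BH"` or `"bonferroni"`).
#' @param quiet Suppress stderr stage logging.
#' @return A list with `filtered`, `panel_variants`, `classified`,
#'   `deleterious`, `vus`, `enrichment`, `vus_enrichment`, `report`,
#'   `qc_report`.
#' @export
run_pipeline <- function(variants, samples, panel, reference,
                         clinical = NULL,
                         cfg = filter_config(),
                         default_an = 18394L,
                         fdr_cutoff = 0.05,
                         mode = "allele",
                         adjust = "BH",
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  say("input: %d variants, %d samples", nrow(variants), length(samples))
  filtered <- qc_filter(variants, cfg)
  say("after QC filters: %d variants", nrow(filtered))
  panel_variants <- intersect_panel(filtered, panel)
  say("in panel: %d variants", nrow(panel_variants))
  classified <- classify_variants(panel_variants, reference, default_an = default_an)
  deleterious <- classified[classified$tier3 == "deleterious", , drop = FALSE]
  vus <- classified[classified$tier3 == "VUS", , drop = FALSE]
  say(
    "classified: %d deleterious, %d VUS, %d benign",
    nrow(deleterious), nrow(vus), sum(classified$tier3 == "benign")
  )
  enrichment <- if (nrow(deleterious) > 0) {
    run_enrichment(deleterious, length(samples), reference,
                   mode = mode, default_an = default_an,
                   adjust = adjust, fdr_cutoff = fdr_cutoff)
  } else {
    NULL
  }
  if (!is.null(enrichment)) {
    say("enriched at FDR <= %.2f: %d of %d deleterious variants",
        fdr_cutoff, sum(enrichment$significant), nrow(enrichment))
  }
  vus_enrichment <- if (nrow(vus) > 0) {
    # uncertain-significance screen: raw p <= 0.05, no FDR
    run_enrichment(vus, length(samples), reference,
                   mode = mode, default_an = default_an, p_cutoff = 0.05)
  } else {
    NULL
  }
  report <- cohort_report(deleterious, samples, clinical)
  list(
    filtered = filtered,
    panel_variants = panel_variants,
    classified = classified,
    deleterious = deleterious,
    vus = vus,
    enrichment = enrichment,
    vus_enrichment = vus_enrichment,
    report = report,
    qc_report = qc_report(panel_variants)
  )
}

#' Run the paired discovery/validation analysis
#'
#' Runs [run_pipeline()] on both cohorts, intersects their deleterious
#' genes and variants, and calls novel genes from the pooled enrichment
#' results.
#'
#' @param study A [simulate_study()] result, or an equivalently shaped
#'   list of loaded artifacts.
#' @param known_genes Previously reported predisposition genes (input to
#'   novel-gene calling).
#' @param ... Passed to [run_pipeline()].
#' @return A list with both pipeline results, the `replication` report and
#'   the `novel_genes` vector.
#' @export
run_study <- function(study, known_genes = character(), ...) {
  a <- run_pipeline(
    study$discovery$variants, study$discovery$samples,
    study$panel, study$reference, study$discovery$clinical, ...
  )
  b <- run_pipeline(
    study$validation$variants, study$validation$samples,
    study$panel, study$reference, study$validation$clinical, ...
  )
  replication <- intersect_cohorts(
    a$deleterious$gene, b$deleterious$gene,
    variant_key(a$deleterious$chrom, a$deleterious$pos,
                a$deleterious$ref, a$deleterious$alt),
    variant_key(b$deleterious$chrom, b$deleterious$pos,
                b$deleterious$ref, b$deleterious$alt)
  )
  novel <- call_novel_genes(a$enrichment, b$enrichment, known_genes = known_genes)
  list(discovery = a, validation = b, replication = replication,
       novel_genes = novel)
}
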