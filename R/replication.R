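#' Cross-cohort intersection of deleterious genes and variants
#'
#' @param genes_a,genes_b Character vectors of deleterious-variant genes in
#'   the discovery and validation cohorts (harmonized symbols).
#' @param variants_a,variants_b Character vectors of variant keys (or rsids)
#'   in the two cohorts.
#' @return An object of class `replication_report`: shared genes and
#'   variants, and the shared fraction of each cohort's gene set as a
#'   half-up 1-decimal percentage.
#' @export
intersect_cohorts <- function(genes_a, genes_b,
                              variants_a = character(),
                              variants_b = character()) {
  genes_a <- unique(genes_a)
  genes_b <- unique(genes_b)
  shared_genes <- sort(intersect(genes_a, genes_b))
  shared_variants <- sort(intersect(unique(variants_a), unique(variants_b)))
  structure(
    list(
      shared_genes = shared_genes,
      shared_variants = shared_variants,
      n_discovery_genes = length(genes_a),
      n_validation_genes = length(genes_b),
      discovery_fraction_pct = if (length(genes_a) > 0) {
        percent_round(100 * length(shared_genes) / length(genes_a))
      } else {
        NA_real_
      },
      validation_fraction_pct = if (length(genes_b) > 0) {
        percent_round(100 * length(shared_genes) / length(genes_b))
      } else {
        NA_real_
      }
    ),
    class = "replication_report"
  )
}

#' @export
print.replication_report <- function(x, ...) {
  cat("<replication_report>\n")
  cat(sprintf(
    "  %d shared genes (%.1f%% of %d discovery, %.1f%% of %d validation)\n",
    length(x$shared_genes), x$discovery_fraction_pct, x$n_discovery_genes,
    x$validation_fraction_pct, x$n_validation_genes
  ))
  cat(sprintf("  %d shared variant(s)\n", length(x$shared_variants)))
  invisible(x)
}

#' @export
glance.replication_report <- function(x, ...) {
  tibble::tibble(
    n_shared_genes = length(x$shared_genes),
    n_shared_variants = length(x$shared_variants),
    n_discovery_genes = x$n_discovery_genes,
    n_validation_genes = x$n_validation_genes,
    discovery_fraction_pct = x$discovery_fraction_pct,
    validation_fraction_pct = x$validation_fraction_pct
  )
}

#' Call novel predisposition genes from pooled enrichment results
#'
#' A gene is called novel when it harbors at least one variant with
#' adjusted value `q <= fdr_cutoff` and odds ratio `>= 1` in either cohort
#' (or in both, in strict mode), is not a DNA-damage-repair gene, and is
#' absent from the supplied list of already-reported predisposition genes.
#'
#' @param results_a,results_b Enrichment tibbles from [run_enrichment()]
#'   for the discovery and validation cohorts (must carry `gene`, `q`,
#'   `or`, `is_ddr`).
#' @param known_genes Character vector of previously reported
#'   predisposition genes.
#' @param fdr_cutoff Significance cutoff (default 0.05).
#' @param require_both Require significance in both cohorts rather than
#'   either (default `FALSE`).
#' @return Sorted character vector of novel gene symbols.
#' @export
call_novel_genes <- function(results_a, results_b = NULL,
                             known_genes = character(),
                             fdr_cutoff = 0.05,
                             require_both = FALSE) {
  sig_genes <- function(res) {
    if (is.null(res) || nrow(res) == 0) return(character())
    assert_columns(res, c("gene", "q", "or", "is_ddr"), "enrichment results")
    if (any(is.na(res$is_ddr))) {
      abort("enrichment results must carry a non-missing is_ddr flag per variant")
    }
    hit <- res$q <= fdr_cutoff & res$or >= 1 & !res$is_ddr
    unique(res$gene[hit])
  }
  ga <- sig_genes(results_a)
  gb <- sig_genes(results_b)
  pooled <- if (require_both && !is.null(results_b)) {
    intersect(ga, gb)
  } else {
    union(ga, gb)
  }
  sort(setdiff(pooled, known_genes))
}
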