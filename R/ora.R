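#' Gene-set overrepresentation analysis
#'
#' For each gene set, tests whether the query is enriched for the set's
#' members using the hypergeometric upper tail: with universe size `N`,
#' set size `K` (after intersecting the set with the universe), query size
#' `n` and overlap `k`, `p = P[X >= k]` for
#' `X ~ Hypergeometric(N, K, n)`.  Adjusted values are Benjamini-Hochberg
#' across the tested sets.
#'
#' @param query Character vector of genes of interest (must be contained
#'   in `universe`).
#' @param sets Named list of gene sets, e.g. from [read_gene_sets()].
#' @param universe Character vector: the background gene universe.
#' @return A tibble of `set`, `k`, `K`, `n`, `N`, `gene_ratio`, `p`, `q`,
#'   sorted by decreasing gene ratio.
#' @export
ora_test <- function(query, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("universe must be non-empty")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    abort(paste0(
      "query gene(s) outside the universe: ",
      paste(head(outside, 5), collapse = ", ")
    ))
  }
  N <- length(universe)
  n <- length(query)
  rows <- purrr::imap(sets, function(members, nm) {
    inset <- intersect(unique(members), universe)
    K <- length(inset)
    k <- length(intersect(query, inset))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(
      set = nm, k = k, K = K, n = n, N = N,
      gene_ratio = if (n > 0) k / n else NA_real_, p = min(1, p)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$q <- adjust_fdr(out$p)
  dplyr::arrange(out, dplyr::desc(.data$gene_ratio), .data$p)
}
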