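#' Build a 2x2 case-versus-reference contingency table
#'
#' In `allele` mode (the default, matching reference databases that publish
#' allele counts) the cells are `a` = case alternate allele count, `b` =
#' `2 * n_cases - a`, `c` = reference alternate allele count, `d` =
#' reference AN minus `c`.  In `carrier` mode `a` is the number of carrier
#' patients, `b = n_cases - a`, and the reference allele count is treated
#' as a carrier estimate out of `an / 2` individuals.
#'
#' @param ac_case Case alternate allele count (allele mode) — a homozygous
#'   carrier contributes two alleles.
#' @param n_carriers Number of carrier patients (carrier mode).
#' @param n_cases Number of patients in the cohort.
#' @param ac_ref,an_ref Reference alternate allele count and allele number.
#' @param mode `"allele"` (default) or `"carrier"`.
#' @return Named integer vector `c(a, b, c, d)`.
#' @export
build_contingency <- function(ac_case, n_cases, ac_ref, an_ref,
                              mode = c("allele", "carrier"),
                              n_carriers = NULL) {
  mode <- match.arg(mode)
  if (n_cases <= 0) abort("n_cases must be positive")
  if (an_ref <= 0) abort("reference allele number must be positive")
  if (mode == "allele") {
    a <- as.integer(ac_case)
    if (a > 2 * n_cases) abort("case alt allele count exceeds 2 * n_cases")
    b <- as.integer(2 * n_cases - a)
    cc <- as.integer(ac_ref)
    d <- as.integer(an_ref - ac_ref)
  } else {
    a <- as.integer(n_carriers %||% ac_case)
    if (a > n_cases) abort("carrier count exceeds n_cases")
    b <- as.integer(n_cases - a)
    n_ref_ind <- as.integer(round(an_ref / 2))
    cc <- as.integer(min(ac_ref, n_ref_ind))
    d <- as.integer(n_ref_ind - cc)
  }
  c(a = a, b = b, c = cc, d = d)
}

#' Two-sided Fisher's exact p-value for a 2x2 table
#'
#' The two-sided p-value sums, over all tables sharing the observed
#' margins, the hypergeometric probabilities no larger than that of the
#' observed table (with relative tolerance 1e-7, the conventional guard
#' against ties lost to floating point).
#'
#' @param a,b,c,d Non-negative integer cells (`a` = case alt, `b` = case
#'   non-alt, `c` = reference alt, `d` = reference non-alt).
#' @return The p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) abort("contingency cells must be non-negative")
  if (any(cells != round(cells))) abort("contingency cells must be integers")
  m <- a + b          # row 1 total (cases)
  n <- c + d          # row 2 total (reference)
  k <- a + c          # alt column total
  if (k == 0 || m + n == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Odds ratio with Haldane-Anscombe continuity correction and Wald CI
#'
#' When any cell of the 2x2 table is zero, 0.5 is added to all four cells
#' (`a`, `b`, `c`, `d`) so that the odds ratio and its confidence interval
#' are finite; the p-value is always computed from the raw integer table,
#' the correction applies to the odds ratio and CI only.
#'
#' @inheritParams fisher_exact_two_sided
#' @param conf_level Confidence level for the Wald interval (default 0.95).
#' @return A list with `or`, `ci_low`, `ci_high`, `corrected`.
#' @export
#' @examples
#' odds_ratio_ci(1, 199, 0, 18394)$or # ~ 276.6
odds_ratio_ci <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) abort("contingency cells must be non-negative")
  if (all(cells == 0)) abort("all-zero contingency table")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] / cells[2]) / (cells[3] / cells[4])
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / cells))
  list(
    or = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    corrected = corrected
  )
}

#' Benjamini-Hochberg step-up adjusted values
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` (default, false-discovery-rate control) or
#'   `"bonferroni"` (family-wise control).
#' @return Adjusted values in the input order.
#' @export
adjust_fdr <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] and be non-missing")
  }
  p.adjust(p, method = method)
}

#' Per-variant case-versus-reference enrichment
#'
#' For each variant, builds the 2x2 table against the population reference,
#' computes the two-sided Fisher exact p-value from the raw integer table,
#' the continuity-corrected odds ratio with its 95% CI, and adjusts across
#' the variants tested in this run.  A variant is called significant when
#' its adjusted value passes the cutoff *and* its case frequency exceeds
#' its reference frequency (so every reported significant odds ratio is
#' `>= 1`).
#'
#' @param variants A variant tibble with `ac_case` and `carriers` columns
#'   (e.g. the deleterious subset after [classify_variants()]).
#' @param n_cases Number of patients in the cohort.
#' @param reference A reference tibble from [read_reference()].
#' @param mode 2x2 construction mode, see [build_contingency()].
#' @param default_an Reference AN for variants absent from the table.
#' @param adjust Multiplicity adjustment across tested variants, `"BH"`
#'   (default) or `"bonferroni"`.
#' @param fdr_cutoff Significance cutoff on the adjusted value
#'   (default 0.05).
#' @param p_cutoff When supplied, significance uses the *raw* p-value at
#'   this cutoff instead of the adjusted value (the convention used for
#'   VUS-level screens at `p <= 0.05`).
#' @param conf_level Confidence level for odds-ratio intervals.
#' @return A tibble with one row per variant: the four cells, `p`, `q`,
#'   `or`, `ci_low`, `ci_high`, `corrected`, `case_freq`, `ref_freq`,
#'   `significant`.
#' @export
run_enrichment <- function(variants, n_cases, reference,
                           mode = c("allele", "carrier"),
                           default_an = 18394L,
                           adjust = c("BH", "bonferroni"),
                           fdr_cutoff = 0.05,
                           p_cutoff = NULL,
                           conf_level = 0.95) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  if (nrow(variants) == 0) {
    warn("no variants to test; returning an empty enrichment table")
    return(tibble::tibble(
      variant = character(), gene = character(), a = integer(), b = integer(),
      c = integer(), d = integer(), p = numeric(), q = numeric(),
      or = numeric(), ci_low = numeric(), ci_high = numeric(),
      corrected = logical(), case_freq = numeric(), ref_freq = numeric(),
      significant = logical()
    ))
  }
  v <- lookup_reference(variants, reference, default_an = default_an)
  n_carriers <- lengths(v$carriers)
  tables <- lapply(seq_len(nrow(v)), function(i) {
    build_contingency(
      ac_case = v$ac_case[i], n_cases = n_cases,
      ac_ref = v$ac_ref[i], an_ref = v$an_ref[i],
      mode = mode, n_carriers = n_carriers[i]
    )
  })
  a <- vapply(tables, `[[`, numeric(1), "a")
  b <- vapply(tables, `[[`, numeric(1), "b")
  cc <- vapply(tables, `[[`, numeric(1), "c")
  d <- vapply(tables, `[[`, numeric(1), "d")
  p <- vapply(seq_along(tables), function(i) {
    fisher_exact_two_sided(a[i], b[i], cc[i], d[i])
  }, numeric(1))
  q <- adjust_fdr(p, method = adjust)
  ors <- lapply(seq_along(tables), function(i) odds_ratio_ci(a[i], b[i], cc[i], d[i], conf_level))
  case_freq <- a / (a + b)
  ref_freq <- cc / (cc + d)
  enriched_direction <- case_freq > ref_freq
  significant <- if (is.null(p_cutoff)) {
    q <= fdr_cutoff & enriched_direction
  } else {
    p <= p_cutoff & enriched_direction
  }
  tibble::tibble(
    variant = variant_key(v$chrom, v$pos, v$ref, v$alt),
    gene = if ("gene" %in% names(v)) v$gene else NA_character_,
    rsid = if ("rsid" %in% names(v)) v$rsid else NA_character_,
    is_ddr = if ("is_ddr" %in% names(v)) v$is_ddr else NA,
    a = as.integer(a), b = as.integer(b), c = as.integer(cc), d = as.integer(d),
    p = p, q = q,
    or = vapply(ors, `[[`, numeric(1), "or"),
    ci_low = vapply(ors, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(ors, `[[`, numeric(1), "ci_high"),
    corrected = vapply(ors, `[[`, logical(1), "corrected"),
    case_freq = case_freq, ref_freq = ref_freq,
    significant = significant
  )
}
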