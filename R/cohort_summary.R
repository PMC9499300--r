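#' Carrier statistics for a set of deleterious variants
#'
#' @param variants A variant tibble with a `carriers` list-column.
#' @param samples Character vector: the cohort roster.
#' @return A list with `n_patients`, `n_variants`, `n_carriers` (patients
#'   with at least one variant), `n_dual_carriers` (patients with at least
#'   two distinct variants), `carrier_pct` (half-up, 1 decimal) and
#'   `per_patient` (tibble of per-carrier variant counts).
#' @export
summarize_carriers <- function(variants, samples) {
  all_carriers <- unlist(variants$carriers)
  unknown <- setdiff(all_carriers, samples)
  if (length(unknown) > 0) {
    abort(paste0(
      "carrier(s) not in the cohort roster: ",
      paste(unique(unknown), collapse = ", ")
    ))
  }
  # a patient listed twice for the same variant counts once per variant
  per_variant <- lapply(variants$carriers, unique)
  counts <- table(factor(unlist(per_variant), levels = samples))
  per_patient <- tibble::tibble(
    sample_id = names(counts)[counts > 0],
    n_variants = as.integer(counts[counts > 0])
  )
  list(
    n_patients = length(samples),
    n_variants = nrow(variants),
    n_carriers = nrow(per_patient),
    n_dual_carriers = sum(per_patient$n_variants >= 2),
    carrier_pct = if (length(samples) > 0) {
      percent_round(100 * nrow(per_patient) / length(samples))
    } else {
      NA_real_
    },
    per_patient = per_patient
  )
}

#' Mutation-type spectrum
#'
#' @param variants A variant tibble with a `consequence` column.
#' @return A tibble of `consequence`, `n`, `percent` (half-up, 1 decimal),
#'   ordered by decreasing count.
#' @export
mutation_spectrum <- function(variants) {
  if (nrow(variants) == 0) {
    return(tibble::tibble(consequence = character(), n = integer(), percent = numeric()))
  }
  variants |>
    dplyr::count(.data$consequence, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$consequence) |>
    dplyr::mutate(percent = percent_round(100 * .data$n / sum(.data$n)))
}

#' Pathway burden over variants and over patients
#'
#' Variant-level fractions are over the number of deleterious variants;
#' patient-level fractions count each patient once per pathway (the union
#' of carriers of that pathway's variants) over the cohort size.
#'
#' @param variants A panel-intersected variant tibble (columns `pathway`,
#'   `carriers`).
#' @param n_patients Cohort size.
#' @return A tibble of `pathway`, `n_variants`, `pct_variants`,
#'   `n_patients_carrying`, `pct_patients`.
#' @export
pathway_burden <- function(variants, n_patients) {
  v <- variants
  if (nrow(v) > 0 && any(is.na(v$pathway))) {
    warn("variant(s) with unlabeled gene assigned pathway 'other'")
    v$pathway[is.na(v$pathway)] <- "other"
  }
  if (nrow(v) == 0) {
    return(tibble::tibble(
      pathway = character(), n_variants = integer(), pct_variants = numeric(),
      n_patients_carrying = integer(), pct_patients = numeric()
    ))
  }
  total <- nrow(v)
  v |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(
      n_variants = dplyr::n(),
      n_patients_carrying = length(unique(unlist(.data$carriers))),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_variants = percent_round(100 * .data$n_variants / total),
      pct_patients = percent_round(100 * .data$n_patients_carrying / n_patients)
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_variants), .data$pathway) |>
    dplyr::select(
      "pathway", "n_variants", "pct_variants",
      "n_patients_carrying", "pct_patients"
    )
}

#' Recurrent variants (seen in two or more patients)
#'
#' @param variants A variant tibble with `carriers` (and optionally `rsid`).
#' @return A tibble of `variant`, `rsid`, `gene`, `n_patients` for variants
#'   carried by at least two distinct patients.
#' @export
find_recurrent <- function(variants) {
  n <- vapply(variants$carriers, function(x) length(unique(x)), integer(1))
  out <- tibble::tibble(
    variant = variant_key(variants$chrom, variants$pos, variants$ref, variants$alt),
    rsid = if ("rsid" %in% names(variants)) variants$rsid else NA_character_,
    gene = if ("gene" %in% names(variants)) variants$gene else NA_character_,
    n_patients = n
  )
  out |>
    dplyr::filter(.data$n_patients >= 2) |>
    dplyr::arrange(dplyr::desc(.data$n_patients))
}

#' Association between carrier status and clinical characteristics
#'
#' Dichotomous traits (metastasis, castration resistance within one year)
#' are tested by Fisher's exact test with a continuity-corrected odds
#' ratio; continuous and ordinal traits (age, PSA, ISUP grade) by the
#' two-sided Wilcoxon rank-sum test — exact when the combined group size is
#' at most 12 and ties are absent, normal approximation with tie correction
#' otherwise.
#'
#' @param clinical A clinical tibble from [read_clinical()].
#' @param carrier_ids Character vector of carrier sample identifiers.
#' @return A tibble of `characteristic`, `type`, `p`, `or`, `ci_low`,
#'   `ci_high` (odds ratios for dichotomous traits only).
#' @export
associate_clinical <- function(clinical, carrier_ids) {
  flag <- clinical$sample_id %in% carrier_ids
  if (all(flag) || !any(flag)) {
    abort("need at least one carrier and one non-carrier")
  }
  exact_ok <- function(x) length(x) <= 12 && !anyDuplicated(x)

  test_continuous <- function(x, name) {
    xc <- x[flag]
    xn <- x[!flag]
    p <- suppressWarnings(
      wilcox.test(xc, xn, exact = exact_ok(c(xc, xn)), correct = TRUE)$p.value
    )
    tibble::tibble(
      characteristic = name, type = "wilcoxon", p = p,
      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_
    )
  }
  test_binary <- function(y, name) {
    if (all(is.na(y))) return(NULL)
    a <- sum(flag & y, na.rm = TRUE)
    b <- sum(flag & !y, na.rm = TRUE)
    cc <- sum(!flag & y, na.rm = TRUE)
    d <- sum(!flag & !y, na.rm = TRUE)
    p <- fisher_exact_two_sided(a, b, cc, d)
    orci <- odds_ratio_ci(a, b, cc, d)
    tibble::tibble(
      characteristic = name, type = "fisher", p = p,
      or = orci$or, ci_low = orci$ci_low, ci_high = orci$ci_high
    )
  }
  dplyr::bind_rows(
    test_continuous(clinical$age, "age"),
    test_continuous(clinical$psa, "psa"),
    test_continuous(as.numeric(clinical$isup), "isup"),
    test_binary(clinical$metastasis == "M1", "metastasis"),
    test_binary(clinical$crpc_within_1yr, "crpc_within_1yr")
  )
}

#' Full cohort report
#'
#' Bundles carrier statistics, mutation spectrum, pathway burden,
#' recurrence and (optionally) clinical associations for the deleterious
#' variants of one cohort.
#'
#' @param variants Deleterious variant tibble (panel-intersected,
#'   classified).
#' @param samples Cohort roster.
#' @param clinical Optional clinical tibble.
#' @return An object of class `cohort_report`.
#' @export
cohort_report <- function(variants, samples, clinical = NULL) {
  carriers <- summarize_carriers(variants, samples)
  out <- list(
    carriers = carriers,
    spectrum = mutation_spectrum(variants),
    pathways = if ("pathway" %in% names(variants)) {
      pathway_burden(variants, length(samples))
    } else {
      NULL
    },
    recurrent = find_recurrent(variants),
    genes = sort(unique(variants$gene[!is.na(variants$gene)])),
    clinical = if (!is.null(clinical) && carriers$n_carriers > 0 &&
                     carriers$n_carriers < length(samples)) {
      associate_clinical(clinical, carriers$per_patient$sample_id)
    } else {
      NULL
    }
  )
  structure(out, class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  ca <- x$carriers
  cat("<cohort_report>\n")
  cat(sprintf(
    "  %d deleterious variants in %d genes; %d/%d carriers (%.1f%%), %d with two or more\n",
    ca$n_variants, length(x$genes), ca$n_carriers, ca$n_patients,
    ca$carrier_pct, ca$n_dual_carriers
  ))
  if (nrow(x$recurrent) > 0) {
    cat(sprintf("  %d recurrent variant(s)\n", nrow(x$recurrent)))
  }
  invisible(x)
}

#' @export
glance.cohort_report <- function(x, ...) {
  ca <- x$carriers
  tibble::tibble(
    n_patients = ca$n_patients,
    n_variants = ca$n_variants,
    n_genes = length(x$genes),
    n_carriers = ca$n_carriers,
    n_dual_carriers = ca$n_dual_carriers,
    carrier_pct = ca$carrier_pct,
    n_recurrent = nrow(x$recurrent)
  )
}

#' @export
tidy.cohort_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$spectrum, section = "spectrum",
                  label = .data$consequence, n = .data$n,
                  percent = .data$percent, .keep = "none"),
    if (!is.null(x$pathways)) {
      dplyr::mutate(x$pathways, section = "pathway_variants",
                    label = .data$pathway, n = .data$n_variants,
                    percent = .data$pct_variants, .keep = "none")
    }
  )
}

#' Patients-by-genes mutation matrix (oncoprint-style)
#'
#' @param variants Deleterious variant tibble with `gene` and `carriers`.
#' @param samples Cohort roster.
#' @return A tibble with one row per patient and one 0/1 column per gene.
#' @export
mutation_matrix <- function(variants, samples) {
  genes <- sort(unique(variants$gene[!is.na(variants$gene)]))
  mat <- matrix(0L, nrow = length(samples), ncol = length(genes),
                dimnames = list(samples, genes))
  for (i in seq_len(nrow(variants))) {
    g <- variants$gene[i]
    if (is.na(g)) next
    mat[intersect(variants$carriers[[i]], samples), g] <- 1L
  }
  dplyr::bind_cols(tibble::tibble(sample_id = samples), tibble::as_tibble(mat))
}
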