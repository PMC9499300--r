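#' Recognized ACMG/AMP evidence codes
#'
#' @return Character vector of the 28 evidence codes: PVS1, PS1-PS4,
#'   PM1-PM6, PP1-PP5 (pathogenic direction) and BA1, BS1-BS4, BP1-BP7
#'   (benign direction).
#' @export
acmg_codes <- function() {
  c(
    "PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
    "BA1", paste0("BS", 1:4), paste0("BP", 1:7)
  )
}

#' Parse a comma-separated evidence string into a validated code set
#'
#' @param x Character scalar such as `"PVS1,PM2"`; `NA` or `""` gives an
#'   empty set.  Duplicates collapse; unknown codes are an error.
#' @return Character vector of unique evidence codes.
#' @export
parse_evidence <- function(x) {
  if (length(x) != 1) abort("parse_evidence() expects a single string")
  if (is.na(x) || !nzchar(x)) return(character())
  codes <- unique(stringr::str_trim(strsplit(x, ",", fixed = TRUE)[[1]]))
  codes <- codes[nzchar(codes)]
  bad <- setdiff(codes, acmg_codes())
  if (length(bad) > 0) {
    abort(paste0("unknown ACMG evidence code(s): ", paste(bad, collapse = ", ")))
  }
  codes
}

evidence_counts <- function(codes) {
  c(
    pvs = sum(codes == "PVS1"),
    ps = sum(grepl("^PS[1-4]$", codes)),
    pm = sum(grepl("^PM[1-6]$", codes)),
    pp = sum(grepl("^PP[1-5]$", codes)),
    ba = sum(codes == "BA1"),
    bs = sum(grepl("^BS[1-4]$", codes)),
    bp = sum(grepl("^BP[1-7]$", codes))
  )
}

combine_from_counts <- function(pvs, ps, pm, pp, ba, bs, bp) {
  pathogenic <-
    (pvs >= 1 & (ps >= 1 | pm >= 2 | (pm >= 1 & pp >= 1) | pp >= 2)) |
    (ps >= 2) |
    (ps == 1 & (pm >= 3 | (pm == 2 & pp >= 2) | (pm == 1 & pp >= 4)))
  likely_path <-
    (pvs >= 1 & pm == 1) |
    (ps == 1 & pm >= 1 & pm <= 2) |
    (ps == 1 & pp >= 2) |
    (pm >= 3) |
    (pm == 2 & pp >= 2) |
    (pm == 1 & pp >= 4)
  benign <- (ba >= 1) | (bs >= 2)
  likely_benign <- (bs >= 1 & bp >= 1) | (bp >= 2)

  path_fires <- pathogenic | likely_path
  ben_fires <- benign | likely_benign
  path_present <- (pvs + ps + pm + pp) >= 1
  ben_present <- (ba + bs + bp) >= 1
  # contradictory: a direction's rule fires while evidence from the
  # opposite direction is on the table
  conflict <- (path_fires & ben_present) | (ben_fires & path_present)
  dplyr::case_when(
    conflict ~ "VUS",
    pathogenic ~ "Pathogenic",
    likely_path ~ "LikelyPathogenic",
    benign ~ "Benign",
    likely_benign ~ "LikelyBenign",
    TRUE ~ "VUS"
  )
}

#' Combine ACMG evidence codes into a five-tier classification
#'
#' Implements the standard evidence-combining rules: pathogenic and likely
#' pathogenic combinations of PVS/PS/PM/PP, benign and likely benign
#' combinations of BA/BS/BP.  Evidence is contradictory — and resolves to
#' a variant of uncertain significance (VUS) — when a qualifying
#' combination in one direction coexists with any evidence code from the
#' opposite direction; no qualifying combination also yields VUS.
#'
#' @param codes Character vector of evidence codes (see [acmg_codes()]),
#'   or a single comma-separated string.
#' @return One of `"Pathogenic"`, `"LikelyPathogenic"`, `"VUS"`,
#'   `"LikelyBenign"`, `"Benign"`.
#' @export
#' @examples
#' combine_evidence(c("PVS1", "PM2")) # LikelyPathogenic
#' combine_evidence(character())      # VUS
combine_evidence <- function(codes) {
  if (length(codes) == 1 && (is.na(codes) || grepl(",", codes) || !codes %in% acmg_codes())) {
    codes <- parse_evidence(codes)
  }
  bad <- setdiff(codes, acmg_codes())
  if (length(bad) > 0) {
    abort(paste0("unknown ACMG evidence code(s): ", paste(bad, collapse = ", ")))
  }
  codes <- unique(codes)
  n <- evidence_counts(codes)
  combine_from_counts(n["pvs"], n["ps"], n["pm"], n["pp"], n["ba"], n["bs"], n["bp"])
}

#' Collapse the five ACMG tiers to the three screening bins
#'
#' Pathogenic and likely pathogenic variants are `deleterious`; benign and
#' likely benign variants are `benign`; the middle tier stays `VUS`.
#'
#' @param tier5 Character vector of five-tier labels.
#' @return Character vector over `deleterious`, `VUS`, `benign`.
#' @export
acmg_triage <- function(tier5) {
  bad <- setdiff(unique(tier5), c(
    "Pathogenic", "LikelyPathogenic", "VUS", "LikelyBenign", "Benign"
  ))
  if (length(bad) > 0) {
    abort(paste0("unknown tier5 label(s): ", paste(bad, collapse = ", ")))
  }
  dplyr::case_when(
    tier5 %in% c("Pathogenic", "LikelyPathogenic") ~ "deleterious",
    tier5 %in% c("Benign", "LikelyBenign") ~ "benign",
    TRUE ~ "VUS"
  )
}

#' Minimal default evidence assigner
#'
#' The published study does not disclose its per-variant evidence
#' assignments, so this assigner is deliberately minimal and swappable:
#' PVS1 for null variants (stopgain, frameshift, splicing) in genes where
#' loss of function is an established mechanism; PM2 when the variant is
#' absent or extremely rare (`< 1e-4`) in both the population reference and
#' every available East Asian frequency source; BA1 when any source exceeds
#' 5% frequency; PP3/BP4 are passed through from the annotation's
#' `evidence` column when present.
#'
#' @param variants A panel-intersected variant tibble (with `consequence`,
#'   `lof_mechanism`, frequency columns, and optionally `evidence`).
#' @param reference A reference tibble from [read_reference()].
#' @param default_an Allele number for variants absent from the reference.
#' @return `variants` with an `evidence` column of comma-separated codes.
#' @export
assign_default_evidence <- function(variants, reference, default_an = 18394L) {
  v <- lookup_reference(variants, reference, default_an = default_an)
  null_csq <- c("stopgain", "frameshift_deletion", "frameshift_insertion", "splicing")
  lof <- if ("lof_mechanism" %in% names(v)) v$lof_mechanism %in% TRUE else rep(TRUE, nrow(v))
  pvs1 <- v$consequence %in% null_csq & lof
  af <- cbind(v$af_exac_eas, v$af_kg_eas, v$af_gnomad_eas)
  af0 <- af
  af0[is.na(af0)] <- 0
  max_af <- if (nrow(v) > 0) apply(af0, 1, max) else numeric()
  pm2 <- (v$ac_ref / v$an_ref) < 1e-4 & max_af < 1e-4
  ba1 <- max_af > 0.05
  prior <- if ("evidence" %in% names(variants)) variants$evidence else rep(NA_character_, nrow(v))
  out_codes <- vapply(seq_len(nrow(v)), function(i) {
    codes <- character()
    if (pvs1[i]) codes <- c(codes, "PVS1")
    if (pm2[i]) codes <- c(codes, "PM2")
    if (ba1[i]) codes <- c(codes, "BA1")
    carried <- intersect(parse_evidence(prior[i] %||% NA_character_), c("PP3", "BP4"))
    paste(unique(c(codes, carried)), collapse = ",")
  }, character(1))
  variants$evidence <- out_codes
  variants
}

#' Classify variants into ACMG tiers
#'
#' Uses the annotation's `evidence` column when populated, otherwise falls
#' back to [assign_default_evidence()]; then combines codes with
#' [combine_evidence()] and triages with [acmg_triage()].
#'
#' @inheritParams assign_default_evidence
#' @param use_annotation_evidence Use pre-assigned evidence codes where the
#'   annotation provides them (default `TRUE`).
#' @return `variants` with `evidence`, `tier5` and `tier3` columns.
#' @export
classify_variants <- function(variants, reference, default_an = 18394L,
                              use_annotation_evidence = TRUE) {
  prior <- if ("evidence" %in% names(variants)) variants$evidence else rep(NA_character_, nrow(variants))
  defaults <- assign_default_evidence(variants, reference, default_an = default_an)$evidence
  use_prior <- use_annotation_evidence & !is.na(prior) & nzchar(prior)
  variants$evidence <- ifelse(use_prior, prior, defaults)
  variants$tier5 <- vapply(variants$evidence, function(e) {
    combine_evidence(parse_evidence(e))
  }, character(1), USE.NAMES = FALSE)
  variants$tier3 <- acmg_triage(variants$tier5)
  variants
}
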