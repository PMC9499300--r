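#' Quality-control filter configuration
#'
#' Encodes the five-criterion variant QC cascade: population rarity,
#' exonic location, coverage, strand bias and variant allele fraction.
#'
#' @param maf_max Maximum population (East Asian) allele frequency; a
#'   variant passes when its frequency is `< maf_max` (default 0.01).
#' @param maf_rule `"every_source"` (default) requires the maximum over
#'   available East Asian sources to be below `maf_max` (absent sources
#'   count as 0); `"any_source"` requires at least one available source
#'   below `maf_max`.
#' @param maf_require_all_sources When `TRUE`, variants missing any of the
#'   three frequency sources fail the rarity stage (default `FALSE`).
#' @param require_exonic Keep exonic variants only (default `TRUE`).
#' @param depth_min Minimum total read depth, strict: pass when
#'   `depth > depth_min` (default 20).
#' @param strand_bias_threshold Phred-scaled Fisher strand score threshold
#'   (default 60).
#' @param strand_bias_mode `"retain_le"` (default) keeps variants with
#'   strand-bias score `<=` the threshold, the variant-calling convention
#'   in which large scores flag strand-biased artifacts;
#'   `"retain_gt_literal"` keeps scores `>` the threshold instead.
#' @param vaf_min Minimum variant allele fraction among carriers, inclusive
#'   (default 0.25).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(maf_max = 0.01,
                          maf_rule = c("every_source", "any_source"),
                          maf_require_all_sources = FALSE,
                          require_exonic = TRUE,
                          depth_min = 20,
                          strand_bias_threshold = 60,
                          strand_bias_mode = c("retain_le", "retain_gt_literal"),
                          vaf_min = 0.25) {
  if (!(maf_max > 0 && maf_max < 1)) abort("maf_max must lie in (0, 1)")
  if (depth_min < 0) abort("depth_min must be >= 0")
  if (vaf_min < 0 || vaf_min > 1) abort("vaf_min must lie in [0, 1]")
  structure(
    list(
      maf_max = maf_max,
      maf_rule = match.arg(maf_rule),
      maf_require_all_sources = maf_require_all_sources,
      require_exonic = require_exonic,
      depth_min = depth_min,
      strand_bias_threshold = strand_bias_threshold,
      strand_bias_mode = match.arg(strand_bias_mode),
      vaf_min = vaf_min
    ),
    class = "filter_config"
  )
}

qc_pass_matrix <- function(variants, cfg) {
  af <- cbind(variants$af_exac_eas, variants$af_kg_eas, variants$af_gnomad_eas)
  n_avail <- rowSums(!is.na(af))
  af0 <- af
  af0[is.na(af0)] <- 0
  pass_maf <- switch(cfg$maf_rule,
    every_source = apply(af0, 1, max) < cfg$maf_max,
    any_source = {
      mn <- suppressWarnings(apply(af, 1, min, na.rm = TRUE))
      ifelse(n_avail == 0, TRUE, mn < cfg$maf_max)
    }
  )
  if (cfg$maf_require_all_sources) pass_maf <- pass_maf & n_avail == 3
  pass_exonic <- if (cfg$require_exonic) {
    !is.na(variants$exonic) & variants$exonic
  } else {
    rep(TRUE, nrow(variants))
  }
  pass_depth <- !is.na(variants$depth) & variants$depth > cfg$depth_min
  pass_strand <- switch(cfg$strand_bias_mode,
    retain_le = !is.na(variants$strand_bias) &
      variants$strand_bias <= cfg$strand_bias_threshold,
    retain_gt_literal = !is.na(variants$strand_bias) &
      variants$strand_bias > cfg$strand_bias_threshold
  )
  max_vaf <- vapply(variants$carrier_vaf, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else max(v)
  }, numeric(1))
  pass_vaf <- !is.na(max_vaf) & max_vaf >= cfg$vaf_min
  cbind(
    maf = pass_maf, exonic = pass_exonic, depth = pass_depth,
    strand = pass_strand, vaf = pass_vaf
  )
}

#' Apply the five-criterion QC cascade
#'
#' A variant is retained when it passes all five criteria; the stage report
#' counts survivors in the declared order (rarity, exonic, depth, strand
#' bias, VAF).  Each criterion is per-variant, so the final retained set is
#' independent of stage order; only the reported per-stage counts depend on
#' it.  Records missing a required field fail the corresponding stage.
#'
#' @param variants A variant tibble from [read_cohort()].
#' @param cfg A [filter_config()].
#' @return The retained tibble, with the stage report attached as attribute
#'   `"qc_report"` (retrieve with [qc_report()]).
#' @export
qc_filter <- function(variants, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (nrow(variants) == 0) {
    report <- tibble::tibble(
      stage = c("input", "maf", "exonic", "depth", "strand", "vaf"),
      n_pass = 0L, n_drop = 0L, dropped = list(character())
    )
    attr(variants, "qc_report") <- report
    return(variants)
  }
  pass <- qc_pass_matrix(variants, cfg)
  key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  alive <- rep(TRUE, nrow(variants))
  stages <- colnames(pass)
  n_pass <- integer(length(stages) + 1)
  n_pass[1] <- nrow(variants)
  dropped <- vector("list", length(stages) + 1)
  dropped[[1]] <- character()
  for (s in seq_along(stages)) {
    newly <- alive & !pass[, s]
    dropped[[s + 1]] <- key[newly]
    alive <- alive & pass[, s]
    n_pass[s + 1] <- sum(alive)
  }
  report <- tibble::tibble(
    stage = c("input", stages),
    n_pass = n_pass,
    n_drop = c(0L, lengths(dropped[-1])),
    dropped = dropped
  )
  out <- variants[alive, , drop = FALSE]
  attr(out, "qc_report") <- report
  out
}

#' Retrieve the QC funnel report attached by [qc_filter()]
#'
#' @param x A tibble returned by [qc_filter()] or [intersect_panel()].
#' @return A tibble with columns `stage`, `n_pass`, `n_drop`, `dropped`.
#' @export
qc_report <- function(x) {
  rep <- attr(x, "qc_report")
  if (is.null(rep)) abort("no qc_report attribute; was qc_filter() applied?")
  rep
}

#' Intersect variants with a predisposition gene panel
#'
#' Keeps variants whose gene symbol matches a panel gene (case-sensitive
#' exact match after whitespace stripping) and annotates each kept variant
#' with the panel's pathway label, DDR flag and loss-of-function mechanism
#' flag.  Variants with an empty gene symbol are dropped with a warning.
#'
#' @param variants A variant tibble (typically the output of [qc_filter()]).
#' @param panel A panel tibble from [read_panel()] or [validate_panel()].
#' @return The in-panel variants with `pathway`, `is_ddr` and
#'   `lof_mechanism` columns appended; the QC report, when present, gains a
#'   `panel` stage.
#' @export
intersect_panel <- function(variants, panel) {
  panel <- validate_panel(panel)
  report <- attr(variants, "qc_report")
  gene <- stringr::str_trim(as.character(variants$gene))
  empty <- is.na(gene) | !nzchar(gene)
  if (any(empty)) {
    warn(sprintf("%d variant(s) with empty gene symbol dropped", sum(empty)))
  }
  keep <- !empty & gene %in% panel$symbol
  out <- variants[keep, , drop = FALSE]
  out$gene <- gene[keep]
  meta <- panel[, c("symbol", "pathway", "is_ddr", "lof_mechanism")]
  out <- dplyr::left_join(out, meta, by = c(gene = "symbol"))
  if (!is.null(report)) {
    key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
    report <- dplyr::bind_rows(report, tibble::tibble(
      stage = "panel", n_pass = sum(keep), n_drop = sum(!keep),
      dropped = list(key[!keep])
    ))
  }
  attr(out, "qc_report") <- report
  out
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  cat(sprintf("  MAF < %g (%s%s)\n", x$maf_max, x$maf_rule,
              if (x$maf_require_all_sources) ", all sources required" else ""))
  cat(sprintf("  exonic required: %s\n", x$require_exonic))
  cat(sprintf("  depth > %g\n", x$depth_min))
  cat(sprintf("  strand bias %s %g\n",
              if (x$strand_bias_mode == "retain_le") "<=" else ">",
              x$strand_bias_threshold))
  cat(sprintf("  VAF >= %g\n", x$vaf_min))
  invisible(x)
}
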