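#' Write a variant tibble as a VCF 4.2 file
#'
#' Emits one record per biallelic variant with INFO fields `DP` (total
#' depth), `FS` (Phred-scaled strand-bias score) and `AF` (population
#' allele frequency when known), and per-sample `GT:AD` genotypes.
#' Carriers are written as heterozygous unless their allele count implies
#' homozygosity.  Per-sample allele depths realize the stored carrier VAF
#' at a nominal per-sample depth of 100 reads.
#'
#' @param variants A variant tibble (package format).
#' @param samples Cohort roster (column order in the VCF).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(variants, samples, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled Fisher strand bias\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Population allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  fmt_num <- function(x) sprintf("%.6g", x)
  lines <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    carriers <- v$carriers[[1]]
    vaf <- v$carrier_vaf[[1]]
    # distribute allele count: first carriers absorb any extra (hom) alleles
    n_hom <- max(0L, v$ac_case - length(carriers))
    gt <- vapply(samples, function(s) {
      j <- match(s, carriers)
      if (is.na(j)) return("0/0:100,0")
      hom <- j <= n_hom
      vf <- if (!is.na(vaf[j])) vaf[j] else 0.5
      ad_alt <- max(1L, round(vf * 100))
      sprintf("%s:%d,%d", if (hom) "1/1" else "0/1", 100L - ad_alt, ad_alt)
    }, character(1))
    info <- paste0(
      "DP=", as.integer(v$depth), ";FS=", fmt_num(v$strand_bias),
      if (!is.na(v$af_gnomad_eas)) paste0(";AF=", fmt_num(v$af_gnomad_eas)) else ""
    )
    paste(c(
      v$chrom, v$pos, ifelse(is.na(v$rsid), ".", v$rsid), v$ref, v$alt,
      ".", "PASS", info, "GT:AD", gt
    ), collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write the annotation table matching a variant tibble
#'
#' @param variants A variant tibble (package format).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(variants, path) {
  ann <- variants[, c(
    "chrom", "pos", "ref", "alt", "rsid", "gene", "consequence", "exonic",
    "af_exac_eas", "af_kg_eas", "af_gnomad_eas", "evidence"
  )]
  readr::write_tsv(ann, path, progress = FALSE)
  invisible(path)
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a self-contained synthetic study directory
#'
#' Emits, for one generated cohort: the VCF, the annotation, clinical,
#' reference and panel tables, the gene sets, the ground truth (JSON) and
#' an echo of the generator configuration (YAML).
#'
#' @param cohort A [generate_cohort()] result.
#' @param cfg The [synthetic_config()] that produced it.
#' @param dir Output directory (created if needed).
#' @param reference Optional reference tibble ([generate_reference()]).
#' @param panel Optional panel tibble.
#' @param sets Optional gene-set list.
#' @return `dir`, invisibly.
#' @export
write_synthetic_cohort <- function(cohort, cfg, dir,
                                   reference = NULL, panel = NULL,
                                   sets = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_vcf(cohort$variants, cohort$samples, file.path(dir, "cohort.vcf"))
  write_annotation(cohort$variants, file.path(dir, "annotation.tsv"))
  readr::write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"), progress = FALSE)
  if (!is.null(reference)) {
    readr::write_tsv(reference, file.path(dir, "reference.tsv"), progress = FALSE)
  }
  if (!is.null(panel)) {
    readr::write_tsv(panel, file.path(dir, "panel.tsv"), progress = FALSE)
  }
  if (!is.null(sets)) {
    write_gene_sets(sets, file.path(dir, "sets.gmt"))
  }
  truth <- cohort$truth
  truth_json <- list(
    planted = as.data.frame(dplyr::mutate(
      truth$planted,
      carriers = vapply(.data$carriers, paste, character(1), collapse = ",")
    )),
    model_carriers = lapply(truth$model_carriers, as.character),
    clinical_beta = as.list(truth$clinical_beta),
    background = if (!is.null(truth$background)) as.data.frame(truth$background)
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg_echo <- cfg[setdiff(names(cfg), c("planted", "model_genes"))]
  cfg_echo$planted <- as.data.frame(cfg$planted)
  cfg_echo$model_genes <- as.data.frame(cfg$model_genes)
  yaml::write_yaml(cfg_echo, file.path(dir, "config.yaml"))
  invisible(dir)
}
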