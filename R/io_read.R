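#' Read a cohort VCF and its annotation table into a tidy variant table
#'
#' Parses a VCF 4.x file, splits multiallelic sites into biallelic records,
#' extracts per-sample genotypes and allele-depth based variant allele
#' fractions (VAF), and joins an external annotation table carrying gene
#' symbol, consequence class, exonic flag and per-source East Asian
#' population allele frequencies.  Coordinates are 1-based VCF-style and
#' alleles must be pre-normalized (left-aligned, parsimonious); records with
#' trimmable alleles are rejected.
#'
#' Per-carrier VAF is computed from the sample AD field as
#' `alt / (ref + alt)`; when AD is absent the site-level INFO `AF` is used
#' for every carrier; when both are absent the VAF is missing and the record
#' cannot pass the VAF filter.
#'
#' @param vcf_path Path to a VCF file (uncompressed or bgzipped).
#' @param annotation_path Optional path to a tab-separated annotation table
#'   with columns `chrom, pos, ref, alt, gene, consequence, exonic,
#'   af_exac_eas, af_kg_eas, af_gnomad_eas` and optionally `rsid` and
#'   `evidence` (comma-separated ACMG codes).  Variants without an
#'   annotation row are retained with `annotated = FALSE`.
#' @return A list with elements `variants` (a tibble, one row per biallelic
#'   alternate allele, with list-columns `carriers` and `carrier_vaf`) and
#'   `samples` (the roster of sample identifiers from the VCF header).
#' @export
read_cohort <- function(vcf_path, annotation_path = NULL) {
  lines <- readLines(vcf_path)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  header_line <- lines[startsWith(lines, "#CHROM")]
  if (length(header_line) != 1) {
    abort("VCF is missing its #CHROM column header line")
  }
  header_fields <- strsplit(header_line, "\t", fixed = TRUE)[[1]]
  samples <- if (length(header_fields) > 9) header_fields[-(1:9)] else character()

  nfield <- lengths(strsplit(body, "\t", fixed = TRUE))
  bad <- which(nfield < 8)
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed VCF data line %d: expected at least 8 tab-separated fields, found %d",
      bad[1], nfield[bad[1]]
    ))
  }

  if (length(body) == 0) {
    variants <- empty_variant_table()
  } else {
    vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
    variants <- split_vcf_records(vcf, samples)
  }

  if (!is.null(annotation_path)) {
    variants <- join_annotation(variants, read_annotation(annotation_path))
  } else {
    variants$annotated <- FALSE
  }

  bad_allele <- !is_parsimonious(variants$ref, variants$alt)
  if (any(bad_allele)) {
    k <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
    abort(paste0(
      "non-parsimonious (trimmable) alleles; normalize the VCF first: ",
      paste(head(k[bad_allele], 5), collapse = ", ")
    ))
  }

  list(variants = variants, samples = samples)
}

empty_variant_table <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    rsid = character(), depth = numeric(), strand_bias = numeric(),
    ac_case = integer(), carriers = list(), carrier_vaf = list(),
    gene = character(), consequence = character(), exonic = logical(),
    af_exac_eas = numeric(), af_kg_eas = numeric(), af_gnomad_eas = numeric(),
    evidence = character(), annotated = logical()
  )
}

# One row per (site, alt allele); genotype "1/2" contributes one alt allele
# to each of the two split records, conserving total alt genotype count.
split_vcf_records <- function(vcf, samples) {
  fix <- vcfR::getFIX(vcf)
  if (is.null(nrow(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_sites <- nrow(fix)
  info_dp <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "DP")))
  info_fs <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "FS")))
  info_af <- vcfR::extract.info(vcf, element = "AF")
  has_gt <- length(samples) > 0 && !is.null(vcf@gt)
  gt <- if (has_gt) vcfR::extract.gt(vcf, element = "GT") else NULL
  ad <- if (has_gt) vcfR::extract.gt(vcf, element = "AD") else NULL

  rows <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    afs <- if (!is.null(info_af) && !is.na(info_af[i])) {
      suppressWarnings(as.numeric(strsplit(info_af[i], ",", fixed = TRUE)[[1]]))
    } else {
      rep(NA_real_, length(alts))
    }
    gt_alleles <- if (has_gt) {
      strsplit(gsub("|", "/", gt[i, ], fixed = TRUE), "/", fixed = TRUE)
    } else {
      NULL
    }
    ad_fields <- if (has_gt && !is.null(ad)) {
      lapply(strsplit(ad[i, ], ",", fixed = TRUE), function(x) suppressWarnings(as.numeric(x)))
    } else {
      NULL
    }
    site_rows <- vector("list", length(alts))
    for (k in seq_along(alts)) {
      if (has_gt) {
        n_alt <- vapply(gt_alleles, function(a) sum(a == as.character(k), na.rm = TRUE), integer(1))
        carriers <- samples[n_alt > 0]
        ac <- sum(n_alt)
        vaf <- vapply(which(n_alt > 0), function(j) {
          adj <- if (!is.null(ad_fields)) ad_fields[[j]] else NA_real_
          if (length(adj) >= k + 1 && !anyNA(adj[c(1, k + 1)])) {
            tot <- adj[1] + adj[k + 1]
            if (tot > 0) adj[k + 1] / tot else NA_real_
          } else if (k <= length(afs)) {
            afs[k]
          } else {
            NA_real_
          }
        }, numeric(1))
      } else {
        carriers <- character()
        ac <- 0L
        vaf <- numeric()
      }
      site_rows[[k]] <- tibble::tibble(
        chrom = fix[i, "CHROM"],
        pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"],
        alt = alts[k],
        rsid = if (is.na(fix[i, "ID"]) || fix[i, "ID"] == ".") NA_character_ else fix[i, "ID"],
        depth = info_dp[i],
        strand_bias = info_fs[i],
        ac_case = as.integer(ac),
        carriers = list(unname(carriers)),
        carrier_vaf = list(unname(vaf))
      )
    }
    rows[[i]] <- dplyr::bind_rows(site_rows)
  }
  dplyr::bind_rows(rows)
}

read_annotation <- function(path) {
  ann <- readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE,
    # allele columns must never be type-guessed ("T" is not a logical)
    col_types = readr::cols(
      chrom = readr::col_character(), ref = readr::col_character(),
      alt = readr::col_character()
    )
  )
  assert_columns(ann, c(
    "chrom", "pos", "ref", "alt", "gene", "consequence", "exonic",
    "af_exac_eas", "af_kg_eas", "af_gnomad_eas"
  ), "annotation table")
  key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  if (anyDuplicated(key)) {
    abort(paste0(
      "duplicate (chrom,pos,ref,alt) in annotation table: ",
      paste(unique(key[duplicated(key)]), collapse = ", ")
    ))
  }
  afs <- c("af_exac_eas", "af_kg_eas", "af_gnomad_eas")
  for (col in afs) {
    x <- ann[[col]]
    if (any(!is.na(x) & (x < 0 | x > 1))) {
      abort(paste0(col, " must lie in [0, 1]"))
    }
  }
  ann$chrom <- as.character(ann$chrom)
  ann$pos <- as.integer(ann$pos)
  ann$exonic <- as.logical(ann$exonic)
  if (!"evidence" %in% names(ann)) ann$evidence <- NA_character_
  known <- c(
    "nonsynonymous_SNV", "stopgain", "frameshift_deletion",
    "frameshift_insertion", "splicing", "synonymous", "nonframeshift", "other"
  )
  odd <- !is.na(ann$consequence) & !ann$consequence %in% known
  if (any(odd)) {
    warn(paste0(
      "unrecognized consequence class(es) mapped to 'other': ",
      paste(unique(ann$consequence[odd]), collapse = ", ")
    ))
    ann$consequence[odd] <- "other"
  }
  ann
}

join_annotation <- function(variants, ann) {
  keep <- c(
    "chrom", "pos", "ref", "alt", "gene", "consequence", "exonic",
    "af_exac_eas", "af_kg_eas", "af_gnomad_eas", "evidence"
  )
  if ("rsid" %in% names(ann)) {
    # annotation rsid fills gaps in the VCF ID column
    keep <- c(keep, "rsid")
    ann <- dplyr::rename(ann, rsid_ann = "rsid")
    keep[keep == "rsid"] <- "rsid_ann"
  }
  out <- dplyr::left_join(
    variants, ann[, keep],
    by = c("chrom", "pos", "ref", "alt")
  )
  if ("rsid_ann" %in% names(out)) {
    out$rsid <- dplyr::coalesce(out$rsid, out$rsid_ann)
    out$rsid_ann <- NULL
  }
  out$annotated <- !is.na(out$gene) | !is.na(out$consequence)
  out
}

#' Read a predisposition gene panel
#'
#' @param path Tab-separated file with columns `symbol`, `categories`
#'   (semicolon-separated subset of `hereditary_cancer`, `cosmic_driver`,
#'   `pca_predisposition`), `pathway`, `is_ddr`, and optionally
#'   `lof_mechanism` (whether loss of function is an established disease
#'   mechanism for the gene, used by the default ACMG evidence assigner).
#' @return A tibble with one row per panel gene.
#' @export
read_panel <- function(path) {
  panel <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(panel, c("symbol", "categories", "pathway", "is_ddr"), "gene panel")
  validate_panel(panel)
}

#' @rdname read_panel
#' @param panel A data frame shaped like the file read by `read_panel()`.
#' @export
validate_panel <- function(panel) {
  panel$symbol <- stringr::str_trim(panel$symbol)
  if (any(!nzchar(panel$symbol) | is.na(panel$symbol))) {
    abort("panel contains an empty gene symbol")
  }
  if (anyDuplicated(panel$symbol)) {
    abort(paste0(
      "duplicate panel gene symbol(s): ",
      paste(unique(panel$symbol[duplicated(panel$symbol)]), collapse = ", ")
    ))
  }
  bad_path <- !panel$pathway %in% pathway_vocabulary()
  if (any(bad_path)) {
    abort(paste0(
      "pathway label(s) outside the controlled vocabulary: ",
      paste(unique(panel$pathway[bad_path]), collapse = ", ")
    ))
  }
  panel$is_ddr <- as.logical(panel$is_ddr)
  if (!"lof_mechanism" %in% names(panel)) panel$lof_mechanism <- TRUE
  panel$lof_mechanism <- as.logical(panel$lof_mechanism)
  tibble::as_tibble(panel)
}

#' Controlled vocabulary of panel pathway labels
#'
#' @return Character vector of recognized pathway labels.
#' @export
pathway_vocabulary <- function() {
  c(
    "DNA_methylation", "DDR", "tyrosine_protein_kinase", "GPCR_signaling",
    "peroxisome", "MAPK_ERK", "ErbB", "cell_cycle",
    "regulation_of_lipid_metabolism", "ILK_signaling", "hydrolase", "other"
  )
}

#' Read a population reference allele-count table
#'
#' The table emulates a population database extract (e.g. East Asian
#' allele counts): one row per observed variant with alternate allele count
#' `ac` and total allele number `an`.  Variants absent from the table are,
#' by convention, unobserved in the reference (`ac = 0`) at a configured
#' default `an`.
#'
#' @param path Tab-separated file with header `chrom, pos, ref, alt, ac, an`.
#' @return A tibble keyed by (chrom, pos, ref, alt).
#' @export
read_reference <- function(path) {
  ref <- readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE,
    # allele columns must never be type-guessed ("T" is not a logical)
    col_types = readr::cols(
      chrom = readr::col_character(), ref = readr::col_character(),
      alt = readr::col_character()
    )
  )
  assert_columns(ref, c("chrom", "pos", "ref", "alt", "ac", "an"), "reference table")
  ref$chrom <- as.character(ref$chrom)
  ref$pos <- as.integer(ref$pos)
  bad <- which(ref$ac > ref$an | ref$ac < 0 | ref$an <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "reference table row %d: need 0 <= ac <= an and an > 0 (ac = %s, an = %s)",
      bad[1], ref$ac[bad[1]], ref$an[bad[1]]
    ))
  }
  key <- variant_key(ref$chrom, ref$pos, ref$ref, ref$alt)
  if (anyDuplicated(key)) {
    abort(paste0(
      "duplicate (chrom,pos,ref,alt) in reference table: ",
      paste(unique(key[duplicated(key)]), collapse = ", ")
    ))
  }
  tibble::as_tibble(ref)
}

#' Look up reference allele counts for a set of variants
#'
#' @param variants A variant tibble with `chrom, pos, ref, alt` columns.
#' @param reference A reference tibble from [read_reference()].
#' @param default_an Allele number assumed for variants absent from the
#'   reference (default `18394`, i.e. two alleles for each of 9,197 diploid
#'   individuals).
#' @return `variants` with `ac_ref` and `an_ref` columns appended; absent
#'   variants get `ac_ref = 0`, `an_ref = default_an`.
#' @export
lookup_reference <- function(variants, reference, default_an = 18394L) {
  ref <- dplyr::rename(reference, ac_ref = "ac", an_ref = "an")
  out <- dplyr::left_join(variants, ref, by = c("chrom", "pos", "ref", "alt"))
  out$ac_ref[is.na(out$ac_ref)] <- 0L
  out$an_ref[is.na(out$an_ref)] <- as.integer(default_an)
  out
}

#' Read clinical covariates
#'
#' @param path Tab-separated file with columns `sample_id, age, psa, isup,
#'   metastasis` (`M0`/`M1`) and optionally `crpc_within_1yr`.
#' @return A validated tibble of per-patient clinical records.
#' @export
read_clinical <- function(path) {
  cl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(cl, c("sample_id", "age", "psa", "isup", "metastasis"), "clinical table")
  if (any(!cl$isup %in% 1:5)) abort("isup must be an integer grade in 1..5")
  if (any(cl$psa < 0, na.rm = TRUE)) abort("psa must be non-negative")
  if (any(cl$age <= 0, na.rm = TRUE)) abort("age must be positive")
  if (any(!cl$metastasis %in% c("M0", "M1"))) {
    abort("metastasis must be coded M0/M1")
  }
  if (!"crpc_within_1yr" %in% names(cl)) cl$crpc_within_1yr <- NA
  cl$crpc_within_1yr <- as.logical(cl$crpc_within_1yr)
  tibble::as_tibble(cl)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (duplicate members collapsed).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    abort(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  }
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    abort(paste0(
      "duplicate gene-set name(s): ",
      paste(unique(nm[duplicated(nm)]), collapse = ", ")
    ))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  if (any(lengths(sets) == 0)) abort("GMT contains an empty gene set")
  setNames(sets, nm)
}

#' Write and re-read result tables losslessly
#'
#' Doubles are serialized with 15 significant digits so a written table
#' re-reads to the same values (12-significant-digit text equality; whole
#' numbers re-read as doubles of exact value).  List-columns (e.g.
#' `carriers`) are collapsed to comma-separated strings.
#'
#' @param x A tibble.
#' @param path Output TSV path.
#' @return `x`, invisibly.
#' @export
write_result_table <- function(x, path) {
  out <- x
  is_list <- vapply(out, is.list, logical(1))
  for (col in names(out)[is_list]) {
    out[[col]] <- vapply(out[[col]], function(v) paste(v, collapse = ","), character(1))
  }
  is_dbl <- vapply(out, is.double, logical(1))
  for (col in names(out)[is_dbl]) {
    out[[col]] <- sprintf("%.15g", out[[col]])
    out[[col]][out[[col]] == "NA"] <- NA_character_
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(x)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
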