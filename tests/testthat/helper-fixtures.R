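# In-code fixture builders shared across test files.

# Build a one-row variant tibble with sensible defaults.
make_variant <- function(chrom = "1", pos = 100L, ref = "G", alt = "A",
                         gene = "BRCA2", consequence = "nonsynonymous_SNV",
                         exonic = TRUE, depth = 50, strand_bias = 5,
                         af_gnomad_eas = 1e-4, af_exac_eas = NA_real_,
                         af_kg_eas = NA_real_,
                         carriers = c("s1"), vaf = rep(0.5, length(carriers)),
                         ac_case = length(carriers),
                         rsid = NA_character_, evidence = NA_character_) {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt, rsid = rsid,
    depth = depth, strand_bias = strand_bias, ac_case = as.integer(ac_case),
    carriers = list(carriers), carrier_vaf = list(vaf),
    gene = gene, consequence = consequence, exonic = exonic,
    af_exac_eas = af_exac_eas, af_kg_eas = af_kg_eas,
    af_gnomad_eas = af_gnomad_eas,
    evidence = evidence, annotated = TRUE
  )
}

make_variants <- function(...) {
  if (...length() == 0) return(make_variant()[0, ])
  dplyr::bind_rows(...)
}

# Write a small VCF from explicit genotype strings.
write_test_vcf <- function(path, samples, records) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"f\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"a\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, records), path)
}

# A tiny reference table.
make_reference <- function(...) {
  rows <- list(...)
  if (length(rows) == 0) {
    return(tibble::tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), ac = integer(), an = integer()
    ))
  }
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      chrom = r[[1]], pos = as.integer(r[[2]]), ref = r[[3]], alt = r[[4]],
      ac = as.integer(r[[5]]), an = as.integer(r[[6]])
    )
  }))
}

# A carrier structure with a given number of single- and dual-variant
# patients: the first `n_dual` patients carry two variants each, the rest
# of the variants go to one fresh patient apiece.
make_carrier_structure <- function(n_variants, n_dual, n_patients,
                                   prefix = "p") {
  samples <- sprintf("%s%03d", prefix, seq_len(n_patients))
  n_single <- n_variants - 2 * n_dual
  carriers <- c(
    rep(samples[seq_len(n_dual)], 2),
    samples[n_dual + seq_len(n_single)]
  )
  vs <- lapply(seq_len(n_variants), function(i) {
    make_variant(pos = 1000L + i, carriers = carriers[i])
  })
  list(variants = dplyr::bind_rows(vs), samples = samples)
}

random_evidence_subset <- function(max_size = 6) {
  sample(acmg_codes(), sample.int(max_size + 1, 1) - 1)
}
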