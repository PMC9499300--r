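clean_variant <- function(pos) {
  make_variant(
    pos = pos, af_gnomad_eas = 0.009, exonic = TRUE, depth = 25,
    strand_bias = 10, vaf = 0.30
  )
}

test_that("a variant meeting every threshold is retained", {
  out <- qc_filter(clean_variant(1L))
  expect_equal(nrow(out), 1)
  expect_equal(qc_report(out)$n_pass, rep(1L, 6))
})

test_that("empty input yields empty output and an all-zero report", {
  out <- qc_filter(make_variants())
  expect_equal(nrow(out), 0)
  expect_true(all(qc_report(out)$n_pass == 0))
})

test_that("each criterion drops exactly its offending variant, in order", {
  vs <- make_variants(
    make_variant(pos = 1L, af_gnomad_eas = 0.02),          # fails MAF
    make_variant(pos = 2L, exonic = FALSE),                # fails exonic
    make_variant(pos = 3L, depth = 15),                    # fails depth
    make_variant(pos = 4L, strand_bias = 80),              # fails strand (retain_le)
    make_variant(pos = 5L, vaf = 0.10),                    # fails VAF
    clean_variant(6L)
  )
  out <- qc_filter(vs)
  expect_equal(nrow(out), 1)
  expect_equal(out$pos, 6L)
  rep <- qc_report(out)
  expect_equal(rep$stage, c("input", "maf", "exonic", "depth", "strand", "vaf"))
  expect_equal(rep$n_pass, c(6L, 5L, 4L, 3L, 2L, 1L))
  expect_equal(rep$n_drop, c(0L, 1L, 1L, 1L, 1L, 1L))
})

test_that("depth is strict > and VAF is inclusive >=", {
  at_depth <- make_variant(pos = 1L, depth = 20)
  expect_equal(nrow(qc_filter(at_depth)), 0)
  above <- make_variant(pos = 1L, depth = 20.5)
  expect_equal(nrow(qc_filter(above)), 1)
  at_vaf <- make_variant(pos = 2L, vaf = 0.25)
  expect_equal(nrow(qc_filter(at_vaf)), 1)
})

test_that("strand-bias mode retain_gt_literal inverts the retained side", {
  biased <- make_variant(pos = 1L, strand_bias = 80)
  clean <- make_variant(pos = 2L, strand_bias = 10)
  cfg <- filter_config(strand_bias_mode = "retain_gt_literal")
  out <- qc_filter(make_variants(biased, clean), cfg)
  expect_equal(out$pos, 1L)
})

test_that("MAF uses the maximum across available sources; any_source relaxes it", {
  v <- make_variant(
    pos = 1L, af_gnomad_eas = 0.02, af_exac_eas = 0.001, af_kg_eas = NA_real_
  )
  expect_equal(nrow(qc_filter(v)), 0) # max 0.02 >= 0.01
  cfg <- filter_config(maf_rule = "any_source")
  expect_equal(nrow(qc_filter(v, cfg)), 1) # min available 0.001 < 0.01
  # absent sources count as zero under the default rule
  v2 <- make_variant(
    pos = 2L, af_gnomad_eas = NA_real_, af_exac_eas = NA_real_,
    af_kg_eas = NA_real_
  )
  expect_equal(nrow(qc_filter(v2)), 1)
  cfg_all <- filter_config(maf_require_all_sources = TRUE)
  expect_equal(nrow(qc_filter(v2, cfg_all)), 0)
})

test_that("records with missing required fields are dropped, not an error", {
  no_vaf <- make_variant(pos = 1L, vaf = NA_real_)
  no_depth <- make_variant(pos = 2L, depth = NA_real_)
  out <- qc_filter(make_variants(no_vaf, no_depth, clean_variant(3L)))
  expect_equal(out$pos, 3L)
})

test_that("the final retained set is the intersection of the per-criterion sets", {
  set.seed(41)
  vs <- dplyr::bind_rows(lapply(1:60, function(i) {
    make_variant(
      pos = i,
      af_gnomad_eas = sample(c(0.001, 0.02, NA), 1),
      exonic = sample(c(TRUE, FALSE), 1),
      depth = sample(c(10, 30), 1),
      strand_bias = sample(c(5, 80), 1),
      vaf = sample(c(0.1, 0.5), 1)
    )
  }))
  full <- qc_filter(vs)
  one_criterion <- function(cfg) qc_filter(vs, cfg)$pos
  relaxed <- filter_config(
    maf_max = 0.99, require_exonic = FALSE, depth_min = 0,
    strand_bias_threshold = 1e6, vaf_min = 0
  )
  sets <- list(
    one_criterion(filter_config(require_exonic = FALSE, depth_min = 0,
                                strand_bias_threshold = 1e6, vaf_min = 0)),
    one_criterion(filter_config(maf_max = 0.99, depth_min = 0,
                                strand_bias_threshold = 1e6, vaf_min = 0)),
    one_criterion(filter_config(maf_max = 0.99, require_exonic = FALSE,
                                strand_bias_threshold = 1e6, vaf_min = 0)),
    one_criterion(filter_config(maf_max = 0.99, require_exonic = FALSE,
                                depth_min = 0, vaf_min = 0)),
    one_criterion(filter_config(maf_max = 0.99, require_exonic = FALSE,
                                depth_min = 0, strand_bias_threshold = 1e6))
  )
  expect_setequal(full$pos, Reduce(intersect, sets))
  # relaxing every threshold keeps everything
  expect_equal(nrow(qc_filter(vs, relaxed)), nrow(vs))
})

test_that("relaxing any single threshold never shrinks the retained set", {
  set.seed(42)
  vs <- dplyr::bind_rows(lapply(1:40, function(i) {
    make_variant(
      pos = i,
      af_gnomad_eas = runif(1, 0, 0.03),
      exonic = sample(c(TRUE, FALSE), 1),
      depth = runif(1, 5, 40),
      strand_bias = runif(1, 0, 100),
      vaf = runif(1, 0, 1)
    )
  }))
  base_cfg <- filter_config()
  base <- qc_filter(vs, base_cfg)$pos
  relaxations <- list(
    filter_config(maf_max = 0.02),
    filter_config(require_exonic = FALSE),
    filter_config(depth_min = 10),
    filter_config(strand_bias_threshold = 90),
    filter_config(vaf_min = 0.1)
  )
  for (cfg in relaxations) {
    expect_true(all(base %in% qc_filter(vs, cfg)$pos))
  }
})

test_that("panel intersection keeps in-panel genes and transfers labels", {
  panel <- tibble::tibble(
    symbol = c("BRCA2", "KMT2C", "SUGCT"), categories = "hereditary_cancer",
    pathway = c("DDR", "DNA_methylation", "peroxisome"),
    is_ddr = c(TRUE, FALSE, FALSE)
  )
  vs <- make_variants(
    make_variant(pos = 1L, gene = "BRCA2"),
    make_variant(pos = 2L, gene = "TTN"),
    make_variant(pos = 3L, gene = " KMT2C "), # whitespace-stripped match
    make_variant(pos = 4L, gene = "kmt2c")    # case-sensitive: no match
  )
  out <- intersect_panel(vs, panel)
  expect_equal(out$pos, c(1L, 3L))
  expect_equal(out$pathway, c("DDR", "DNA_methylation"))
  expect_equal(out$is_ddr, c(TRUE, FALSE))

  expect_equal(nrow(intersect_panel(vs, panel[0, ])), 0)
  expect_warning(
    empty_sym <- intersect_panel(make_variant(pos = 9L, gene = ""), panel),
    "empty gene symbol"
  )
  expect_equal(nrow(empty_sym), 0)
})
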