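test_that("generation is deterministic given the seed", {
  cfg <- synthetic_config(seed = 42, n_patients = 40, background_rate = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_identical(generate_reference(cfg, a), generate_reference(cfg, b))

  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  write_synthetic_cohort(a, cfg, dir_a, reference = generate_reference(cfg, a))
  write_synthetic_cohort(b, cfg, dir_b, reference = generate_reference(cfg, b))
  for (f in list.files(dir_a)) {
    expect_identical(readLines(file.path(dir_a, f)),
                     readLines(file.path(dir_b, f)),
                     info = f)
  }

  c2 <- generate_cohort(synthetic_config(seed = 43, n_patients = 40,
                                         background_rate = 5))
  expect_false(identical(a$clinical, c2$clinical))
})

test_that("realized carrier counts track the planted probabilities", {
  planted <- default_planted_variants()
  recurrent <- which(planted$carrier_probability == 0.04)
  counts <- vapply(1:400, function(s) {
    co <- generate_cohort(synthetic_config(
      seed = s, n_patients = 100, background_rate = 0,
      model_genes = default_model_genes()[0, ]
    ))
    length(co$truth$planted$carriers[[recurrent]])
  }, numeric(1))
  # Binomial(100, 0.04): mean 4, se of the mean over 400 reps ~ 0.098
  expect_lt(abs(mean(counts) - 4), 0.4)
})

test_that("background_rate zero yields only planted and model variants", {
  co <- generate_cohort(synthetic_config(seed = 7, n_patients = 100,
                                         background_rate = 0))
  expect_true(all(grepl("^rs[SM]", co$variants$rsid)))
  expect_true(all(co$variants$ac_case > 0))
  expect_true(all(lengths(co$variants$carriers) > 0))
  expect_null(co$truth$background)
})

test_that("the reference table uses a constant AN and the planted rounding rule", {
  cfg <- synthetic_config(seed = 11, n_patients = 60, background_rate = 10)
  co <- generate_cohort(cfg)
  ref <- generate_reference(cfg, co)
  expect_true(all(ref$an == 18394L))
  expect_true(all(ref$ac > 0))
  # planted reference_af of 5e-5 implies ac = round(5e-5 * 18394) = 1
  planted <- co$truth$planted
  seeded <- planted[planted$reference_af == 5e-5, ]
  key <- variant_key(seeded$chrom, seeded$pos, seeded$ref, seeded$alt)
  hit <- ref[variant_key(ref$chrom, ref$pos, ref$ref, ref$alt) %in% key, ]
  expect_true(all(hit$ac == 1L))
  # reference_af of 0 means the variant is absent from the table
  absent <- planted[planted$reference_af == 0, ]
  key0 <- variant_key(absent$chrom, absent$pos, absent$ref, absent$alt)
  expect_false(any(variant_key(ref$chrom, ref$pos, ref$ref, ref$alt) %in% key0))
})

test_that("the panel holds every planted and model gene plus decoys", {
  cfg <- synthetic_config(seed = 3)
  art <- generate_panel_and_sets(cfg)
  expect_equal(nrow(art$panel), 1166)
  expect_true(all(cfg$planted$gene %in% art$panel$symbol))
  expect_true(all(cfg$model_genes$gene %in% art$panel$symbol))
  expect_true(any(grepl("^DECOY", art$panel$symbol)))
  expect_true(all(cfg$model_genes$gene %in% art$sets$PI3K_AKT_like))
  expect_false(anyDuplicated(art$panel$symbol) > 0)
})

test_that("written artifacts read back into an equivalent cohort", {
  cfg <- synthetic_config(seed = 21, n_patients = 30, background_rate = 3)
  co <- generate_cohort(cfg)
  ref <- generate_reference(cfg, co)
  dir <- withr::local_tempdir()
  write_synthetic_cohort(co, cfg, dir, reference = ref)

  back <- read_cohort(file.path(dir, "cohort.vcf"),
                      file.path(dir, "annotation.tsv"))
  expect_setequal(back$samples, co$samples)
  v0 <- dplyr::arrange(co$variants, .data$chrom, .data$pos)
  v1 <- dplyr::arrange(back$variants, .data$chrom, .data$pos)
  expect_equal(nrow(v1), nrow(v0))
  expect_equal(variant_key(v1$chrom, v1$pos, v1$ref, v1$alt),
               variant_key(v0$chrom, v0$pos, v0$ref, v0$alt))
  expect_equal(v1$ac_case, v0$ac_case)
  expect_equal(v1$depth, v0$depth)
  expect_equal(v1$gene, v0$gene)
  for (i in seq_len(nrow(v0))) {
    expect_setequal(v1$carriers[[i]], v0$carriers[[i]])
  }
  ref_back <- read_reference(file.path(dir, "reference.tsv"))
  expect_equal(dplyr::arrange(ref_back, .data$pos),
               dplyr::arrange(ref, .data$pos))
})

test_that("default study conditions land near the intended carrier prevalence", {
  pcts <- vapply(1:30, function(s) {
    co <- generate_cohort(synthetic_config(seed = 1000 + s, background_rate = 0))
    planted_keys <- variant_key(
      co$truth$planted$chrom, co$truth$planted$pos,
      co$truth$planted$ref, co$truth$planted$alt
    )
    v <- co$variants[variant_key(co$variants$chrom, co$variants$pos,
                                 co$variants$ref, co$variants$alt) %in%
                       planted_keys, ]
    length(unique(unlist(v$carriers)))
  }, numeric(1))
  expect_gt(mean(pcts), 20)
  expect_lt(mean(pcts), 38)
})

test_that("config validation rejects malformed inputs", {
  expect_error(synthetic_config(), "seed")
  bad <- default_planted_variants()
  bad$carrier_probability[1] <- 1.5
  expect_error(synthetic_config(seed = 1, planted = bad), "carrier_probability")
  expect_error(synthetic_config(seed = 1, n_ref_individuals = 0), "positive")
})
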