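test_that("contingency construction matches the allele-accounting rules", {
  # four heterozygous carriers among 100 patients vs reference 1/18394
  t1 <- build_contingency(ac_case = 4, n_cases = 100, ac_ref = 1, an_ref = 18394)
  expect_equal(unname(t1), c(4L, 196L, 1L, 18393L))
  # zero carriers
  t2 <- build_contingency(ac_case = 0, n_cases = 100, ac_ref = 5, an_ref = 18394)
  expect_equal(unname(t2[1:2]), c(0L, 200L))
  # one homozygous carrier contributes two alleles
  t3 <- build_contingency(ac_case = 2, n_cases = 100, ac_ref = 0, an_ref = 18394)
  expect_equal(unname(t3[1]), 2L)
  # carrier mode counts patients, reference as carrier estimate over an/2
  t4 <- build_contingency(
    ac_case = 2, n_cases = 100, ac_ref = 3, an_ref = 18394,
    mode = "carrier", n_carriers = 2
  )
  expect_equal(unname(t4), c(2L, 98L, 3L, 9194L))
  expect_error(build_contingency(300, 100, 0, 18394), "exceeds")
})

test_that("Fisher p is exact on degenerate and symmetric tables", {
  expect_equal(fisher_exact_two_sided(2, 8, 2, 8), 1)
  expect_equal(fisher_exact_two_sided(0, 10, 0, 10), 1)
  expect_error(fisher_exact_two_sided(-1, 1, 1, 1), "non-negative")
})

test_that("Fisher p matches the enumeration oracle and stats::fisher.test", {
  set.seed(7)
  for (i in 1:300) {
    cells <- c(
      sample(0:12, 1), sample(0:12, 1), sample(0:12, 1), sample(0:12, 1)
    )
    p_impl <- fisher_exact_two_sided(cells[1], cells[2], cells[3], cells[4])
    p_oracle <- oracle_fisher_p(cells[1], cells[2], cells[3], cells[4])
    expect_equal(p_impl, p_oracle, tolerance = 1e-7)
    if (sum(cells) > 0) {
      p_base <- fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
      expect_equal(p_impl, min(1, p_base), tolerance = 1e-7)
    }
  }
  # extreme margins typical of a cohort-vs-reference comparison
  expect_equal(
    fisher_exact_two_sided(4, 196, 1, 18393),
    fisher.test(matrix(c(4, 196, 1, 18393), 2, byrow = TRUE))$p.value,
    tolerance = 1e-7
  )
})

test_that("odds ratio applies the continuity correction only when needed", {
  sym <- odds_ratio_ci(5, 95, 5, 95)
  expect_equal(sym$or, 1)
  expect_false(sym$corrected)

  corr <- odds_ratio_ci(1, 199, 0, 18394)
  expect_true(corr$corrected)
  expect_equal(corr$or, (1.5 / 199.5) / (0.5 / 18394.5))
  expect_equal(corr$or, 276.6, tolerance = 0.1 / 276.6)
  expect_lt(corr$ci_low, corr$or)
  expect_gt(corr$ci_high, corr$or)

  prop <- odds_ratio_ci(2, 98, 20, 980)
  expect_equal(prop$or, 1)
  expect_error(odds_ratio_ci(0, 0, 0, 0), "all-zero")
})

test_that("uncorrected OR is invariant to transposition and double row swap", {
  o <- odds_ratio_ci(3, 7, 5, 11)
  expect_equal(odds_ratio_ci(3, 5, 7, 11)$or, o$or)  # transpose
  expect_equal(odds_ratio_ci(7, 3, 11, 5)$or, 1 / o$or) # one swap inverts
  expect_equal(odds_ratio_ci(11, 5, 7, 3)$or, o$or)  # double inversion
})

test_that("BH step-up reproduces hand-computed adjustments and properties", {
  expect_equal(adjust_fdr(0.5), 0.5)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(12)
  p <- runif(50)
  q <- adjust_fdr(p)
  expect_true(all(q >= 0 & q <= 1))
  expect_false(is.unsorted(q[order(p)])) # q order-preserving in p
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(adjust_fdr(c(0.01, 0.5), method = "bonferroni"), c(0.02, 1))
})

test_that("raising any p-value never grows the BH-significant set", {
  set.seed(5)
  for (i in 1:50) {
    p <- runif(20)
    sig <- which(adjust_fdr(p) <= 0.05)
    j <- sample(20, 1)
    p2 <- p
    p2[j] <- min(1, p[j] + runif(1, 0, 1 - p[j]))
    expect_true(all(which(adjust_fdr(p2) <= 0.05) %in% union(sig, j)))
  }
})

test_that("run_enrichment flags a strongly enriched planted variant", {
  ref <- make_reference(list("1", 100L, "G", "A", 1, 18394))
  v <- make_variant(
    pos = 100L, carriers = paste0("s", 1:4), vaf = rep(0.5, 4), ac_case = 4
  )
  res <- run_enrichment(v, n_cases = 100, reference = ref)
  expect_true(res$significant)
  expect_equal(res$a, 4L)
  expect_equal(res$c, 1L)
  expect_lt(res$q, 0.05)
  expect_gt(res$or, 1)
})

test_that("a frequency-matched variant is not significant and ORs respect direction", {
  # identical case and reference frequency: 2/200 vs 184/18394
  ref <- make_reference(list("1", 100L, "G", "A", 184, 18400))
  v <- make_variant(pos = 100L, carriers = c("s1", "s2"), ac_case = 2)
  res <- run_enrichment(v, n_cases = 100, reference = ref)
  expect_false(res$significant)

  # every significant variant must have OR >= 1 (direction filter)
  set.seed(31)
  vs <- dplyr::bind_rows(lapply(1:20, function(i) {
    make_variant(pos = i, carriers = paste0("s", seq_len(sample(0:5, 1))))
  }))
  vs$ac_case <- lengths(vs$carriers)
  ref2 <- make_reference(list("1", 1L, "G", "A", 500, 18394))
  res2 <- run_enrichment(vs, n_cases = 100, reference = ref2)
  expect_true(all(res2$or[res2$significant] >= 1))
})

test_that("empty input warns and returns an empty result", {
  ref <- make_reference(list("1", 1L, "G", "A", 1, 18394))
  expect_warning(res <- run_enrichment(make_variants(), 100, ref), "no variants")
  expect_equal(nrow(res), 0)
})

test_that("VUS-mode significance uses raw p at the supplied cutoff", {
  ref <- make_reference(list("1", 100L, "G", "A", 2, 18394))
  v <- make_variant(pos = 100L, carriers = c("s1", "s2"), ac_case = 2)
  res_fdr <- run_enrichment(v, 100, ref)
  res_p <- run_enrichment(v, 100, ref, p_cutoff = 0.05)
  expect_equal(res_p$significant, res_p$p <= 0.05 & res_p$case_freq > res_p$ref_freq)
  expect_equal(res_fdr$p, res_p$p)
})
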