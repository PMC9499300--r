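test_that("overrepresentation p-values match closed forms", {
  # query = set = universe is degenerate: p = 1
  u <- paste0("g", 1:10)
  res <- ora_test(u, list(all = u), u)
  expect_equal(res$p, 1)
  expect_equal(res$k, 10)

  # perfect draw: N=20, K=5, n=5, k=5 -> 1 / C(20,5)
  u2 <- paste0("g", 1:20)
  res2 <- ora_test(u2[1:5], list(s = u2[1:5]), u2)
  expect_equal(res2$p, 1 / choose(20, 5))

  # empty overlap: p = P[X >= 0] = 1
  res3 <- ora_test(u2[6:10], list(s = u2[1:5]), u2)
  expect_equal(res3$k, 0)
  expect_equal(res3$p, 1)

  expect_error(ora_test("g1", list(s = "g1"), character()), "universe")
  expect_error(ora_test("zz", list(s = "g1"), u2), "outside")
})

test_that("overrepresentation matches exhaustive draw enumeration for small universes", {
  set.seed(17)
  for (i in 1:25) {
    N <- sample(5:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    u <- paste0("g", seq_len(N))
    query <- sample(u, n)
    res <- ora_test(query, list(s = u[seq_len(K)]), u)
    expect_equal(res$p, oracle_ora_p(N, K, n, res$k), tolerance = 1e-10)
  }
})

test_that("logistic coefficients shrink to zero under the null", {
  set.seed(100)
  n <- 5000
  d <- tibble::tibble(
    x1 = stats::rnorm(n), x2 = stats::rbinom(n, 1, 0.3),
    y = stats::rbinom(n, 1, 0.4)
  )
  fit <- fit_logistic(y ~ x1 + x2, d)
  expect_true(all(abs(coef(fit)[c("x1", "x2")]) < 0.1))
  expect_false(fit$separation)
})

test_that("logistic fitting recovers planted coefficients and matches glm", {
  set.seed(101)
  n <- 2000
  x1 <- stats::rnorm(n)
  x2 <- stats::rbinom(n, 1, 0.4)
  eta <- -1 + 0.8 * x1 + 0.5 * x2
  y <- stats::rbinom(n, 1, plogis(eta))
  d <- tibble::tibble(x1 = x1, x2 = x2, y = y)
  fit <- fit_logistic(y ~ x1 + x2, d)
  expect_equal(unname(coef(fit)), c(-1, 0.8, 0.5), tolerance = 0.15 / 0.5)
  expect_true(all(abs(coef(fit) - c(-1, 0.8, 0.5)) < 0.15))

  ref <- stats::glm(y ~ x1 + x2, data = d, family = stats::binomial())
  expect_equal(unname(coef(fit)), unname(stats::coef(ref)), tolerance = 1e-6)
  expect_equal(unname(tidy(fit)$std.error),
               unname(summary(ref)$coefficients[, 2]), tolerance = 1e-4)
})

test_that("log-likelihood is non-decreasing across IRLS iterations", {
  set.seed(102)
  d <- tibble::tibble(
    x = stats::rnorm(60),
    y = stats::rbinom(60, 1, plogis(0.8 * stats::rnorm(60)))
  )
  fit <- fit_logistic(y ~ x, d)
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) >= -1e-10))
})

test_that("perfect separation raises the flag and the ridge fallback fits", {
  d <- tibble::tibble(x = c(-2, -1, -0.5, 0.5, 1, 2), y = c(0, 0, 0, 1, 1, 1))
  expect_warning(fit <- fit_logistic(y ~ x, d), NA)
  expect_true(fit$separation)
  expect_true(all(is.finite(coef(fit))))
})

test_that("single-class outcomes and constant columns are handled", {
  d <- tibble::tibble(x = stats::rnorm(10), z = 1, y = rep(1, 10))
  expect_error(fit_logistic(y ~ x, d), "single class")
  d$y <- rep(c(0, 1), 5)
  expect_warning(fit <- fit_logistic(y ~ x + z, d), "constant")
  expect_false("z" %in% names(coef(fit)))
})

test_that("AUC matches pair counting and its invariances", {
  expect_equal(evaluate_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 3 / 4)
  expect_equal(evaluate_auc(c(10, 9, 2, 1), c(1, 1, 0, 0)), 1)
  expect_equal(evaluate_auc(rep(0.5, 8), rep(c(0, 1), 4)), 0.5)
  expect_error(evaluate_auc(1:3, c(1, 1, 1)), "both classes")

  set.seed(103)
  s <- stats::rnorm(50)
  y <- stats::rbinom(50, 1, 0.4)
  a1 <- evaluate_auc(s, y)
  expect_equal(evaluate_auc(exp(s), y), a1)      # strictly increasing transform
  expect_equal(evaluate_auc(qnorm(plogis(s)), y), a1)
  skip_if_not_installed("pROC")
  expect_equal(
    a1,
    as.numeric(suppressMessages(pROC::auc(pROC::roc(y, s, quiet = TRUE)))),
    tolerance = 1e-12
  )
})

test_that("cross-cohort evaluation reports full and control models", {
  set.seed(104)
  sep <- tibble::tibble(
    log10_psa = c(stats::rnorm(10, 0, 0.3), stats::rnorm(10, 3, 0.3)),
    isup = c(sample(1:2, 10, replace = TRUE), sample(4:5, 10, replace = TRUE)),
    G1 = rep(c(0L, 1L), each = 10),
    metastasis = rep(c(0L, 1L), each = 10)
  )
  ev <- suppressWarnings(
    cross_cohort_evaluate(sep, sep, features = c("log10_psa", "isup", "G1"))
  )
  expect_equal(ev$full$auc_test, 1)
  expect_equal(ev$control$auc_test, 1)
  g <- glance(ev)
  expect_equal(g$model, c("full", "control"))

  expect_error(
    cross_cohort_evaluate(sep, sep[, -3], features = c("log10_psa", "isup", "G1")),
    "missing"
  )
})

test_that("the model frame encodes PSA, ISUP and gene indicators", {
  clin <- tibble::tibble(
    sample_id = c("p1", "p2"), age = c(60, 70), psa = c(9, 99),
    isup = c(2L, 5L), metastasis = c("M0", "M1"), crpc_within_1yr = NA
  )
  vs <- make_variant(gene = "TSC2", carriers = "p2")
  mf <- build_model_frame(clin, vs, c("TSC2", "ERBB2"))
  expect_equal(mf$log10_psa, log10(c(10, 100)))
  expect_equal(mf$TSC2, c(0L, 1L))
  expect_equal(mf$ERBB2, c(0L, 0L))
  expect_equal(mf$metastasis, c(0L, 1L))
})
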