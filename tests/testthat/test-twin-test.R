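# The two-level random-effects machinery: MAD filter, sufficient
# statistics, pair differences, DerSimonian-Laird pooling.

test_that("MAD filter keeps inliers and handles the degenerate zero-MAD case", {
  expect_equal(remove_outliers(c(1, 2, 3, 100)), c(1, 2, 3))
  expect_equal(remove_outliers(c(2, 2, 2, 2)), c(2, 2, 2, 2))
  x <- c(9.8, 10, 10.2, 10.1, 9.9)
  expect_equal(remove_outliers(x), x)
  expect_error(remove_outliers(numeric(0)),
               class = "twindff_error_structural")
})

test_that("subject summaries are the unbiased mean and variance of the mean", {
  s <- summarize_subject(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$var_of_mean, 1 / 3)
  expect_equal(s$n_cells, 3L)
  expect_equal(summarize_subject(c(5, 5, 5))$var_of_mean, 0)
  expect_error(summarize_subject(7),
               class = "twindff_error_insufficient_cells")
})

test_that("pair differences subtract means, sum variances, and flip under role swap", {
  summ <- tibble::tibble(pair_id = "p1", role = c("ST", "HT"),
                         mean = c(2, 1), var_of_mean = c(0.25, 0.25),
                         n_cells = c(10L, 12L))
  pd <- pair_differences(summ)
  expect_equal(pd$y, 1)
  expect_equal(pd$se, sqrt(0.5), tolerance = 1e-12)
  # identical summaries -> zero difference
  summ0 <- summ
  summ0$mean <- c(1.5, 1.5)
  expect_equal(pair_differences(summ0)$y, 0)
  # swapping roles flips the sign
  swapped <- summ
  swapped$role <- c("HT", "ST")
  expect_equal(pair_differences(swapped)$y, -pd$y)
  # incomplete pairs are dropped with a warning
  expect_warning(
    out <- pair_differences(tibble::tibble(
      pair_id = c("p1", "p1", "p2"), role = c("ST", "HT", "ST"),
      mean = c(2, 1, 5), var_of_mean = c(0.1, 0.1, 0.1))),
    "incomplete")
  expect_equal(out$pair_id, "p1")
})

test_that("DerSimonian-Laird pooling reproduces hand-computed examples", {
  # single pair: pooled is the difference itself
  d1 <- dersimonian_laird(0.4, 0.04)
  expect_equal(d1$pooled, 0.4)
  expect_equal(d1$tau2, 0)
  expect_equal(d1$se, 0.2)
  # homogeneous pair of studies
  d2 <- dersimonian_laird(c(1, 1), c(1, 1))
  expect_equal(d2$Q, 0)
  expect_equal(d2$tau2, 0)
  expect_equal(d2$pooled, 1)
  expect_equal(d2$se, sqrt(0.5), tolerance = 1e-12)
  # heterogeneous: Q = 2, tau2 = 1, z = 1
  d3 <- dersimonian_laird(c(0, 2), c(1, 1))
  expect_equal(d3$Q, 2)
  expect_equal(d3$tau2, 1)
  expect_equal(d3$pooled, 1)
  expect_equal(d3$se, 1)
  expect_equal(d3$z, 1)
  expect_equal(d3$p, 2 * pnorm(-1), tolerance = 1e-12)
  expect_error(dersimonian_laird(c(1, 2), c(1, 0)),
               class = "twindff_error_weighting")
})

test_that("tau2 truncates at zero and grows with heterogeneity", {
  # Q <= k - 1 -> tau2 = 0
  d <- dersimonian_laird(c(1, 1.01, 0.99), c(1, 1, 1))
  expect_equal(d$tau2, 0)
  # holding weights fixed, spreading y increases Q and tau2 monotonically
  v <- c(0.5, 1, 2)
  spreads <- seq(0.5, 4, by = 0.5)
  fits <- lapply(spreads, function(s) dersimonian_laird(c(-s, 0, s), v))
  qs <- vapply(fits, `[[`, numeric(1), "Q")
  taus <- vapply(fits, `[[`, numeric(1), "tau2")
  expect_true(all(diff(qs) > 0))
  expect_true(all(diff(taus) >= 0))
})

test_that("with equal variances and no heterogeneity the pool is the plain mean", {
  y <- c(0.1, 0.12, 0.11, 0.09)
  d <- dersimonian_laird(y, rep(0.04, 4))
  expect_equal(d$tau2, 0)
  expect_equal(d$pooled, mean(y), tolerance = 1e-12)
})

test_that("pooling matches metafor's DL estimator on random instances", {
  set.seed(31)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    y <- rnorm(k, 0, 1)
    v <- runif(k, 0.01, 2)
    mine <- dersimonian_laird(y, v)
    ref <- metafor::rma(yi = y, vi = v, method = "DL")
    expect_equal(mine$pooled, as.numeric(ref$b), tolerance = 1e-10)
    expect_equal(mine$se, ref$se, tolerance = 1e-10)
    expect_equal(mine$tau2, ref$tau2, tolerance = 1e-10)
    expect_equal(mine$p, ref$pval, tolerance = 1e-10)
  }
})

test_that("the twin contrast composes the two levels and honours equivariance", {
  design <- cohort_design(n_pairs = 4, cells_per_subject = 30,
                          true_pair_effect = 0.25)
  resp <- simulate_cohort_responses(design, seed = 51)
  fit <- twin_contrast_test(resp, "GABA", "pre")
  expect_s3_class(fit, "twin_contrast")
  expect_equal(fit$pooled$k, 4L)

  # composition: single pair equals DL on that one difference
  resp1 <- simulate_cohort_responses(
    cohort_design(n_pairs = 1, cells_per_subject = 20), seed = 52)
  f1 <- twin_contrast_test(resp1, "GABA", "pre")
  direct <- dersimonian_laird(f1$pairs$y, f1$pairs$v)
  expect_equal(f1$pooled$pooled, direct$pooled)
  expect_equal(f1$pooled$se, direct$se)

  # location equivariance: shifting every ST cell by c shifts the pool by c
  shifted <- resp
  st <- shifted$role == "ST"
  shifted$final[st] <- shifted$final[st] + 0.5
  fit2 <- twin_contrast_test(shifted, "GABA", "pre")
  expect_equal(fit2$pooled$pooled, fit$pooled$pooled + 0.5,
               tolerance = 1e-9)

  # tidy/glance expose both levels
  expect_equal(nrow(tidy(fit)), 4L)
  expect_named(glance(fit),
               c("agent", "treatment", "estimate", "std.error", "tau2",
                 "Q", "statistic", "p.value", "k", "n_outliers_removed"))
})

test_that("outlier cells are removed before summarisation and are audited", {
  design <- cohort_design(n_pairs = 3, cells_per_subject = 25,
                          true_pair_effect = 0, between_pair_sd = 0,
                          within_subject_cell_sd = 0.1)
  resp <- simulate_cohort_responses(design, seed = 61)
  # contaminate two ST cells grossly
  idx <- which(resp$role == "ST" & resp$treatment == "pre")[c(1, 30)]
  resp$final[idx] <- resp$final[idx] + 50
  fit <- twin_contrast_test(resp, "GABA", "pre")
  expect_gte(fit$n_outliers_removed, 2)
  expect_lt(abs(fit$pooled$pooled), 1)
})

test_that("null cohorts give approximately uniform p-values", {
  design <- cohort_design(n_pairs = 5, cells_per_subject = 30,
                          true_pair_effect = 0, between_pair_sd = 0,
                          treatment_labels = "pre")
  sims <- twin_power_sim(design, n_sim = 200, seed = 71)
  expect_gt(stats::ks.test(sims$p.value, "punif")$p.value, 0.01)
})

test_that("strata without data or pairs raise informative errors", {
  resp <- simulate_cohort_responses(cohort_design(n_pairs = 2), seed = 81)
  expect_error(twin_contrast_test(resp, "glycine", "pre"),
               class = "twindff_error_structural")
  only_st <- resp[resp$role == "ST", ]
  expect_error(suppressWarnings(twin_contrast_test(only_st, "GABA", "pre")),
               class = "twindff_error")
})
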