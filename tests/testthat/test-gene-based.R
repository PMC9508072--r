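test_that("probit transform matches the standard normal quantile", {
  expect_equal(probit_z(0.5), 0)
  expect_equal(probit_z(0.05), qnorm(0.95), tolerance = 1e-10)
  expect_equal(probit_z(0.05), 1.6449, tolerance = 1e-4)
  expect_equal(probit_z(2.7e-6), 4.547, tolerance = 1e-3)
  expect_error(probit_z(0), "strictly")
  expect_error(probit_z(1), "strictly")
  ## round trip far into the tail
  for (p in 10^-c(1, 10, 50, 150, 250)) {
    z <- probit_z(p)
    expect_equal(pnorm(z, lower.tail = FALSE), p, tolerance = 1e-12)
  }
  ## log-p pathway agrees and extends below double underflow
  expect_equal(probit_z(log(1e-10), log_p = TRUE), probit_z(1e-10))
  expect_gt(probit_z(-800, log_p = TRUE), 39)
})

test_that("gene test reduces to exact chi-square under independence", {
  ## single SNP passes through
  r <- gene_statistic_pvalue(0.05, matrix(1))
  expect_equal(r$p, 0.05, tolerance = 1e-12)

  ## k = 5, identity LD, all p = 0.5: T = 5 * qchisq(0.5, 1), exact chi2_5
  r5 <- gene_statistic_pvalue(rep(0.5, 5), diag(5))
  expect_equal(r5$stat, 5 * qchisq(0.5, 1), tolerance = 1e-12)
  expect_equal(r5$p, pchisq(r5$stat, 5, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r5$p, 0.810, tolerance = 1e-3)

  ## identity LD equals exact chi2_k tails for k up to 50, deep tails too
  set.seed(1)
  for (k in c(2, 10, 50)) {
    p <- runif(k)^4
    r <- gene_statistic_pvalue(p, diag(k))
    T <- sum(qchisq(p, 1, lower.tail = FALSE))
    expect_equal(r$p, pchisq(T, k, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("saddlepoint gene p tracks the Monte-Carlo oracle under LD", {
  set.seed(42)
  for (i in 1:5) {
    k <- sample(5:12, 1); rho <- runif(1, 0.3, 0.85)
    R <- ar1_mat(k, rho)
    p <- runif(k)
    r <- gene_statistic_pvalue(p, R)
    pm <- monte_carlo_gene_pvalue(r$stat, R, n_draws = 2e5, seed = i)
    expect_lt(abs(log10(r$p / pm)), 0.1)
  }
})

test_that("monte-carlo estimator is deterministic, never zero, calibrated", {
  R <- diag(5)
  expect_gt(monte_carlo_gene_pvalue(0, R, n_draws = 1e4, seed = 1), 0.999)
  p1 <- monte_carlo_gene_pvalue(12, R, n_draws = 1e4, seed = 7)
  p2 <- monte_carlo_gene_pvalue(12, R, n_draws = 1e4, seed = 7)
  expect_identical(p1, p2)
  ## identity R: matches chi2_5 tail within 3 binomial SE
  exact <- pchisq(12, 5, lower.tail = FALSE)
  se <- sqrt(exact * (1 - exact) / 1e4)
  expect_lt(abs(p1 - exact), 3 * se + 1e-4)
  expect_gt(monte_carlo_gene_pvalue(1e6, R, n_draws = 1e4, seed = 1), 0)
})

test_that("decreasing a SNP p-value never increases the gene p", {
  set.seed(3)
  R <- ar1_mat(8, 0.6)
  p <- runif(8, 0.05, 0.9)
  base <- gene_statistic_pvalue(p, R)$p
  for (j in 1:8) {
    p2 <- p; p2[j] <- p[j] / 4
    expect_lte(gene_statistic_pvalue(p2, R)$p, base)
  }
})

test_that("gene p-value methods reject invalid input", {
  expect_error(gene_statistic_pvalue(c(0.5, 1.2), diag(2)), "0, 1")
  R_bad <- matrix(c(1, 2, 2, 1), 2)  # indefinite
  expect_error(gene_statistic_pvalue(c(0.5, 0.5), R_bad),
               "positive semi-definite")
})

test_that("gene analysis excludes the MHC and reports the tested threshold", {
  ld <- build_ld_structure(n_blocks = 30, block_size = 10, rho = 0.4,
                           chrom = "6", spacing = 200000)
  truth <- sim_truth(h2_1 = 0, h2_2 = 0, rg = 0, n1 = 2e4, n2 = 2e4)
  sim <- simulate_pair(ld, truth, seed = 5)
  genes <- sim_gene_models(ld, 30)
  ann <- map_snps_to_genes(sim$ss1, genes)
  res <- run_gene_analysis(sim$ss1, ann, ld)
  mhc <- mhc_interval()
  in_mhc <- genes$start <= mhc$end & genes$end >= mhc$start
  expect_equal(attr(res, "n_mhc_excluded"), sum(in_mhc))
  expect_gt(sum(in_mhc), 0)  # the fixture genuinely straddles the MHC
  expect_false(any(res$gene_id %in% genes$gene_id[in_mhc]))
  expect_equal(attr(res, "bonferroni_threshold"), 0.05 / nrow(res))
  ## any-overlap rule: a gene overlapping only the MHC start is excluded
  g1 <- data.frame(gene_id = "edge", chrom = "6",
                   start = 28000000L, end = 28500000L)
  expect_true(g1$start <= mhc$end && g1$end >= mhc$start)

  ## probit z column is consistent with p
  expect_equal(res$z, qnorm(res$p, lower.tail = FALSE), tolerance = 1e-6)
})

test_that("null simulation gives calibrated gene p-values", {
  ld <- build_ld_structure(n_blocks = 100, block_size = 10, rho = 0.5)
  truth <- sim_truth(h2_1 = 0, h2_2 = 0, rg = 0, n1 = 5e4, n2 = 5e4)
  sim <- simulate_pair(ld, truth, seed = 11)
  genes <- sim_gene_models(ld, 250)
  ann <- map_snps_to_genes(sim$ss1, genes)
  res <- run_gene_analysis(sim$ss1, ann, ld, mhc = NULL)
  ## fraction below 0.05 within binomial 99% CI of 0.05
  frac <- mean(res$p < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(res))
  expect_lt(abs(frac - 0.05), 2.58 * se + 1e-9)
  ## and approximately uniform overall
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("the published gene count yields the published threshold", {
  expect_equal(signif(bonferroni_threshold(18297), 2), 2.7e-6)
})
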