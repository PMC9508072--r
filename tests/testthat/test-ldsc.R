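test_that("QC filter applies strict MAF, whitelist and MHC rules", {
  n <- 300
  ss <- data.frame(snp_id = sprintf("s%03d", 1:n),
                   chrom = rep("1", n), pos = 1:n * 1000,
                   a1 = "A", a2 = "G", z = 0, p = 1, n = 1e4,
                   maf = rep(0.3, n))
  class(ss) <- c("sumstats", "data.frame")
  ## identity when nothing filters
  out <- qc_filter(ss, min_snps = 100)
  expect_equal(nrow(out), n)

  ## maf = 0.05 exactly is removed (strict >)
  ss2 <- ss; ss2$maf[1] <- 0.05
  out2 <- qc_filter(ss2, min_snps = 100)
  expect_false("s001" %in% out2$snp_id)

  ## SNP inside the MHC is removed
  ss3 <- ss; ss3$chrom[2] <- "6"; ss3$pos[2] <- 30000000L
  out3 <- qc_filter(ss3, min_snps = 100)
  expect_false("s002" %in% out3$snp_id)

  ## whitelist restriction
  out4 <- qc_filter(ss, whitelist = ss$snp_id[1:250], min_snps = 100)
  expect_equal(nrow(out4), 250)

  expect_error(qc_filter(ss, whitelist = ss$snp_id[1:10]),
               "fewer than 200")
})

test_that("heritability regression recovers simulated h2 and intercept", {
  ld <- build_ld_structure(400, 25, rho = 0.5)
  lds <- compute_ld_scores(ld)

  ## null: h2 within 2 jackknife SE of 0, intercept near 1
  s0 <- simulate_pair(ld, sim_truth(h2_1 = 0, h2_2 = 0, rg = 0,
                                    n1 = 6e4, n2 = 6e4), seed = 31)
  ## a null estimate may dip below zero, which itself warns
  h0 <- suppressWarnings(estimate_h2(s0$ss1, lds, M = ld$M))
  expect_lt(abs(h0$h2), 2 * h0$se)
  expect_lt(abs(h0$intercept - 1), 3 * h0$intercept_se)

  ## h2 = 0.4 recovery across a few replicates
  truth <- sim_truth(h2_1 = 0.4, h2_2 = 0.4, rg = 0, n1 = 6e4, n2 = 6e4)
  ests <- sapply(1:8, function(s) {
    sim <- simulate_pair(ld, truth, seed = 100 + s)
    estimate_h2(sim$ss1, lds, M = ld$M)$h2
  })
  expect_lt(abs(mean(ests) - 0.4), 2 * sd(ests) / sqrt(length(ests)) + 0.02)

  ## degenerate input: all z = 0
  sz <- s0$ss1; sz$z <- 0
  expect_warning(h_dg <- estimate_h2(sz, lds, M = ld$M), "non-positive")
  expect_lte(h_dg$h2, 0)
  expect_lt(abs(h_dg$intercept), 1e-10)

  expect_error(estimate_h2(s0$ss1, lds, M = ld$M, n_blocks = 10),
               "at least 20")
})

test_that("genetic correlation: self-correlation, symmetry, recovery", {
  ld <- build_ld_structure(400, 25, rho = 0.5)
  lds <- compute_ld_scores(ld)
  truth <- sim_truth(h2_1 = 0.5, h2_2 = 0.5, rg = 0.3, n1 = 6e4, n2 = 6e4)
  sim <- simulate_pair(ld, truth, seed = 41)

  ## a trait with itself: rg = 1, cross-intercept ~ 1
  self <- estimate_rg(sim$ss1, sim$ss1, lds, M = ld$M)
  expect_equal(self$rg, 1, tolerance = 1e-6)
  expect_lt(abs(self$cross_intercept - 1), 3 * self$cross_intercept_se)

  ## symmetry in the trait order
  ab <- estimate_rg(sim$ss1, sim$ss2, lds, M = ld$M)
  ba <- estimate_rg(sim$ss2, sim$ss1, lds, M = ld$M)
  expect_equal(ab$rg, ba$rg, tolerance = 1e-10)

  ## point estimate is sane and the truth is well inside the interval
  expect_lt(abs(ab$rg - 0.3), 3 * ab$se)

  ## panel mismatch is an error, not a silent flip
  ss_sw <- sim$ss2; ss_sw$a1[5] <- "G"; ss_sw$a2[5] <- "A"
  expect_error(estimate_rg(sim$ss1, ss_sw, lds, M = ld$M),
               "allele orientation")
  ss_mm <- sim$ss2[c(2:1, 3:nrow(sim$ss2)), ]
  expect_error(estimate_rg(sim$ss1, ss_mm, lds, M = ld$M),
               "panels differ")
})

test_that("sample overlap moves the cross-intercept, not the covariance", {
  ld <- build_ld_structure(1500, 20, rho = 0.8)
  lds <- compute_ld_scores(ld)
  tr_ov <- sim_truth(h2_1 = 0.1, h2_2 = 0.1, rg = 0, n1 = 2e4, n2 = 2e4,
                     n_overlap = 1e4, pheno_corr = 0.4)
  tr_no <- sim_truth(h2_1 = 0.1, h2_2 = 0.1, rg = 0, n1 = 2e4, n2 = 2e4)
  ints_ov <- p_ov <- ints_no <- rhog <- numeric(3)
  for (s in 1:3) {
    e <- estimate_rg(simulate_pair(ld, tr_ov, seed = 200 + s)$ss1,
                     simulate_pair(ld, tr_ov, seed = 200 + s)$ss2,
                     lds, M = ld$M)
    e0 <- suppressWarnings(
      estimate_rg(simulate_pair(ld, tr_no, seed = 300 + s)$ss1,
                  simulate_pair(ld, tr_no, seed = 300 + s)$ss2,
                  lds, M = ld$M))
    ints_ov[s] <- e$cross_intercept; p_ov[s] <- e$cross_intercept_p
    ints_no[s] <- e0$cross_intercept; rhog[s] <- e$rho_g
  }
  rho_e <- 0.4 * 1e4 / 2e4
  expect_gt(mean(ints_ov), rho_e / 2)     # intercept absorbs the overlap
  expect_lt(median(p_ov), 0.01)           # and is markedly non-zero
  expect_lt(abs(mean(ints_no)), 0.1)      # none without overlap
  expect_lt(abs(mean(rhog)), 0.05)        # genetic covariance stays null
})

test_that("jackknife uncertainty shrinks with panel size", {
  ses <- sapply(c(2, 8), function(kblocks) {
    ld <- build_ld_structure(kblocks * 100, 20, rho = 0.5)
    lds <- compute_ld_scores(ld)
    sim <- simulate_pair(ld, sim_truth(h2_1 = 0.5, h2_2 = 0.5, rg = 0.3,
                                       n1 = 6e4, n2 = 6e4), seed = 77)
    estimate_rg(sim$ss1, sim$ss2, lds, M = ld$M, n_blocks = 50)$se
  })
  expect_lt(ses[2], ses[1])
})
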