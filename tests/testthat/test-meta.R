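test_that("stouffer combination follows the weighted-Z algebra", {
  ## equal studies: z_meta = sqrt(2) z0
  z0 <- 2.5
  r <- stouffer_combine(c(z0, z0), c(1e5, 1e5))
  expect_equal(r$z_meta, sqrt(2) * z0, tolerance = 1e-12)
  expect_equal(r$p_meta, pnorm(sqrt(2) * z0, lower.tail = FALSE))

  ## continuity: a vanishing-weight study leaves the other's z
  r2 <- stouffer_combine(c(3, -1), c(1e8, 1))
  expect_equal(r2$z_meta, 3, tolerance = 1e-3)

  expect_error(stouffer_combine(c(1, 2), c(10, 0)), "positive")

  ## extreme z stays finite in log space
  r3 <- stouffer_combine(c(40, 40), c(1e5, 1e5))
  expect_lt(r3$log_p, -1000)
})

test_that("published pairwise worked examples reproduce", {
  tab <- read.delim(system.file("extdata", "sz_sud_gene_examples.tsv",
                                package = "pairmeta"))
  for (i in seq_len(nrow(tab))) {
    z <- probit_z(c(tab$p_trait1[i], tab$p_trait2[i]))
    r <- stouffer_combine(z, c(tab$n1[i], tab$n2[i]))
    expect_lt(abs(r$p_meta / tab$p_meta_published[i] - 1), 0.05,
              label = tab$gene[i])
  }
})

test_that("cauchy combination: fixed points and small-tail accuracy", {
  expect_equal(cauchy_combine(c(0.5, 0.5), c(10, 10))$p_meta, 0.5)
  ## ACAT fixed point: equal weights, equal p
  for (p0 in c(0.01, 0.2, 0.9)) {
    expect_equal(cauchy_combine(c(p0, p0), c(5, 5))$p_meta, p0,
                 tolerance = 1e-10)
  }
  ## high-precision small-tail oracle: asymptotic expansion of the
  ## Cauchy upper tail, 0.5 - atan(T)/pi = 1/(pi T) - 1/(3 pi T^3) + ...
  p <- c(1e-20, 0.3)
  T <- 0.5 / (1e-20 * pi) + 0.5 * tan((0.5 - 0.3) * pi)
  oracle <- 1 / (pi * T) - 1 / (3 * pi * T^3)
  got <- cauchy_combine(p, c(7, 7))$p_meta
  expect_lt(abs(got / oracle - 1), 1e-6)
  expect_error(cauchy_combine(c(0, 0.5), c(1, 1)), "0, 1")
})

test_that("method concordance: Pearson r with Fisher-z interval", {
  p <- c(0.5, 0.01, 0.2, 1e-4, 0.8)
  r <- method_concordance(p, p)
  expect_equal(r$r, 1)
  expect_equal(r$ci_low, 1)

  ## Fisher-z oracle at r = 0.9744, n = 18297
  set.seed(1)
  n <- 18297
  fz <- atanh(0.9744); hw <- qnorm(0.975) / sqrt(n - 3)
  expect_equal(tanh(fz - hw), 0.9737, tolerance = 1e-4)
  expect_equal(tanh(fz + hw), 0.9751, tolerance = 1e-4)

  ## independent uniforms: r near 0
  pa <- runif(1000); pb <- runif(1000)
  rr <- method_concordance(pa, pb)
  expect_lt(abs(rr$r), 0.08)
  expect_error(method_concordance(rep(0.5, 5), runif(5)),
               "zero variance")
})

test_that("novel-signal filter equals the row-wise predicate", {
  mk_res <- function(id, p) {
    d <- data.frame(gene_id = id, p = p, log_p = log(p))
    class(d) <- c("gene_results", "data.frame"); d
  }
  ids <- c("BDNFlike", "weak2", "bonf1", "ok2")
  res1 <- mk_res(ids, c(4.22e-6, 1e-7, 1e-8, 3e-4))
  res2 <- mk_res(ids, c(1.08e-2, 0.2, 0.01, 0.003))
  meta <- meta_combine_genes(res1, res2, 130644, 28757)
  rep_ <- novel_signal_filter(res1, res2, meta, alpha_gene = 2.7e-6,
                              nominal = 0.05)
  ## BDNF-like row is retained
  expect_true(rep_$retained[rep_$gene_id == "BDNFlike"])
  ## p2 = 0.2 fails nominal regardless of meta p
  expect_false(rep_$retained[rep_$gene_id == "weak2"])
  ## Bonferroni-significant in trait 1 alone fails sub-threshold condition
  expect_false(rep_$retained[rep_$gene_id == "bonf1"])

  ## brute-force predicate on random fixtures
  set.seed(9)
  for (rep_i in 1:3) {
    n <- 50
    ids <- sprintf("g%02d", 1:n)
    p1 <- 10^runif(n, -8, 0); p2 <- 10^runif(n, -8, 0)
    r1 <- mk_res(ids, p1); r2 <- mk_res(ids, p2)
    m <- meta_combine_genes(r1, r2, 5e4, 5e4)
    rp <- novel_signal_filter(r1, r2, m, alpha_gene = 1e-4,
                              nominal = 0.05)
    want <- m$p_stouffer < 1e-4 & p1 < 0.05 & p2 < 0.05 &
      p1 >= 1e-4 & p2 >= 1e-4
    expect_equal(rp$retained, want)
  }

  ## missing gene in a trait is a consistency error
  meta_bad <- meta; meta_bad$gene_id[1] <- "ghost"
  expect_error(novel_signal_filter(res1, res2, meta_bad), "ghost")

  ## recurrence counting across pairs
  recur <- novel_signal_recurrence(list(rep_, rep_))
  expect_equal(recur$n_pairs[recur$gene_id == "BDNFlike"], 2L)
})

test_that("both meta methods are calibrated for independent traits", {
  d <- paired_null_gene_z(4000, rho_e = 0, seed = 21)
  zm <- (d$g1 + d$g2) / sqrt(2)
  p_st <- pnorm(zm, lower.tail = FALSE)
  p_ca <- vapply(seq_along(d$p1), function(i)
    cauchy_combine(c(d$p1[i], d$p2[i]), c(1, 1))$p_meta, 0)
  se <- 2.58 * sqrt(0.05 * 0.95 / 4000)
  expect_lt(abs(mean(p_st < 0.05) - 0.05), se)
  expect_lt(abs(mean(p_ca < 0.05) - 0.05), se)
})
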