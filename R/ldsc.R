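#' QC filter for LD score regression inputs
#'
#' Retains common SNPs (`maf > maf_min`, strict), restricted to a SNP
#' whitelist (HapMap3-style) when given, and outside the MHC region.
#' Filter counts are recorded in `attr(x, "qc_counts")`.
#'
#' @param ss A `sumstats` data frame with `maf` present.
#' @param whitelist Character vector of SNP ids to keep, or `NULL` for all.
#' @param maf_min Minor-allele-frequency cutoff (default 0.05, strict `>`).
#' @param mhc MHC interval to mask (see [mhc_interval()]), or `NULL`.
#' @param min_snps Minimum surviving SNPs (default 200) below which an
#'   error is raised.
#' @return Filtered `sumstats`.
#' @export
qc_filter <- function(ss, whitelist = NULL, maf_min = 0.05,
                      mhc = mhc_interval(), min_snps = 200) {
  if (all(is.na(ss$maf))) stop("qc_filter requires a maf column")
  keep_maf <- !is.na(ss$maf) & ss$maf > maf_min
  keep_wl <- if (is.null(whitelist)) rep(TRUE, nrow(ss)) else
    ss$snp_id %in% whitelist
  keep_mhc <- if (is.null(mhc)) rep(TRUE, nrow(ss)) else
    !(ss$chrom == mhc$chrom & ss$pos >= mhc$start & ss$pos <= mhc$end)
  keep <- keep_maf & keep_wl & keep_mhc
  out <- ss[keep, , drop = FALSE]
  if (nrow(out) < min_snps)
    stop("fewer than ", min_snps, " SNPs survive QC (", nrow(out), ")")
  rownames(out) <- NULL
  attr(out, "qc_counts") <- c(input = nrow(ss),
                              fail_maf = sum(!keep_maf),
                              fail_whitelist = sum(!keep_wl),
                              fail_mhc = sum(!keep_mhc),
                              retained = nrow(out))
  class(out) <- c("sumstats", "data.frame")
  out
}

## Align sumstats with an LD-score table by snp_id; errors on missing SNPs.
align_ldscores <- function(ss, ldscores) {
  hit <- match(ss$snp_id, ldscores$snp_id)
  if (anyNA(hit))
    stop("SNP missing from LD scores: ", ss$snp_id[which(is.na(hit))[1]])
  ldscores$ldscore[hit]
}

## Contiguous jackknife block ids for M SNPs.
jackknife_blocks <- function(M, n_blocks) {
  if (n_blocks < 20) stop("need at least 20 jackknife blocks")
  if (n_blocks > M) stop("more jackknife blocks than SNPs")
  ceiling(seq_len(M) / (M / n_blocks))
}

## Weighted regression y ~ l returning c(intercept, slope).
wls_fit <- function(y, l, w) {
  sw <- sum(w); mx <- sum(w * l) / sw; my <- sum(w * y) / sw
  sxx <- sum(w * (l - mx)^2)
  slope <- sum(w * (l - mx) * (y - my)) / sxx
  c(my - slope * mx, slope)
}

#' SNP heritability by LD score regression
#'
#' Weighted least squares of the per-SNP chi-square statistic on the LD
#' score: under the polygenic model `E[chi2_j] = 1 + N*h2*l_j/M`, so the
#' slope times `M/N` estimates the SNP heritability and the intercept
#' captures confounding. Heteroskedasticity weights `1/(1 + N*h2*l_j/M)^2`
#' are iterated (twice by default); uncertainty is by delete-one block
#' jackknife over contiguous SNP blocks.
#'
#' @param ss A `sumstats` data frame (needs `z` and `n`).
#' @param ldscores LD-score table (`snp_id`, `ldscore`), or a numeric
#'   vector aligned with `ss`.
#' @param M Number of SNPs the LD scores were computed over (defaults to
#'   `nrow(ss)`).
#' @param n_blocks Jackknife blocks (default 200; at least 20).
#' @param n_iter Weight iterations (default 2).
#' @return Object of class `h2_estimate`: list with `h2`, `se`,
#'   `intercept`, `intercept_se`, `z_h2`, `M`, `N`.
#' @export
estimate_h2 <- function(ss, ldscores, M = nrow(ss), n_blocks = 200,
                        n_iter = 2) {
  if (anyNA(ss$z)) stop("estimate_h2 requires z for every SNP")
  l <- if (is.numeric(ldscores)) ldscores else align_ldscores(ss, ldscores)
  N <- mean(ss$n)
  chi <- ss$z^2
  w <- 1 / pmax(l, 1)
  h2 <- 0
  for (i in seq_len(n_iter + 1)) {
    co <- wls_fit(chi, l, w)
    h2 <- co[2] * M / N
    w <- 1 / (pmax(l, 1) * (1 + N * max(h2, 0) * l / M)^2)
  }
  blk <- jackknife_blocks(length(chi), n_blocks)
  est_fun <- function(keep) {
    co <- wls_fit(chi[keep], l[keep], w[keep])
    c(co[2] * M / N, co[1])
  }
  jk <- jackknife_se(est_fun, blk)
  out <- list(h2 = jk$est[1], se = jk$se[1],
              intercept = jk$est[2], intercept_se = jk$se[2],
              z_h2 = jk$est[1] / jk$se[1], M = M, N = N,
              n_blocks = n_blocks)
  if (out$h2 <= 0)
    warning("non-positive heritability estimate (", signif(out$h2, 3), ")")
  class(out) <- "h2_estimate"
  out
}

## Delete-one-block jackknife: est_fun(keep) returns a vector statistic
## computed on the retained SNPs; returns full-sample estimate and
## jackknife SE per component.
jackknife_se <- function(est_fun, blk) {
  full <- est_fun(rep(TRUE, length(blk)))
  ids <- unique(blk)
  B <- length(ids)
  loo <- vapply(ids, function(b) est_fun(blk != b), full)
  loo <- matrix(loo, nrow = length(full))
  mean_loo <- rowMeans(loo)
  se <- sqrt((B - 1) / B * rowSums((loo - mean_loo)^2))
  list(est = full, se = se, loo = loo)
}

#' Cross-trait genetic correlation by LD score regression
#'
#' Regresses the product of the two traits' Z-scores on the LD score:
#' `E[z1_j*z2_j] = rho_e + sqrt(N1*N2)*rho_g*l_j/M`, so the slope estimates
#' the genetic covariance `rho_g` and the intercept the cross-trait
#' score-noise correlation induced by sample overlap. The genetic
#' correlation is `rg = rho_g / sqrt(h2_1*h2_2)` with per-trait
#' heritabilities estimated on the same panel. SE and a two-sided Wald p
#' for `rg`, plus the cross-intercept SE, come from a delete-one block
#' jackknife of the entire procedure (all three regressions).
#'
#' @param ss1,ss2 `sumstats` for the two traits, on the identical SNP
#'   panel post-QC (same snp_ids in the same order) with identical a1/a2
#'   orientation; a mismatch is an error, never a silent allele flip.
#' @param ldscores LD-score table or aligned numeric vector.
#' @param M SNPs behind the LD scores (default `nrow(ss1)`).
#' @param n_blocks Jackknife blocks (default 200).
#' @param intercept_alpha Threshold below which the cross-intercept's
#'   two-sided p flags "marked" sample overlap (default 0.01).
#' @return Object of class `rg_estimate`: list with `rg`, `se`, `p`,
#'   `rho_g`, `cross_intercept`, `cross_intercept_se`,
#'   `cross_intercept_p`, `overlap_flag`, and the two `h2_estimate`s.
#' @export
estimate_rg <- function(ss1, ss2, ldscores, M = nrow(ss1), n_blocks = 200,
                        intercept_alpha = 0.01) {
  if (nrow(ss1) != nrow(ss2) || any(ss1$snp_id != ss2$snp_id))
    stop("SNP panels differ: ",
         ss1$snp_id[which(ss1$snp_id != ss2$snp_id)[1]])
  mism <- which(ss1$a1 != ss2$a1 | ss1$a2 != ss2$a2)
  if (length(mism))
    stop("allele orientation mismatch at ", ss1$snp_id[mism[1]])
  l <- if (is.numeric(ldscores)) ldscores else align_ldscores(ss1, ldscores)
  N1 <- mean(ss1$n); N2 <- mean(ss2$n)
  h2_1 <- estimate_h2(ss1, l, M = M, n_blocks = n_blocks)
  h2_2 <- estimate_h2(ss2, l, M = M, n_blocks = n_blocks)
  y <- ss1$z * ss2$z
  w <- 1 / (pmax(l, 1) *
              (1 + N1 * max(h2_1$h2, 0) * l / M) *
              (1 + N2 * max(h2_2$h2, 0) * l / M))
  est_fun <- function(keep) {
    co1 <- wls_fit(ss1$z[keep]^2, l[keep], w[keep])
    co2 <- wls_fit(ss2$z[keep]^2, l[keep], w[keep])
    co <- wls_fit(y[keep], l[keep], w[keep])
    rho_g <- co[2] * M / sqrt(N1 * N2)
    h1 <- co1[2] * M / N1; h2 <- co2[2] * M / N2
    rg <- rho_g / sqrt(max(h1, 1e-12) * max(h2, 1e-12))
    c(rg = rg, rho_g = rho_g, cross_int = co[1])
  }
  blk <- jackknife_blocks(length(y), n_blocks)
  jk <- jackknife_se(est_fun, blk)
  jk$est <- unname(jk$est); jk$se <- unname(jk$se)
  rg <- jk$est[1]
  if (abs(rg) > 1.25)
    warning("rg estimate far outside [-1, 1]: ", signif(rg, 3))
  else if (abs(rg) > 1)
    warning("rg estimate slightly exceeds 1 in magnitude: ",
            signif(rg, 3))
  p <- 2 * stats::pnorm(abs(rg / jk$se[1]), lower.tail = FALSE)
  ci_p <- 2 * stats::pnorm(abs(jk$est[3] / jk$se[3]), lower.tail = FALSE)
  out <- list(rg = rg, se = jk$se[1], p = p,
              rho_g = jk$est[2],
              cross_intercept = jk$est[3],
              cross_intercept_se = jk$se[3],
              cross_intercept_p = ci_p,
              overlap_flag = ci_p < intercept_alpha,
              h2_1 = h2_1, h2_2 = h2_2,
              M = M, n_blocks = n_blocks)
  class(out) <- "rg_estimate"
  out
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("SNP heritability: h2 = %.4f (SE %.4f, Z = %.2f)\n",
              x$h2, x$se, x$z_h2))
  cat(sprintf("intercept: %.4f (SE %.4f); M = %d, N = %.0f\n",
              x$intercept, x$intercept_se, x$M, x$N))
  invisible(x)
}

#' @export
print.rg_estimate <- function(x, ...) {
  cat(sprintf("genetic correlation: rg = %.4f (SE %.4f, P = %.3g)\n",
              x$rg, x$se, x$p))
  cat(sprintf("cross-trait intercept: %.4f (SE %.4f, P = %.3g)%s\n",
              x$cross_intercept, x$cross_intercept_se,
              x$cross_intercept_p,
              if (x$overlap_flag) "  [markedly non-zero]" else ""))
  cat(sprintf("h2 trait 1: %.4f (Z = %.2f); h2 trait 2: %.4f (Z = %.2f)\n",
              x$h2_1$h2, x$h2_1$z_h2, x$h2_2$h2, x$h2_2$z_h2))
  invisible(x)
}
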