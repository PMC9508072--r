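#' Mixed moments (cokurtosis) of paired normalised effect sizes
#'
#' Converts the two traits' Z-scores to normalised per-SNP effects
#' `a = z/sqrt(N)`, rescales each trait so its LD-weighted second moment is
#' one, and estimates the cross-trait moments that drive the latent causal
#' variable model: the effect correlation `rho = E[a1*a2]` and the two
#' excess cokurtosis statistics `k1 = E[a1^3*a2] - 3*rho` and
#' `k2 = E[a1*a2^3] - 3*rho` (the `-3*rho` term removes the Gaussian part,
#' so both are zero for bivariate-normal effects). All moments are
#' LD-weighted by `1/l_j` and accompanied by a delete-one block-jackknife
#' covariance.
#'
#' Asymmetry between `k1` and `k2` is the causality signal: if trait 1's
#' genetic component is upstream of trait 2's, large trait-1 effects
#' project onto trait 2 but not conversely, so `k1 > k2`.
#'
#' @param ss1,ss2 `sumstats` on an identical SNP panel (post-QC).
#' @param ldscores LD-score table or aligned numeric vector.
#' @param n_blocks Jackknife blocks (default 100).
#' @param min_rho Minimum `|rho|` below which the model is uninformative
#'   and an error is raised (default 0.05).
#' @return Object of class `lcv_moments`: list with `rho`, `k1`, `k2`,
#'   `cov_k` (2x2 jackknife covariance of `(k1, k2)`), `se_rho`, `M`.
#' @export
compute_mixed_moments <- function(ss1, ss2, ldscores, n_blocks = 100,
                                  min_rho = 0.05) {
  if (nrow(ss1) != nrow(ss2) || any(ss1$snp_id != ss2$snp_id))
    stop("SNP panels differ between the two traits")
  l <- if (is.numeric(ldscores)) ldscores else align_ldscores(ss1, ldscores)
  a1 <- ss1$z / sqrt(ss1$n)
  a2 <- ss2$z / sqrt(ss2$n)
  w <- 1 / pmax(l, 1)
  stat <- function(keep) {
    ww <- w[keep]
    x1 <- a1[keep]; x2 <- a2[keep]
    x1 <- x1 / sqrt(stats::weighted.mean(x1^2, ww))
    x2 <- x2 / sqrt(stats::weighted.mean(x2^2, ww))
    rho <- stats::weighted.mean(x1 * x2, ww)
    c(rho,
      stats::weighted.mean(x1^3 * x2, ww) - 3 * rho,
      stats::weighted.mean(x1 * x2^3, ww) - 3 * rho)
  }
  blk <- jackknife_blocks(length(a1), n_blocks)
  full <- stat(rep(TRUE, length(blk)))
  ids <- unique(blk)
  B <- length(ids)
  loo <- vapply(ids, function(b) stat(blk != b), full)
  mean_loo <- rowMeans(loo)
  cov_all <- (B - 1) / B *
    tcrossprod(loo - mean_loo) # 3x3 jackknife covariance
  rho <- full[1]
  if (abs(rho) < min_rho)
    stop("effect correlation |rho| = ", signif(abs(rho), 3),
         " < ", min_rho, ": causality proportion is uninformative")
  out <- list(rho = rho, k1 = full[2], k2 = full[3],
              cov_k = cov_all[2:3, 2:3], se_rho = sqrt(cov_all[1, 1]),
              M = length(a1), n_blocks = n_blocks)
  class(out) <- "lcv_moments"
  out
}

#' Fit the latent causal variable model
#'
#' Grid posterior for the genetic causality proportion (GCP). Under the
#' latent model the two traits load on a shared kurtotic latent variable
#' with loadings `q1 = |rho|^{(1-gcp)/2}` and `q2 = |rho|^{(1+gcp)/2}`
#' (so `q1*q2 = |rho|` and `gcp = log(q2/q1)/log|rho|`), and the expected
#' excess cokurtosis statistics are proportional to `(q1^3*q2, q1*q2^3)`
#' with an unknown positive kurtosis scale that is profiled out by
#' generalised least squares. The likelihood is the bivariate normal
#' density of the observed `(k1, k2)` at their expectation under the
#' jackknife covariance; with a uniform prior on the grid the posterior
#' mean and SD give the GCP estimate and its SE.
#'
#' `gcp = 1` means trait 1's genetic component is fully causal for trait
#' 2; `gcp = -1` the reverse; 0 is symmetric pleiotropy. Negative `rho` is
#' handled by flipping trait 2's sign before fitting and restoring it in
#' the report. When either trait's heritability Z-score is below
#' `z_h2_caution` the result carries an "interpret cautiously" warning
#' flag.
#'
#' @param moments An `lcv_moments` object.
#' @param grid_step Grid resolution over [-1, 1] (default 0.01).
#' @param alpha Significance level for the partial-causality flag
#'   (default 0.05).
#' @param gcp_threshold |GCP| needed (with significance) to declare
#'   partial genetic causality (default 0.6).
#' @param z_h2 Optional numeric vector of the two traits' heritability
#'   Z-scores (for the low-precision warning).
#' @param z_h2_caution Caution threshold for those Z-scores (default 7).
#' @return Object of class `lcv_result`: list with `gcp`, `gcp_se`,
#'   `z_gcp`, `p`, `rho`, `partial_causality_flag`, `warnings`, and the
#'   posterior grid.
#' @export
fit_lcv <- function(moments, grid_step = 0.01, alpha = 0.05,
                    gcp_threshold = 0.6, z_h2 = NULL, z_h2_caution = 7) {
  stopifnot(inherits(moments, "lcv_moments"))
  rho <- moments$rho
  flip <- rho < 0
  rho_a <- abs(rho)
  k <- c(moments$k1, moments$k2)
  if (flip) k <- -k  # flipping trait 2's sign flips both cokurtoses
  S <- moments$cov_k
  ridged <- FALSE
  if (rcond(S) < 1e-12) {
    S <- S + diag(1e-3 * mean(diag(S)) + 1e-20, 2)
    ridged <- TRUE
    warning("jackknife covariance near-singular; ridge added")
  }
  Si <- solve(S)
  grid <- seq(-1, 1, by = grid_step)
  loglik <- vapply(grid, function(g) {
    q1 <- rho_a^((1 - g) / 2)
    q2 <- rho_a^((1 + g) / 2)
    v <- c(q1^3 * q2, q1 * q2^3)
    kap <- max(0, sum(v * (Si %*% k)) / sum(v * (Si %*% v)))
    r <- k - kap * v
    -0.5 * drop(t(r) %*% Si %*% r)
  }, 0)
  post <- exp(loglik - max(loglik))
  post <- post / sum(post)
  gcp <- sum(grid * post)
  gcp_se <- sqrt(sum((grid - gcp)^2 * post))
  z_gcp <- gcp / gcp_se
  p <- 2 * stats::pnorm(abs(z_gcp), lower.tail = FALSE)
  warnings <- character()
  if (!is.null(z_h2) && min(z_h2) < z_h2_caution)
    warnings <- c(warnings, sprintf(
      "min heritability Z = %.2f < %g: interpret causality cautiously",
      min(z_h2), z_h2_caution))
  if (ridged) warnings <- c(warnings, "ridged jackknife covariance")
  out <- list(gcp = gcp, gcp_se = gcp_se, z_gcp = z_gcp, p = p,
              rho = rho,
              z_h2_1 = if (is.null(z_h2)) NA_real_ else z_h2[1],
              z_h2_2 = if (is.null(z_h2)) NA_real_ else z_h2[2],
              partial_causality_flag = (p < alpha) &&
                (abs(gcp) > gcp_threshold),
              warnings = warnings,
              grid = grid, posterior = post)
  class(out) <- "lcv_result"
  out
}

#' Genetic causality proportion between two traits
#'
#' Convenience wrapper: mixed moments then the grid posterior fit.
#'
#' @inheritParams compute_mixed_moments
#' @inheritParams fit_lcv
#' @param ... Passed to [fit_lcv()].
#' @return An `lcv_result`.
#' @export
lcv_gcp <- function(ss1, ss2, ldscores, n_blocks = 100, ...) {
  mom <- compute_mixed_moments(ss1, ss2, ldscores, n_blocks = n_blocks)
  fit_lcv(mom, ...)
}

#' @export
print.lcv_result <- function(x, ...) {
  cat(sprintf("GCP = %.3f (SE %.3f, Z = %.2f, P = %.3g); rho = %.3f\n",
              x$gcp, x$gcp_se, x$z_gcp, x$p, x$rho))
  cat("partial genetic causality:",
      if (x$partial_causality_flag) "YES" else "no", "\n")
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}
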