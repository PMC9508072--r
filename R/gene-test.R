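#' Probit transform of a one-sided p-value
#'
#' `z = qnorm(1 - p)`, strictly decreasing in p. For extreme p the quantile
#' is computed from log(p), so p-values down to the smallest representable
#' double (and beyond, via `log_p = TRUE`) keep full accuracy.
#'
#' @param p P-value(s) strictly in (0, 1); when `log_p = TRUE`, natural-log
#'   p-values (strictly negative).
#' @param log_p Interpret `p` as log(p)?
#' @return Probit Z-score(s).
#' @export
probit_z <- function(p, log_p = FALSE) {
  if (log_p) {
    if (any(p >= 0)) stop("log p-values must be < 0")
    return(stats::qnorm(p, lower.tail = FALSE, log.p = TRUE))
  }
  if (any(p <= 0 | p >= 1)) stop("p-values must lie strictly in (0, 1)")
  stats::qnorm(log(p), lower.tail = FALSE, log.p = TRUE)
}

## Upper-tail probability of a positively weighted sum of independent 1-df
## chi-squares, Q = sum(lam_i * chi2_1).
##
## method "saddlepoint": Lugannani-Rice / Kuonen formula on the cumulant
##   generating function; accurate to a few percent relative error over the
##   whole range, including very small tails (computed in log space). When
##   all weights are equal the distribution is exactly a scaled chi-square
##   and the exact tail is returned.
## method "gamma": classical Brown two-moment gamma (matches mean and
##   variance); fast but underestimates small tails.
qform_tail_p <- function(q, lam, method = c("saddlepoint", "gamma"),
                         log_p = FALSE) {
  method <- match.arg(method)
  stopifnot(all(lam >= 0), any(lam > 0))
  lam <- lam[lam > 0]
  k <- length(lam)
  wrap <- function(lp) if (log_p) lp else exp(lp)

  if (max(lam) - min(lam) <= 1e-12 * max(lam))  # exact scaled chi-square
    return(wrap(stats::pchisq(q / lam[1], df = k, lower.tail = FALSE,
                              log.p = TRUE)))
  mu <- sum(lam); v <- 2 * sum(lam^2)
  gamma_lp <- stats::pgamma(q, shape = mu^2 / v, scale = v / mu,
                            lower.tail = FALSE, log.p = TRUE)
  if (method == "gamma") return(wrap(gamma_lp))

  ## saddlepoint: solve K'(z) = q on (-Inf, 1/(2*max(lam)))
  K <- function(z) -0.5 * sum(log1p(-2 * z * lam))
  K1 <- function(z) sum(lam / (1 - 2 * z * lam))
  K2 <- function(z) 2 * sum(lam^2 / (1 - 2 * z * lam)^2)
  up <- 1 / (2 * max(lam))
  f <- function(z) K1(z) - q
  lo <- -1
  while (f(lo) > 0) lo <- lo * 2
  zh <- stats::uniroot(f, c(lo, up - 1e-10 * up), tol = 1e-14)$root
  w <- sign(zh) * sqrt(max(0, 2 * (zh * q - K(zh))))
  u <- zh * sqrt(K2(zh))
  if (abs(zh) < 1e-4 || abs(w) < 1e-4)  # saddlepoint singular near the mean
    return(wrap(gamma_lp))
  wrap(stats::pnorm(w + log(u / w) / w, lower.tail = FALSE, log.p = TRUE))
}

#' LD-aware gene test statistic and p-value
#'
#' Combines SNP-wise p-values within one gene into a single gene-level
#' test, accounting for LD between the SNPs. Each p-value is converted to a
#' 1-df chi-square quantile (two-sided convention,
#' `q_i = qnorm(1 - p_i/2)^2`) and the statistic is their sum,
#' `T = sum(q_i)`. Under the null, T is distributed as
#' `sum(lambda_k * chi2_1)` where `lambda_k` are the eigenvalues of the SNP
#' correlation matrix; the tail probability of that weighted sum is the
#' gene p-value (Brown's method with a moment-matched null, here evaluated
#' by a saddlepoint approximation by default).
#'
#' @param snp_p SNP p-values, strictly in (0, 1).
#' @param R SNP correlation matrix (unit diagonal, PSD up to a clipping
#'   tolerance of 1e-8).
#' @param method `"saddlepoint"` (default), `"gamma"` (two-moment Brown),
#'   or `"montecarlo"`.
#' @param n_draws,seed Monte-Carlo settings (used when
#'   `method = "montecarlo"`).
#' @return List with `stat` (T), `p`, and `log_p` (natural log of p).
#' @export
gene_statistic_pvalue <- function(snp_p, R,
                                  method = c("saddlepoint", "gamma",
                                             "montecarlo"),
                                  n_draws = 1e6, seed = 1) {
  method <- match.arg(method)
  if (any(snp_p <= 0 | snp_p >= 1)) stop("SNP p-values must lie in (0, 1)")
  R <- as.matrix(R)
  k <- length(snp_p)
  stopifnot(nrow(R) == k, ncol(R) == k)
  qv <- stats::qchisq(snp_p, df = 1, lower.tail = FALSE)
  stat <- sum(qv)
  lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(lam) < -1e-8)
    stop("SNP correlation matrix is not positive semi-definite")
  lam <- pmax(lam, 0)
  if (method == "montecarlo") {
    p <- monte_carlo_gene_pvalue(stat, R, n_draws = n_draws, seed = seed)
    return(list(stat = stat, p = p, log_p = log(p)))
  }
  lp <- qform_tail_p(stat, lam, method = method, log_p = TRUE)
  list(stat = stat, p = exp(lp), log_p = lp)
}

#' Monte-Carlo gene p-value
#'
#' Empirical tail probability of the gene statistic under `Z ~ N(0, R)`,
#' using the eigen-decomposition to draw the weighted chi-square sum
#' directly. The add-one estimator `(1 + #{T_sim >= stat}) / (n_draws + 1)`
#' never returns exactly zero.
#'
#' @param stat Observed gene statistic (sum of 1-df chi-squares).
#' @param R SNP correlation matrix.
#' @param n_draws Number of null draws (>= 1e4).
#' @param seed RNG seed.
#' @return Empirical p-value.
#' @export
monte_carlo_gene_pvalue <- function(stat, R, n_draws = 1e6, seed = 1) {
  stopifnot(n_draws >= 1e4)
  lam <- eigen(as.matrix(R), symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  k <- length(lam)
  set.seed(seed)
  ## chunked so that k x n_draws never exceeds ~8e7 doubles
  chunk <- max(1e4, floor(8e7 / k))
  exceed <- 0
  done <- 0
  while (done < n_draws) {
    m <- min(chunk, n_draws - done)
    Ts <- colSums(lam * matrix(stats::rnorm(k * m)^2, k))
    exceed <- exceed + sum(Ts >= stat)
    done <- done + m
  }
  (1 + exceed) / (n_draws + 1)
}

## Correlation matrix for an arbitrary subset of SNPs of an ld_structure:
## block-diagonal pieces, zero across blocks. `which_block`/`offset` are
## positions of the subset within the structure.
ld_submatrix <- function(ld, block, offset) {
  k <- length(block)
  R <- diag(k)
  for (b in unique(block)) {
    sel <- which(block == b)
    R[sel, sel] <- ld$blocks[[b]]$R[offset[sel], offset[sel]]
  }
  R
}

## Locate sumstats rows inside an ld_structure by (chrom, pos).
## Returns data.frame(block, offset) aligned with rows of ss; errors if a
## SNP is absent from the LD structure.
ld_locate <- function(ld, ss) {
  key <- unlist(lapply(seq_along(ld$blocks), function(b)
    paste(ld$blocks[[b]]$chrom, as.integer(ld$blocks[[b]]$pos))))
  block <- rep(seq_along(ld$blocks),
               vapply(ld$blocks, function(b) length(b$pos), 0L))
  offset <- unlist(lapply(ld$blocks, function(b) seq_along(b$pos)))
  hit <- match(paste(ss$chrom, as.integer(ss$pos)), key)
  if (anyNA(hit))
    stop("SNP not present in LD structure: ",
         ss$snp_id[which(is.na(hit))[1]])
  data.frame(block = block[hit], offset = offset[hit])
}

#' MHC interval (hg19)
#'
#' The extended major histocompatibility complex on chromosome 6,
#' chr6:28,477,797-33,448,354 (1-based, closed), conventionally excluded
#' from gene-based analyses because of its extreme LD.
#' @return List with `chrom`, `start`, `end`.
#' @export
mhc_interval <- function() list(chrom = "6", start = 28477797L,
                                end = 33448354L)

#' Run gene-based association for one trait
#'
#' Applies the LD-aware gene test to every annotated gene. Genes
#' overlapping the MHC (any-overlap rule on the closed interval) are
#' excluded before testing; the Bonferroni threshold is `alpha` divided by
#' the number of genes actually tested.
#'
#' @param ss A `sumstats` data frame.
#' @param annot A `gene_annotation` from [map_snps_to_genes()].
#' @param ld The `ld_structure` providing SNP correlations.
#' @param alpha Family-wise error target for the Bonferroni flag
#'   (default 0.05).
#' @param method Gene p-value method, see [gene_statistic_pvalue()].
#' @param mhc MHC interval to mask, or `NULL` to skip masking.
#' @return Object of class `gene_results`: data frame with `gene_id`,
#'   `chrom`, `start`, `end`, `n_snps`, `mac`, `stat`, `p`, `log_p`, `z`
#'   (probit of the one-sided p), `bonferroni_sig`. Metadata in attributes:
#'   `n_tested`, `n_mhc_excluded`, `bonferroni_threshold`, `method`.
#' @export
run_gene_analysis <- function(ss, annot, ld, alpha = 0.05,
                              method = "saddlepoint",
                              mhc = mhc_interval()) {
  stopifnot(inherits(annot, "gene_annotation"))
  genes <- annot$genes
  keep <- rep(TRUE, nrow(genes))
  if (!is.null(mhc)) {
    keep <- !(genes$chrom == mhc$chrom &
                genes$start <= mhc$end & genes$end >= mhc$start)
  }
  n_mhc <- sum(!keep)
  genes <- genes[keep, , drop = FALSE]
  loc <- ld_locate(ld, ss)
  n <- nrow(genes)
  if (n == 0L) stop("no genes left to test after MHC exclusion")
  stat <- p <- lp <- mac <- numeric(n)
  for (i in seq_len(n)) {
    ridx <- annot$idx[[genes$gene_id[i]]]
    R <- ld_submatrix(ld, loc$block[ridx], loc$offset[ridx])
    pv <- pmin(pmax(ss$p[ridx], 1e-300), 1 - 1e-16)
    res <- gene_statistic_pvalue(pv, R, method = method)
    stat[i] <- res$stat; p[i] <- res$p; lp[i] <- res$log_p
    mac[i] <- sum(2 * ss$n[ridx] * ss$maf[ridx])
  }
  thr <- alpha / n
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = genes$start, end = genes$end,
                    n_snps = genes$n_snps, mac = mac,
                    stat = stat, p = p, log_p = lp,
                    z = probit_z(lp, log_p = TRUE),
                    bonferroni_sig = p < thr,
                    stringsAsFactors = FALSE)
  attr(out, "n_tested") <- n
  attr(out, "n_mhc_excluded") <- n_mhc
  attr(out, "bonferroni_threshold") <- thr
  attr(out, "alpha") <- alpha
  attr(out, "method") <- method
  class(out) <- c("gene_results", "data.frame")
  out
}

#' Bonferroni threshold for a gene-based analysis
#'
#' @param n_genes Number of genes tested.
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / n_genes`.
#' @export
bonferroni_threshold <- function(n_genes, alpha = 0.05) {
  stopifnot(n_genes >= 1)
  alpha / n_genes
}
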