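#' Sample-size weighted Stouffer combination
#'
#' Inverse-normal meta-analysis of gene-level Z-scores with weights
#' proportional to the square root of each study's sample size:
#' `z_meta = sum(sqrt(n_i) * z_i) / sqrt(sum(n_i))`. This is the weighted-Z
#' convention under which the combined statistic has unit variance when the
#' inputs are independent standard normals. The meta p-value is the
#' one-sided upper tail, computed in log space so extreme Z-scores do not
#' underflow.
#'
#' @param z Gene Z-scores (probit of one-sided p-values), length >= 2.
#' @param n Study sample sizes, same length, all > 0.
#' @return List with `z_meta`, `p_meta`, `log_p` (natural log).
#' @export
stouffer_combine <- function(z, n) {
  stopifnot(length(z) == length(n), length(z) >= 2)
  if (any(n <= 0)) stop("sample sizes must be positive")
  z_meta <- sum(sqrt(n) * z) / sqrt(sum(n))
  lp <- stats::pnorm(z_meta, lower.tail = FALSE, log.p = TRUE)
  list(z_meta = z_meta, p_meta = exp(lp), log_p = lp)
}

#' Sample-size weighted Cauchy (ACAT) combination
#'
#' Each p-value is mapped to a Cauchy variate `tan((0.5 - p) * pi)` (with
#' the numerically stable substitution `1/(p*pi)` for p < 1e-15) and the
#' weighted sum `T = sum(w_i * tan((0.5 - p_i) * pi))`, with
#' `w_i = n_i / sum(n)`, is referred to the standard Cauchy distribution.
#' Because of the Cauchy's heavy tail the test is insensitive to
#' correlation between the component p-values (e.g. from overlapping GWAS
#' samples).
#'
#' @param p P-values strictly in (0, 1), length >= 2.
#' @param n Sample-size weights, same length, all > 0.
#' @return List with `stat` (T) and `p_meta`.
#' @export
cauchy_combine <- function(p, n) {
  stopifnot(length(p) == length(n), length(p) >= 2)
  if (any(p <= 0 | p >= 1)) stop("p-values must lie strictly in (0, 1)")
  if (any(n <= 0)) stop("sample sizes must be positive")
  w <- n / sum(n)
  t_i <- ifelse(p < 1e-15, 1 / (p * pi), tan((0.5 - p) * pi))
  T <- sum(w * t_i)
  p_meta <- if (T > 1e15) 1 / (T * pi) else
    stats::pcauchy(T, lower.tail = FALSE)
  list(stat = T, p_meta = p_meta)
}

#' Meta-analyse two gene-result tables
#'
#' Aligns two `gene_results` tables on their shared gene universe and
#' combines them per gene by the requested method(s).
#'
#' @param res1,res2 `gene_results` tables for the two traits.
#' @param n1,n2 GWAS sample sizes used as weights.
#' @param method `"stouffer"`, `"cauchy"`, or `"both"`.
#' @return Data frame of class `meta_results` with `gene_id`, `p_trait1`,
#'   `p_trait2`, and per method `z_meta`/`p_meta` columns (`z_meta` is `NA`
#'   for the Cauchy method). Attribute `n_genes` records the intersected
#'   universe size.
#' @export
meta_combine_genes <- function(res1, res2, n1, n2,
                               method = c("stouffer", "cauchy", "both")) {
  method <- match.arg(method)
  common <- intersect(res1$gene_id, res2$gene_id)
  if (!length(common)) stop("no shared genes between the two result sets")
  i1 <- match(common, res1$gene_id); i2 <- match(common, res2$gene_id)
  out <- data.frame(gene_id = common,
                    p_trait1 = res1$p[i1], p_trait2 = res2$p[i2],
                    stringsAsFactors = FALSE)
  z1 <- probit_z(res1$log_p[i1], log_p = TRUE)
  z2 <- probit_z(res2$log_p[i2], log_p = TRUE)
  if (method %in% c("stouffer", "both")) {
    zm <- (sqrt(n1) * z1 + sqrt(n2) * z2) / sqrt(n1 + n2)
    out$z_meta <- zm
    out$log_p_stouffer <- stats::pnorm(zm, lower.tail = FALSE, log.p = TRUE)
    out$p_stouffer <- exp(out$log_p_stouffer)
  }
  if (method %in% c("cauchy", "both")) {
    out$p_cauchy <- vapply(seq_along(common), function(i)
      cauchy_combine(c(out$p_trait1[i], out$p_trait2[i]),
                     c(n1, n2))$p_meta, 0)
  }
  attr(out, "n_genes") <- length(common)
  attr(out, "n1") <- n1
  attr(out, "n2") <- n2
  attr(out, "method") <- method
  class(out) <- c("meta_results", "data.frame")
  out
}

#' Concordance of two p-value vectors on the -log10 scale
#'
#' Pearson correlation of `-log10(p_a)` and `-log10(p_b)` with a 95%
#' confidence interval from the Fisher z-transform
#' (`SE = 1/sqrt(n - 3)`).
#'
#' @param p_a,p_b Equal-length p-value vectors for the same genes in the
#'   same order, length >= 4.
#' @return List with `r`, `ci_low`, `ci_high`, `n`.
#' @export
method_concordance <- function(p_a, p_b) {
  stopifnot(length(p_a) == length(p_b), length(p_a) >= 4)
  x <- -log10(p_a); y <- -log10(p_b)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  r <- stats::cor(x, y)
  n <- length(x)
  if (abs(r) >= 1) return(list(r = r, ci_low = r, ci_high = r, n = n))
  fz <- atanh(r)
  hw <- stats::qnorm(0.975) / sqrt(n - 3)
  list(r = r, ci_low = tanh(fz - hw), ci_high = tanh(fz + hw), n = n)
}

#' Filter for novel pleiotropic gene signals
#'
#' A gene is retained iff it is Bonferroni-significant in the meta-analysis
#' (`p_meta < alpha_gene`), at least nominally significant in both
#' single-trait analyses (`p < nominal`), and Bonferroni-significant in
#' neither (`p >= alpha_gene` in both). Such genes are candidate shared
#' signals that neither GWAS could establish on its own.
#'
#' @param res1,res2 `gene_results` tables for the two traits.
#' @param meta `meta_results` table (or any data frame with `gene_id` and
#'   a meta p-value column named by `p_col`).
#' @param alpha_gene Bonferroni threshold for both the meta and the
#'   "sub-threshold in each single trait" conditions (default 2.7e-6).
#' @param nominal Nominal significance level (default 0.05).
#' @param p_col Meta p-value column to use (default `"p_stouffer"`).
#' @return Data frame of class `novel_signal_report` with per-gene
#'   p-values, the three component flags (`meta_bonf`, `nominal_both`,
#'   `sub_bonf_both`) and `retained`.
#' @export
novel_signal_filter <- function(res1, res2, meta, alpha_gene = 2.7e-6,
                                nominal = 0.05, p_col = "p_stouffer") {
  stopifnot(p_col %in% names(meta))
  i1 <- match(meta$gene_id, res1$gene_id)
  i2 <- match(meta$gene_id, res2$gene_id)
  if (anyNA(i1) || anyNA(i2))
    stop("gene present in meta but missing from a trait: ",
         meta$gene_id[which(is.na(i1) | is.na(i2))[1]])
  p1 <- res1$p[i1]; p2 <- res2$p[i2]; pm <- meta[[p_col]]
  out <- data.frame(gene_id = meta$gene_id,
                    p_trait1 = p1, p_trait2 = p2, p_meta = pm,
                    meta_bonf = pm < alpha_gene,
                    nominal_both = p1 < nominal & p2 < nominal,
                    sub_bonf_both = p1 >= alpha_gene & p2 >= alpha_gene,
                    stringsAsFactors = FALSE)
  out$retained <- out$meta_bonf & out$nominal_both & out$sub_bonf_both
  attr(out, "alpha_gene") <- alpha_gene
  attr(out, "nominal") <- nominal
  class(out) <- c("novel_signal_report", "data.frame")
  out
}

#' Count gene recurrence across several novel-signal reports
#'
#' @param reports List of `novel_signal_report` objects (one per trait
#'   pair).
#' @return Data frame `gene_id`, `n_pairs` for genes retained in at least
#'   one report, sorted by decreasing recurrence.
#' @export
novel_signal_recurrence <- function(reports) {
  kept <- unlist(lapply(reports, function(r) r$gene_id[r$retained]))
  if (!length(kept))
    return(data.frame(gene_id = character(), n_pairs = integer()))
  tab <- sort(table(kept), decreasing = TRUE)
  data.frame(gene_id = names(tab), n_pairs = as.integer(tab),
             stringsAsFactors = FALSE)
}
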