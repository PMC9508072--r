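#' Competitive gene-set association test
#'
#' Ordinary least squares of the gene Z-scores on set membership plus
#' confounder covariates and an intercept. The one-sided p-value for a
#' positive membership coefficient asks whether member genes carry more
#' association signal than the remaining genes, after adjusting for gene
#' size and aggregate minor allele count.
#'
#' @param gene_z Gene Z-scores (probit of the one-sided gene p-values).
#' @param membership 0/1 (or logical) membership indicator, not constant.
#' @param covariates Optional numeric matrix of confounders (columns are
#'   covariates); collinear columns are dropped with a warning.
#' @return List with `beta`, `se`, `p` (one-sided, beta > 0), `df`.
#' @export
competitive_geneset_test <- function(gene_z, membership,
                                     covariates = NULL) {
  membership <- as.numeric(membership)
  stopifnot(length(gene_z) == length(membership))
  if (length(unique(membership)) < 2)
    stop("membership is constant: no complement genes to compare against")
  X <- cbind(intercept = 1, membership = membership)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == length(gene_z))
    ## centre and scale for conditioning; the membership coefficient is
    ## invariant to affine transforms of the other columns
    sds <- apply(covariates, 2, stats::sd)
    covariates <- sweep(covariates, 2, colMeans(covariates))
    covariates <- sweep(covariates, 2, ifelse(sds > 0, sds, 1), "/")
    X <- cbind(X, covariates)
  }
  qrX <- qr(X, tol = 1e-9)
  if (qrX$rank < ncol(X)) {
    drop_cols <- qrX$pivot[-seq_len(qrX$rank)]
    if (2 %in% drop_cols)
      stop("membership column is collinear with the covariates")
    warning("dropping collinear covariate column(s): ",
            paste(colnames(X)[drop_cols], collapse = ", "))
    X <- X[, -drop_cols, drop = FALSE]
    qrX <- qr(X, tol = 1e-9)
  }
  fit <- stats::lm.fit(X, gene_z)
  df <- length(gene_z) - ncol(X)
  if (df < 1) stop("not enough genes for the design")
  sigma2 <- sum(fit$residuals^2) / df
  ## (X'X)^-1 via the QR factor, undoing column pivoting
  XtXi_piv <- chol2inv(qr.R(qrX))
  piv <- qrX$pivot
  XtXi <- matrix(0, ncol(X), ncol(X))
  XtXi[piv, piv] <- XtXi_piv
  beta <- unname(fit$coefficients["membership"])
  se <- sqrt(sigma2 * XtXi[2, 2])
  tval <- beta / se
  list(beta = beta, se = se,
       p = stats::pt(tval, df = df, lower.tail = FALSE), df = df)
}

## Default confounder matrix from a gene_results table: gene size (SNP
## count), log size, genic minor allele count, log thereof.
geneset_covariates <- function(gene_results) {
  cov <- cbind(n_snps = gene_results$n_snps,
               log_n_snps = log(gene_results$n_snps))
  if (!all(is.na(gene_results$mac)) && all(gene_results$mac > 0,
                                           na.rm = TRUE)) {
    mac <- ifelse(is.na(gene_results$mac), 1, gene_results$mac)
    cov <- cbind(cov, mac = mac, log_mac = log(mac))
  }
  ## constant columns carry no adjustment information
  cov[, apply(cov, 2, stats::sd) > 0, drop = FALSE]
}

#' Run a gene-set collection against gene results
#'
#' Intersects every set with the analysed gene universe, skips sets below
#' `min_set_size`, runs the competitive test per set, and applies
#' Benjamini-Hochberg FDR within the collection. When a comparison run is
#' supplied (e.g. the anchor trait alone versus a meta-analysed run), sets
#' significant here but not there are flagged `novel_vs_single_trait`.
#'
#' @param gene_results A `gene_results` (or `meta_results`-derived) table;
#'   needs `gene_id`, `z`, `n_snps`, and optionally `mac`.
#' @param collection A `geneset_collection`.
#' @param min_set_size Minimum intersected size (default 3).
#' @param fdr_alpha FDR significance level (default 0.05).
#' @param compare_run Optional `geneset_results` from a single-trait run,
#'   for novelty flags.
#' @return Object of class `geneset_results`: data frame with `set_id`,
#'   `n_genes`, `beta`, `se`, `p`, `q`, `significant`, and
#'   `novel_vs_single_trait` when `compare_run` is given. Skipped sets are
#'   listed in `attr(x, "skipped_sets")`.
#' @export
run_geneset_collection <- function(gene_results, collection,
                                   min_set_size = 3, fdr_alpha = 0.05,
                                   compare_run = NULL) {
  stopifnot(inherits(collection, "geneset_collection"))
  universe <- gene_results$gene_id
  memb_list <- lapply(collection$sets, function(g) universe %in% g)
  sizes <- vapply(memb_list, sum, 0L)
  ok <- sizes >= min_set_size & sizes < length(universe)
  skipped <- names(collection$sets)[!ok]
  if (!any(ok)) stop("no gene set passes the size filter")
  cov <- geneset_covariates(gene_results)
  rows <- lapply(which(ok), function(i) {
    r <- competitive_geneset_test(gene_results$z, memb_list[[i]], cov)
    data.frame(set_id = names(collection$sets)[i], n_genes = sizes[i],
               beta = r$beta, se = r$se, p = r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr_alpha
  if (!is.null(compare_run)) {
    sig_before <- compare_run$set_id[compare_run$significant]
    out$novel_vs_single_trait <- out$significant &
      !(out$set_id %in% sig_before)
  }
  attr(out, "skipped_sets") <- skipped
  attr(out, "collection_name") <- collection$collection_name
  attr(out, "fdr_alpha") <- fdr_alpha
  attr(out, "min_set_size") <- min_set_size
  class(out) <- c("geneset_results", "data.frame")
  out
}
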