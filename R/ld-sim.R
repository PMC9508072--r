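#' Build a block-diagonal AR(1) LD structure
#'
#' The genome is modelled as disjoint LD blocks; within a block the SNP
#' correlation is AR(1), `r[j,k] = rho^|j-k|`, which is positive definite
#' for `0 <= rho < 1`. Blocks are laid out on chromosome `chrom` at `spacing`
#' bp intervals so positional operations (gene mapping, MHC masking) work
#' on simulated data.
#'
#' @param n_blocks Number of LD blocks.
#' @param block_size SNPs per block.
#' @param rho AR(1) parameter, in [0, 1).
#' @param chrom Chromosome label(s); recycled across blocks.
#' @param spacing Base pairs between adjacent SNPs (default 1000).
#' @return Object of class `ld_structure`: list with `blocks` (each with
#'   `chrom`, `pos`, correlation matrix `R` and its symmetric square root),
#'   `M` (total SNPs) and `snp_id` for every SNP in order.
#' @export
build_ld_structure <- function(n_blocks, block_size, rho, chrom = "1",
                               spacing = 1000) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  stopifnot(n_blocks >= 1, block_size >= 1)
  R <- rho^abs(outer(seq_len(block_size), seq_len(block_size), "-"))
  Rh <- mat_sqrt_psd(R)
  chrom <- rep_len(as.character(chrom), n_blocks)
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    start <- (b - 1L) * block_size
    blocks[[b]] <- list(chrom = chrom[b],
                        pos = as.integer((start + seq_len(block_size)) *
                                           spacing),
                        R = R, R_sqrt = Rh)
  }
  M <- n_blocks * block_size
  out <- list(blocks = blocks, M = M,
              snp_id = sprintf("rs%07d", seq_len(M)))
  class(out) <- "ld_structure"
  out
}

## Symmetric PSD square root; negative eigenvalues are clipped at zero
## (with a warning when the violation is material).
mat_sqrt_psd <- function(R, tol = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -tol)
    warning("correlation matrix not PSD; clipping eigenvalues at 0")
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Per-SNP LD scores of an LD structure
#'
#' The LD score of SNP j is the sum of squared correlations with all SNPs
#' in its block (including itself, so every score is >= 1).
#'
#' @param ld An `ld_structure`.
#' @param path Optional path: also write the scores as a TSV with columns
#'   `SNP`, `CHR`, `BP`, `L2`.
#' @return Data frame with `snp_id`, `chrom`, `pos`, `ldscore`, plus the
#'   total SNP count in `attr(x, "M")`.
#' @export
compute_ld_scores <- function(ld, path = NULL) {
  rows <- lapply(ld$blocks, function(b)
    data.frame(chrom = b$chrom, pos = b$pos, ldscore = rowSums(b$R^2)))
  out <- do.call(rbind, rows)
  out <- data.frame(snp_id = ld$snp_id, out, stringsAsFactors = FALSE)
  attr(out, "M") <- ld$M
  if (!is.null(path)) {
    tab <- data.frame(SNP = out$snp_id, CHR = out$chrom, BP = out$pos,
                      L2 = format(out$ldscore, digits = 17, trim = TRUE))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

#' Generative parameters for a simulated trait pair
#'
#' Records the ground truth a simulation is drawn from, for recovery tests.
#' In `lcv_latent` mode the latent loadings `q1`, `q2` determine the
#' genetic correlation (`rg = q1*q2`); supplying them overrides `rg`.
#'
#' @param h2_1,h2_2 SNP heritabilities in [0, 1].
#' @param rg Genetic effect correlation in [-1, 1].
#' @param n1,n2 GWAS sample sizes.
#' @param n_overlap Number of samples shared between the two GWAS.
#' @param pheno_corr Phenotypic correlation within the overlapping samples;
#'   with `n_overlap` it sets the cross-trait score-noise correlation
#'   `pheno_corr * n_overlap / sqrt(n1*n2)` (the LDSC cross-intercept).
#' @param q1,q2 Latent-variable loadings (lcv_latent mode only).
#' @param p_causal Proportion of SNPs with nonzero latent effect in the
#'   point-normal latent distribution (default 0.1); smaller values give
#'   larger excess kurtosis, which is what makes the causality proportion
#'   identifiable.
#' @return List of class `sim_truth`.
#' @export
sim_truth <- function(h2_1 = 0.5, h2_2 = 0.5, rg = 0.3,
                      n1 = 50000, n2 = 50000,
                      n_overlap = 0, pheno_corr = 0,
                      q1 = NULL, q2 = NULL, p_causal = 0.1) {
  if (h2_1 < 0 || h2_1 > 1 || h2_2 < 0 || h2_2 > 1)
    stop("heritabilities must lie in [0, 1]")
  if (!is.null(q1) && !is.null(q2)) {
    if (abs(q1) > 1 || abs(q2) > 1) stop("|q| loadings must be <= 1")
    rg <- q1 * q2
  }
  if (abs(rg) > 1) stop("|rg| must be <= 1")
  if (n_overlap > min(n1, n2)) stop("n_overlap exceeds min(n1, n2)")
  if (p_causal <= 0 || p_causal > 1) stop("p_causal must lie in (0, 1]")
  out <- list(h2_1 = h2_1, h2_2 = h2_2, rg = rg, n1 = n1, n2 = n2,
              n_overlap = n_overlap, pheno_corr = pheno_corr,
              q1 = q1, q2 = q2, p_causal = p_causal)
  class(out) <- "sim_truth"
  out
}

#' Simulate paired GWAS summary statistics
#'
#' Per-SNP true effects are drawn jointly for the two traits, then marginal
#' Z-scores are formed under the standard summary-statistics model:
#' `z = sqrt(N) * R %*% beta + eps` with `eps ~ N(0, R)` per block and
#' cross-trait noise correlation `pheno_corr * n_overlap / sqrt(n1*n2)`.
#'
#' Modes:
#' \describe{
#'   \item{bivariate_normal}{effects are bivariate normal with per-SNP
#'     variance `h2/M` and correlation `rg`.}
#'   \item{lcv_latent}{a latent variable `pi` with a point-normal (hence
#'     kurtotic) distribution drives both traits: in normalised units
#'     `alpha_i = q_i*pi + e_i`, `Var(alpha_i) = 1`, so `rg = q1*q2` and
#'     the causality proportion is identifiable from mixed fourth moments.}
#' }
#'
#' Per-block RNG substreams are derived from the master seed so earlier
#' blocks are unchanged when more blocks are added.
#'
#' @param ld An `ld_structure`.
#' @param truth A [sim_truth()].
#' @param mode `"bivariate_normal"` or `"lcv_latent"`.
#' @param seed Master RNG seed.
#' @return List with elements `ss1`, `ss2` (both `sumstats`) and `truth`.
#' @export
simulate_pair <- function(ld, truth, mode = c("bivariate_normal",
                                              "lcv_latent"),
                          seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(ld, "ld_structure"), inherits(truth, "sim_truth"))
  M <- ld$M
  if (mode == "lcv_latent" && (is.null(truth$q1) || is.null(truth$q2)))
    stop("lcv_latent mode requires q1 and q2 loadings in sim_truth()")
  rho_e <- with(truth, pheno_corr * n_overlap / sqrt(n1 * n2))

  set.seed(seed)
  maf <- stats::runif(M, 0.05, 0.5)
  nb <- length(ld$blocks)
  block_seeds <- sample.int(.Machine$integer.max - 1L, nb)

  ## per-SNP standardised effects alpha (unit total variance per trait)
  if (mode == "bivariate_normal") {
    a1 <- stats::rnorm(M)
    a2 <- truth$rg * a1 + sqrt(max(0, 1 - truth$rg^2)) * stats::rnorm(M)
  } else {
    pc <- truth$p_causal
    lat <- ifelse(stats::runif(M) < pc,
                  stats::rnorm(M, sd = 1 / sqrt(pc)), 0)
    q1 <- truth$q1; q2 <- truth$q2
    a1 <- q1 * lat + sqrt(max(0, 1 - q1^2)) * stats::rnorm(M)
    a2 <- q2 * lat + sqrt(max(0, 1 - q2^2)) * stats::rnorm(M)
  }
  b1 <- a1 * sqrt(truth$h2_1 / M)
  b2 <- a2 * sqrt(truth$h2_2 / M)

  z1 <- numeric(M); z2 <- numeric(M)
  off <- 0L
  for (b in seq_len(nb)) {
    blk <- ld$blocks[[b]]
    m <- length(blk$pos)
    idx <- off + seq_len(m)
    set.seed(block_seeds[b])
    e1 <- blk$R_sqrt %*% stats::rnorm(m)
    e2 <- rho_e * e1 + sqrt(1 - rho_e^2) * (blk$R_sqrt %*% stats::rnorm(m))
    z1[idx] <- sqrt(truth$n1) * (blk$R %*% b1[idx]) + e1
    z2[idx] <- sqrt(truth$n2) * (blk$R %*% b2[idx]) + e2
    off <- off + m
  }

  chrom <- unlist(lapply(ld$blocks, function(b) rep(b$chrom, length(b$pos))))
  pos <- unlist(lapply(ld$blocks, function(b) b$pos))
  mk <- function(z, n) {
    ss <- data.frame(snp_id = ld$snp_id, chrom = chrom, pos = pos,
                     a1 = "A", a2 = "G", z = z, p = two_sided_p(z),
                     n = n, maf = maf, stringsAsFactors = FALSE)
    class(ss) <- c("sumstats", "data.frame")
    ss
  }
  list(ss1 = mk(z1, truth$n1), ss2 = mk(z2, truth$n2), truth = truth)
}

#' Partition the SNPs of an LD structure into contiguous gene models
#'
#' Utility for building gene-location fixtures over simulated data: SNPs
#' are split (in genome order, per chromosome) into `n_genes` contiguous
#' runs, and each run's positional span becomes one gene.
#'
#' @param ld An `ld_structure`.
#' @param n_genes Number of genes to create.
#' @return Gene table with `gene_id`, `chrom`, `start`, `end`.
#' @export
sim_gene_models <- function(ld, n_genes) {
  chrom <- unlist(lapply(ld$blocks, function(b) rep(b$chrom, length(b$pos))))
  pos <- unlist(lapply(ld$blocks, function(b) b$pos))
  stopifnot(n_genes >= 1, n_genes <= length(pos))
  grp <- cut(seq_along(pos), breaks = n_genes, labels = FALSE)
  ## avoid genes straddling chromosomes: split runs at chromosome changes
  key <- paste(grp, chrom, sep = ":")
  runs <- split(seq_along(pos), factor(key, levels = unique(key)))
  data.frame(gene_id = sprintf("G%04d", seq_along(runs)),
             chrom = vapply(runs, function(i) chrom[i[1]], ""),
             start = vapply(runs, function(i) min(pos[i]), 0),
             end = vapply(runs, function(i) max(pos[i]), 0),
             stringsAsFactors = FALSE)
}

#' Generate a random gene-set collection
#'
#' @param gene_ids Universe of gene identifiers.
#' @param n_sets Number of sets.
#' @param size_range Integer range of set sizes.
#' @param seed RNG seed.
#' @param path Optional path: write the collection in GMT format.
#' @return A `geneset_collection`.
#' @export
sim_gmt <- function(gene_ids, n_sets, size_range = c(10, 50), seed = 1,
                    path = NULL) {
  set.seed(seed)
  sets <- list()
  for (i in seq_len(n_sets)) {
    k <- sample(size_range[1]:size_range[2], 1)
    sets[[sprintf("SET_%03d", i)]] <- sample(gene_ids, min(k, length(gene_ids)))
  }
  out <- list(sets = sets, collection_name = "simulated", source = NA)
  class(out) <- "geneset_collection"
  if (!is.null(path)) {
    lines <- vapply(names(sets), function(s)
      paste(c(s, "simulated", sets[[s]]), collapse = "\t"), "")
    writeLines(lines, path)
    out$source <- path
  }
  out
}

#' @export
print.ld_structure <- function(x, ...) {
  cat("ld_structure:", length(x$blocks), "blocks,", x$M, "SNPs\n")
  invisible(x)
}
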