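# Fixtures are built in code at test time; nothing binary is stored.

write_toy_sumstats <- function(path,
                               snp = c("rs1", "rs2", "rs3"),
                               chr = c(1, 1, 2),
                               bp = c(100, 200, 300),
                               z = c(2, -1, 0.5),
                               n = 1000,
                               p = NULL,
                               maf = c(0.1, 0.2, 0.3)) {
  df <- data.frame(SNP = snp, CHR = chr, BP = bp, A1 = "A", A2 = "G",
                   Z = z, N = n, MAF = maf)
  if (!is.null(p)) df$P <- p
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## Brute-force O(SNPs x genes) mapping oracle.
map_oracle <- function(ss, genes, window_kb = 0) {
  w <- window_kb * 1000
  out <- list()
  for (g in seq_len(nrow(genes))) {
    hit <- which(ss$chrom == genes$chrom[g] &
                   ss$pos >= genes$start[g] - w &
                   ss$pos <= genes$end[g] + w)
    if (length(hit)) out[[genes$gene_id[g]]] <- sort(hit)
  }
  out
}

## Step-up BH oracle, straight from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- rep(NA_real_, n)
  cummin_rev <- rev(cummin(rev(p[o] * n / seq_len(n))))
  q[o] <- pmin(cummin_rev, 1)
  q
}

## Small AR(1) correlation matrix.
ar1_mat <- function(k, rho) rho^abs(outer(seq_len(k), seq_len(k), "-"))

## Fast paired null gene Z-scores (single-SNP genes) with cross-trait
## score correlation rho_e; used for meta-calibration checks.
paired_null_gene_z <- function(n_genes, rho_e, seed) {
  set.seed(seed)
  z1 <- rnorm(n_genes)
  z2 <- rho_e * z1 + sqrt(1 - rho_e^2) * rnorm(n_genes)
  p1 <- 2 * pnorm(abs(z1), lower.tail = FALSE)
  p2 <- 2 * pnorm(abs(z2), lower.tail = FALSE)
  list(p1 = p1, p2 = p2,
       g1 = qnorm(p1, lower.tail = FALSE),
       g2 = qnorm(p2, lower.tail = FALSE))
}
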