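#' Column dialect for summary-statistics tables
#'
#' GWAS summary statistics arrive with many header conventions. A dialect
#' maps the canonical field names used throughout this package to the
#' column names present in a particular file.
#'
#' @param snp,chrom,pos,a1,a2,z,p,n,maf Column names in the file for each
#'   canonical field. `z`, `p`, `n` and `maf` may be `NA` if absent; at
#'   least one of `z` or `p` must be named, and `n` may instead be supplied
#'   as a study-wide scalar to [read_sumstats()].
#' @return A named character vector of class `"sumstats_dialect"`.
#' @export
sumstats_dialect <- function(snp = "SNP", chrom = "CHR", pos = "BP",
                             a1 = "A1", a2 = "A2", z = "Z", p = "P",
                             n = "N", maf = "MAF") {
  d <- c(snp = snp, chrom = chrom, pos = pos, a1 = a1, a2 = a2,
         z = z, p = p, n = n, maf = maf)
  class(d) <- "sumstats_dialect"
  d
}

#' Read GWAS summary statistics
#'
#' Reads a delimited text file of per-SNP association records and returns a
#' validated `sumstats` data frame with canonical columns `snp_id`, `chrom`,
#' `pos`, `a1`, `a2`, `z`, `p`, `n`, `maf`. Rows failing row-level
#' validation (p outside (0,1], non-positive n, pos < 1, maf outside
#' [0, 0.5]) are dropped and counted in `attr(x, "n_dropped")`.
#'
#' When both Z and P columns are present they must be mutually consistent:
#' the two-sided normal tail of |z| must equal p to within 1e-6 relative,
#' otherwise an error naming the first offending SNP is raised. When only P
#' is given, `z` is set to `NA` — a signed statistic cannot be recovered
#' from a two-sided p-value alone.
#'
#' @param path Path to a tab/whitespace-delimited file with a header row.
#' @param dialect A [sumstats_dialect()] mapping canonical fields to the
#'   file's column names.
#' @param n Optional study-wide sample size used when the file has no N
#'   column.
#' @param sep Field separator passed to [utils::read.table()].
#' @return A data frame of class `c("sumstats", "data.frame")`.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(), n = NULL,
                          sep = "") {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("snp", "chrom", "pos", "a1", "a2")
  for (f in need) {
    if (is.na(dialect[[f]]) || !dialect[[f]] %in% names(raw))
      stop("missing mandatory column '", dialect[[f]], "' (field ", f, ")")
  }
  has_z <- !is.na(dialect[["z"]]) && dialect[["z"]] %in% names(raw)
  has_p <- !is.na(dialect[["p"]]) && dialect[["p"]] %in% names(raw)
  if (!has_z && !has_p)
    stop("need at least one of Z ('", dialect[["z"]], "') or P ('",
         dialect[["p"]], "') columns")
  has_n <- !is.na(dialect[["n"]]) && dialect[["n"]] %in% names(raw)
  if (!has_n && is.null(n))
    stop("no N column '", dialect[["n"]], "' and no scalar n= supplied")

  ss <- data.frame(
    snp_id = as.character(raw[[dialect[["snp"]]]]),
    chrom  = as.character(raw[[dialect[["chrom"]]]]),
    pos    = as.integer(raw[[dialect[["pos"]]]]),
    a1     = as.character(raw[[dialect[["a1"]]]]),
    a2     = as.character(raw[[dialect[["a2"]]]]),
    z      = if (has_z) as.numeric(raw[[dialect[["z"]]]]) else NA_real_,
    p      = if (has_p) as.numeric(raw[[dialect[["p"]]]]) else NA_real_,
    n      = if (has_n) as.numeric(raw[[dialect[["n"]]]]) else as.numeric(n),
    maf    = if (!is.na(dialect[["maf"]]) && dialect[["maf"]] %in% names(raw))
               as.numeric(raw[[dialect[["maf"]]]]) else NA_real_,
    stringsAsFactors = FALSE)

  if (!has_p && has_z)
    ss$p <- two_sided_p(ss$z)

  ## z/p consistency is a file-level defect, not a row-level one
  if (has_z && has_p) {
    both <- !is.na(ss$z) & !is.na(ss$p) & ss$p > 0 & ss$p <= 1
    expect <- two_sided_p(ss$z[both])
    rel <- abs(expect - ss$p[both]) / pmax(ss$p[both], .Machine$double.xmin)
    bad <- which(rel > 1e-6 + 1e-12)
    if (length(bad))
      stop("Z and P columns disagree (first offender: snp_id ",
           ss$snp_id[both][bad[1]], ")")
  }

  ok <- !is.na(ss$pos) & ss$pos >= 1 &
    !is.na(ss$n) & ss$n > 0 &
    (is.na(ss$p) | (ss$p > 0 & ss$p <= 1)) &
    (is.na(ss$maf) | (ss$maf >= 0 & ss$maf <= 0.5))
  n_dropped <- sum(!ok)
  ss <- ss[ok, , drop = FALSE]
  if (nrow(ss) == 0L) stop("no rows survived validation in ", path)
  if (anyDuplicated(ss$snp_id))
    stop("duplicate snp_id: ", ss$snp_id[duplicated(ss$snp_id)][1])
  rownames(ss) <- NULL
  attr(ss, "n_dropped") <- n_dropped
  class(ss) <- c("sumstats", "data.frame")
  ss
}

#' Write summary statistics as TSV
#'
#' Full-precision round trip: values are written with 17 significant digits
#' so that read-after-write reproduces them exactly.
#'
#' @param ss A `sumstats` data frame.
#' @param path Output path.
#' @export
write_sumstats <- function(ss, path) {
  out <- data.frame(SNP = ss$snp_id, CHR = ss$chrom, BP = ss$pos,
                    A1 = ss$a1, A2 = ss$a2,
                    Z = format(ss$z, digits = 17, trim = TRUE),
                    P = format(ss$p, digits = 17, trim = TRUE),
                    N = format(ss$n, digits = 17, trim = TRUE),
                    MAF = format(ss$maf, digits = 17, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

two_sided_p <- function(z) 2 * stats::pnorm(abs(z), lower.tail = FALSE)

#' Read a gene location table
#'
#' Whitespace/tab-delimited table with columns gene id, chromosome, start,
#' end (1-based, closed intervals). Chromosome names may carry a "chr"
#' prefix, which is stripped.
#'
#' @param path Path to the table (no header by default).
#' @param header Does the file have a header row?
#' @param autosomes_only Drop genes on non-autosomal chromosomes? The count
#'   of excluded genes is recorded in `attr(x, "n_non_autosomal")`.
#' @return A data frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_loc <- function(path, header = FALSE, autosomes_only = TRUE) {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = header, stringsAsFactors = FALSE)
  if (ncol(raw) < 4) stop("gene location table needs >= 4 columns")
  g <- data.frame(gene_id = as.character(raw[[1]]),
                  chrom = sub("^chr", "", as.character(raw[[2]])),
                  start = as.integer(raw[[3]]),
                  end = as.integer(raw[[4]]),
                  stringsAsFactors = FALSE)
  bad <- which(g$start > g$end)
  if (length(bad))
    stop("start > end for gene ", g$gene_id[bad[1]])
  if (anyDuplicated(g$gene_id))
    stop("duplicate gene_id: ", g$gene_id[duplicated(g$gene_id)][1])
  n_non_auto <- 0L
  if (autosomes_only) {
    auto <- g$chrom %in% as.character(1:22)
    n_non_auto <- sum(!auto)
    g <- g[auto, , drop = FALSE]
  }
  rownames(g) <- NULL
  attr(g, "n_non_autosomal") <- n_non_auto
  g
}

#' Map SNPs to genes by position
#'
#' SNP j is assigned to gene g iff the chromosomes match and
#' `start - w <= pos_j <= end + w` where `w = window_kb * 1000` (closed
#' interval, symmetric window). Genes tagged by no SNP are omitted from the
#' mapping and counted in `attr(x, "n_empty_genes")`.
#'
#' @param ss A `sumstats` data frame.
#' @param genes Gene table from [read_gene_loc()].
#' @param window_kb Symmetric window in kilobases (default 0).
#' @return An object of class `gene_annotation`: list with `idx` (named
#'   list mapping gene_id to integer row indices into `ss`), `genes` (the
#'   gene table restricted to non-empty genes, with `n_snps`), and
#'   `window_kb`.
#' @export
map_snps_to_genes <- function(ss, genes, window_kb = 0) {
  stopifnot(window_kb >= 0)
  w <- window_kb * 1000
  idx <- vector("list", nrow(genes))
  names(idx) <- genes$gene_id
  ord <- order(ss$pos)
  for (ch in unique(genes$chrom)) {
    on_ch <- ord[ss$chrom[ord] == ch]
    if (!length(on_ch)) next
    pos_ch <- ss$pos[on_ch]
    gi <- which(genes$chrom == ch)
    lo <- findInterval(genes$start[gi] - w - 1L, pos_ch) + 1L
    hi <- findInterval(genes$end[gi] + w, pos_ch)
    for (k in seq_along(gi)) {
      if (lo[k] <= hi[k]) idx[[gi[k]]] <- sort(on_ch[lo[k]:hi[k]])
    }
  }
  nz <- lengths(idx) > 0L
  if (!any(nz)) warning("no gene was tagged by any SNP")
  ann_genes <- genes[nz, , drop = FALSE]
  ann_genes$n_snps <- lengths(idx)[nz]
  rownames(ann_genes) <- NULL
  out <- list(idx = idx[nz], genes = ann_genes, window_kb = window_kb)
  attr(out, "n_empty_genes") <- sum(!nz)
  class(out) <- "gene_annotation"
  out
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields
#' `set_id<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within
#' a set are deduplicated; file order is preserved.
#'
#' @param path Path to a GMT file.
#' @param collection_name Label stored with the collection (defaults to the
#'   file name).
#' @return An object of class `geneset_collection`: list with `sets` (named
#'   list of character vectors), `collection_name` and `source`.
#' @export
read_gmt <- function(path, collection_name = basename(path)) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT collection: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 fields")
    sets[[f[1]]] <- unique(f[-(1:2)])
  }
  out <- list(sets = sets, collection_name = collection_name, source = path)
  class(out) <- "geneset_collection"
  out
}

#' Read per-SNP LD scores
#'
#' TSV with a header and columns `SNP` and `L2` (or `snp_id`/`ldscore`).
#'
#' @param path Path to the LD-score table.
#' @return Data frame with columns `snp_id`, `ldscore`.
#' @export
read_ld_scores <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  snp_col <- intersect(c("SNP", "snp_id"), names(raw))[1]
  l_col <- intersect(c("L2", "ldscore", "l2"), names(raw))[1]
  if (is.na(snp_col) || is.na(l_col))
    stop("LD score table needs SNP/snp_id and L2/ldscore columns")
  data.frame(snp_id = as.character(raw[[snp_col]]),
             ldscore = as.numeric(raw[[l_col]]),
             stringsAsFactors = FALSE)
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", length(x$idx), "genes with >=1 SNP,",
      "window", x$window_kb, "kb\n")
  invisible(x)
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat("geneset_collection '", x$collection_name, "': ",
      length(x$sets), " sets\n", sep = "")
  invisible(x)
}
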