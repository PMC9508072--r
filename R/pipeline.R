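#' Write a result table as TSV
#'
#' Fixed, documented headers; numeric columns at full precision.
#'
#' @param x A data frame.
#' @param path Output path.
#' @export
write_result_tsv <- function(x, path) {
  out <- as.data.frame(x)
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(v)
    format(v, digits = 17, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validate a pairwise-pipeline configuration
#'
#' A configuration is a named list (or a YAML file parsed into one) with:
#' \describe{
#'   \item{traits}{list of trait specs: `label`, `n_samples` (`n` also
#'     accepted in programmatic lists; YAML parses a bare `n` key as a
#'     boolean), and either `sumstats` (a path) or `sumstats_object`.}
#'   \item{anchor}{label of the anchor trait, meta-analysed against every
#'     other trait.}
#'   \item{ld}{an `ld_structure`, or a list with `n_blocks`, `block_size`,
#'     `rho` (AR(1) generator parameters).}
#'   \item{gene_loc}{path to a gene-location table, or a gene data frame.}
#'   \item{gmt}{optional named list of GMT paths (or
#'     `geneset_collection`s).}
#'   \item{thresholds}{`alpha_gene`, `nominal`, `fdr`, `rg_alpha` (LCV
#'     gate).}
#'   \item{window_kb, jackknife_blocks, seed, out_dir}{scalars.}
#' }
#'
#' @param config Named list or path to a YAML file.
#' @return The validated config with defaults filled in.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$traits),
            !is.null(config$out_dir))
  if (length(config$traits) < 2) stop("need at least two traits")
  labels <- vapply(config$traits, `[[`, "", "label")
  if (is.null(config$anchor)) config$anchor <- labels[1]
  if (!config$anchor %in% labels) stop("anchor trait not among traits")
  defaults <- list(alpha_gene = NA, nominal = 0.05, fdr = 0.05,
                   rg_alpha = 0.05)
  config$thresholds <- utils::modifyList(defaults,
                                         config$thresholds %||% list())
  th <- config$thresholds[c("nominal", "fdr", "rg_alpha")]
  if (any(unlist(th) <= 0 | unlist(th) >= 1))
    stop("thresholds must lie in (0, 1)")
  config$window_kb <- config$window_kb %||% 0
  config$jackknife_blocks <- config$jackknife_blocks %||% 200
  config$seed <- config$seed %||% 1
  for (i in seq_along(config$traits)) {
    tr <- config$traits[[i]]
    ## YAML 1.1 parses a bare `n` key as a boolean, so configs use
    ## `n_samples`; programmatic lists may use either
    tr$n <- tr[["n"]] %||% tr[["n_samples"]]
    if (is.null(tr$n) || !is.numeric(tr$n) || tr$n <= 0)
      stop("trait '", tr$label, "' needs a positive n_samples")
    if (!is.null(tr[["sumstats"]]) && !file.exists(tr[["sumstats"]]))
      stop("sumstats path does not exist: ", tr[["sumstats"]])
    config$traits[[i]] <- tr
  }
  if (is.character(config$gene_loc) && !file.exists(config$gene_loc))
    stop("gene_loc path does not exist: ", config$gene_loc)
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_ld <- function(ld) {
  if (inherits(ld, "ld_structure")) return(ld)
  build_ld_structure(ld$n_blocks, ld$block_size, ld$rho,
                     chrom = ld$chrom %||% "1")
}

resolve_sumstats <- function(tr) {
  if (!is.null(tr[["sumstats_object"]])) return(tr[["sumstats_object"]])
  read_sumstats(tr[["sumstats"]], n = tr$n)
}

#' Run the full pairwise cross-trait analysis
#'
#' For each non-anchor trait, runs the complete pairwise workflow against
#' the anchor: gene-based association for both traits, Stouffer and Cauchy
#' gene meta-analysis, method concordance, the novel-pleiotropic-signal
#' filter, LD score regression genetic correlation, an LCV causality fit
#' (skipped with a recorded reason when the genetic correlation does not
#' pass the configured threshold), and competitive gene-set runs on the
#' anchor alone and on the meta-analysed Z-scores. A failure in one pair
#' is logged and does not abort the remaining pairs. Results are written
#' under `out_dir/<anchor>_<partner>/` and a manifest under
#' `out_dir/manifest.yaml`.
#'
#' @param config See [validate_pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pairwise_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ld <- resolve_ld(config$ld)
  ldsc_tab <- compute_ld_scores(ld)
  genes <- if (is.character(config$gene_loc))
    read_gene_loc(config$gene_loc) else config$gene_loc
  gmts <- lapply(config$gmt %||% list(), function(g)
    if (inherits(g, "geneset_collection")) g else read_gmt(g))

  labels <- vapply(config$traits, `[[`, "", "label")
  anchor_i <- which(labels == config$anchor)
  anchor <- config$traits[[anchor_i]]
  ss_a <- resolve_sumstats(anchor)
  annot <- map_snps_to_genes(ss_a, genes, window_kb = config$window_kb)
  res_a <- run_gene_analysis(ss_a, annot, ld)
  alpha_gene <- config$thresholds$alpha_gene
  if (is.na(alpha_gene) || is.null(alpha_gene))
    alpha_gene <- attr(res_a, "bonferroni_threshold")

  geneset_anchor <- lapply(gmts, function(g)
    run_geneset_collection(res_a, g, fdr_alpha = config$thresholds$fdr))

  manifest <- list(package = "pairmeta",
                   version = as.character(utils::packageVersion("pairmeta")),
                   seed = config$seed,
                   anchor = config$anchor,
                   window_kb = config$window_kb,
                   jackknife_blocks = config$jackknife_blocks,
                   thresholds = config$thresholds,
                   alpha_gene_used = alpha_gene,
                   n_genes_tested_anchor = attr(res_a, "n_tested"),
                   pairs = list(), files = character(), errors = list())

  for (j in seq_along(config$traits)[-anchor_i]) {
    partner <- config$traits[[j]]
    pair_id <- paste(config$anchor, partner$label, sep = "_")
    pair_dir <- file.path(config$out_dir, pair_id)
    pair_info <- list(partner = partner$label)
    ok <- tryCatch({
      dir.create(pair_dir, showWarnings = FALSE)
      ss_b <- resolve_sumstats(partner)
      res_b <- run_gene_analysis(ss_b, annot, ld)
      meta <- meta_combine_genes(res_a, res_b, anchor$n, partner$n,
                                 method = "both")
      conc <- method_concordance(meta$p_stouffer, meta$p_cauchy)
      novel <- novel_signal_filter(res_a, res_b, meta,
                                   alpha_gene = alpha_gene,
                                   nominal = config$thresholds$nominal)
      rg <- estimate_rg(qc_filter(ss_a, min_snps = 50),
                        qc_filter(ss_b, min_snps = 50),
                        ldsc_tab, M = ld$M,
                        n_blocks = config$jackknife_blocks)
      lcv <- NULL
      lcv_skip_reason <- NULL
      if (rg$p < config$thresholds$rg_alpha) {
        lcv <- tryCatch(
          lcv_gcp(qc_filter(ss_a, min_snps = 50),
                  qc_filter(ss_b, min_snps = 50), ldsc_tab,
                  z_h2 = c(rg$h2_1$z_h2, rg$h2_2$z_h2)),
          error = function(e) {
            lcv_skip_reason <<- conditionMessage(e); NULL })
      } else {
        lcv_skip_reason <- sprintf(
          "genetic correlation not significant (p = %.3g >= %.3g)",
          rg$p, config$thresholds$rg_alpha)
      }
      gs_meta <- lapply(names(gmts), function(nm) {
        gm <- res_a[match(meta$gene_id, res_a$gene_id), ]
        gm$z <- meta$z_meta
        gm$gene_id <- meta$gene_id
        run_geneset_collection(gm, gmts[[nm]],
                               fdr_alpha = config$thresholds$fdr,
                               compare_run = geneset_anchor[[nm]])
      })
      names(gs_meta) <- names(gmts)

      files <- c(
        gene_a = write_result_tsv(res_a,
          file.path(pair_dir, "gene_results_anchor.tsv")),
        gene_b = write_result_tsv(res_b,
          file.path(pair_dir, "gene_results_partner.tsv")),
        meta = write_result_tsv(meta, file.path(pair_dir, "meta.tsv")),
        novel = write_result_tsv(novel, file.path(pair_dir, "novel.tsv")))
      rg_tab <- data.frame(
        rg = rg$rg, se = rg$se, p = rg$p,
        cross_intercept = rg$cross_intercept,
        cross_intercept_p = rg$cross_intercept_p,
        h2_1 = rg$h2_1$h2, h2_1_se = rg$h2_1$se,
        h2_2 = rg$h2_2$h2, h2_2_se = rg$h2_2$se)
      files <- c(files, rg = write_result_tsv(
        rg_tab, file.path(pair_dir, "rg.tsv")))
      if (!is.null(lcv)) {
        lcv_tab <- data.frame(gcp = lcv$gcp, gcp_se = lcv$gcp_se,
                              z_gcp = lcv$z_gcp, p = lcv$p,
                              rho = lcv$rho,
                              partial_causality =
                                lcv$partial_causality_flag,
                              warnings = paste(lcv$warnings,
                                               collapse = "; "))
        files <- c(files, lcv = write_result_tsv(
          lcv_tab, file.path(pair_dir, "lcv.tsv")))
      }
      for (nm in names(gs_meta)) {
        files <- c(files, write_result_tsv(gs_meta[[nm]],
          file.path(pair_dir, paste0("geneset_", nm, ".tsv"))))
      }
      pair_info$concordance <- conc[c("r", "ci_low", "ci_high")]
      pair_info$n_genes_meta <- attr(meta, "n_genes")
      pair_info$n_novel <- sum(novel$retained)
      pair_info$rg <- rg$rg
      pair_info$rg_p <- rg$p
      pair_info$lcv_skip_reason <- lcv_skip_reason
      pair_info$files <- unname(files)
      manifest$files <- c(manifest$files, unname(files))
      TRUE
    }, error = function(e) {
      manifest$errors[[pair_id]] <<- conditionMessage(e)
      FALSE
    })
    pair_info$status <- if (ok) "ok" else "failed"
    manifest$pairs[[pair_id]] <- pair_info
  }
  for (nm in names(geneset_anchor)) {
    f <- file.path(config$out_dir,
                   paste0("geneset_anchor_", nm, ".tsv"))
    write_result_tsv(geneset_anchor[[nm]], f)
    manifest$files <- c(manifest$files, f)
  }
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(manifest)
}
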