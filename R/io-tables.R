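#' @noRd
require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, ": missing required column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

#' Read per-SNP GWAS summary statistics
#'
#' Tab-separated with header columns `snp_id`, `chrom`, `pos_bp`,
#' `effect_allele`, `other_allele`, `ln_or`, `se`, `p` (the per-allele
#' natural-log odds ratio of the additive case-control model and its
#' standard error and p value).
#'
#' @param path path to the TSV.
#' @return data.frame with the columns above, validated (`p` in (0,1],
#'   `se > 0`, alleles distinct, unique SNP ids).
#' @export
read_gwas_summary <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  require_cols(df, c("snp_id", "chrom", "pos_bp", "effect_allele",
                     "other_allele", "ln_or", "se", "p"), "gwas summary")
  if (anyDuplicated(df$snp_id))
    stop("gwas summary: duplicated snp_id: ",
         df$snp_id[duplicated(df$snp_id)][1])
  if (any(df$p <= 0 | df$p > 1)) stop("gwas summary: p must lie in (0, 1]")
  if (any(df$se <= 0)) stop("gwas summary: se must be positive")
  if (any(df$effect_allele == df$other_allele))
    stop("gwas summary: effect_allele equals other_allele")
  df
}

#' Read gene intervals from a BED4 file
#'
#' BED is 0-based half-open on disk; intervals are converted to the
#' package's 1-based inclusive convention (the VCF convention), i.e.
#' `start + 1` with the end unchanged.
#'
#' @param path path to a 4-column BED file (chrom, start, end, name).
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_gene_bed <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = FALSE))
  if (ncol(df) < 4) stop("BED4 requires 4 columns (chrom, start, end, name)")
  out <- data.frame(gene = as.character(df[[4]]), chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]) + 1L, end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("BED: empty or inverted interval")
  out
}

#' Write gene intervals as BED4
#' @param genes data.frame as returned by [read_gene_bed()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  data.table::fwrite(
    data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read the phenotype/covariate table
#'
#' Tab-separated with header: `sample_id`, `sex` (0/1, 1 = female),
#' `birth_year`, `lrs_raw` (children ever born), and the fitness
#' covariates `education`, `smoking`, `born_in_country`, `estrogen_use`.
#' An `lrs_adjusted` column is accepted but normally produced later by
#' [adjust_lrs()].
#'
#' @param path path to the TSV.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  require_cols(df, c("sample_id", "sex", "birth_year", "lrs_raw", "education",
                     "smoking", "born_in_country", "estrogen_use"),
               "phenotypes")
  if (any(df$lrs_raw < 0)) stop("phenotypes: lrs_raw must be non-negative")
  df
}

#' Read a probes-x-samples expression matrix
#'
#' Tab-separated; first two columns `probe_id` and `gene`, remaining
#' columns one per sample. Values are assumed log2-scale and
#' pre-normalized (quantile within replicates, median per population) --
#' normalization itself is an input contract, not performed here.
#'
#' @param path path to the TSV.
#' @return list of class `expression_matrix` with `probe_ids`,
#'   `gene_links` (probe -> gene), `values` (probes x samples) and
#'   `sample_ids`.
#' @export
read_expression <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  require_cols(df, c("probe_id", "gene"), "expression")
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  if (anyNA(vals)) stop("expression: missing values are not allowed")
  rownames(vals) <- df$probe_id
  structure(list(probe_ids = df$probe_id,
                 gene_links = setNames(df$gene, df$probe_id),
                 values = vals, sample_ids = colnames(vals)),
            class = "expression_matrix")
}

#' Write an expression matrix
#' @param expr an `expression_matrix` (see [read_expression()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(probe_id = expr$probe_ids,
                   gene = unname(expr$gene_links[expr$probe_ids]),
                   expr$values, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Write a named list of result tables as TSV files
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if absent).
#' @return character vector of the files written.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, paste0(names(tables), ".tsv"))
  for (i in seq_along(tables))
    data.table::fwrite(tables[[i]], paths[i], sep = "\t")
  invisible(paths)
}

#' Load a run configuration
#'
#' YAML with seeds, thresholds (iHS cutoff, r-squared thresholds,
#' permutation counts, MAF/DAF bin widths, QC filters), file paths and the
#' population list. Missing fields are filled from [default_config()];
#' permutation counts must be at least 1.
#'
#' @param path path to a YAML file.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- modifyList(default_config(), cfg)
  validate_config(cfg)
}

#' Default pipeline configuration
#' @return a list of every tunable the pipeline uses, at its documented
#'   default.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    populations = c("CEU", "YRI"),
    n_genes = 4L,
    sim = list(n_samples = 100L, n_snps = 2000L, chrom_length_bp = 1e7,
               recomb_rate_cM_per_Mb = 3, wf_population_size = 400L,
               wf_generations = 200L, sweep_s = 0.05, sweep_stop = 0.6),
    qc = list(call_rate_min = 0.95, hwe_p_min = 1e-6, maf_min = 0.01),
    scan = list(cutoff = 0.05, max_gap_bp = 2e5, maf_min = 0.05,
                daf_bin_width = 0.025, n_perm = 1000L,
                ihs_min = 2, p_max = 0.05, cluster_k = 2L,
                cluster_window_bp = 5e4),
    locus = list(flank_bp = 5000L, r2_link = 0.7, r2_block = 0.7,
                 length_tol = 0.2, n_null_genes = 100L),
    assoc = list(n_perm = 1000L, alpha = 0.05, min_count = 4L),
    eqtl = list(n_perm = 1000L),
    fitness = list(n_groups = 6L, prune_r2 = 0.2, r2_excl = 0.8,
                   exclude_window_bp = 1e6, n_perm = 1000L, maf_bin = 0.05,
                   n_set_draws = 100L, n_gene_perm = 100L,
                   n_set_gene_draws = 300L, alpha = 0.05),
    antagonism = list(alpha = 0.05, r2_proxy = 0.8, proxy_window_bp = 1e6)
  )
}

validate_config <- function(cfg) {
  perms <- c(cfg$scan$n_perm, cfg$assoc$n_perm, cfg$eqtl$n_perm,
             cfg$fitness$n_perm, cfg$fitness$n_set_draws,
             cfg$fitness$n_gene_perm, cfg$fitness$n_set_gene_draws)
  if (any(perms < 1)) stop("config: every permutation count must be >= 1")
  if (is.null(cfg$seed)) stop("config: seed is required")
  cfg
}

#' Append timestamped lines to a run log
#' @param log_path path of the log file (created if absent).
#' @param ... character fragments pasted into one line.
#' @return `log_path`, invisibly.
#' @export
run_log <- function(log_path, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " | ",
                 paste0(..., collapse = ""))
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
  invisible(log_path)
}
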