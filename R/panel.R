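#' Phased haplotype panel
#'
#' The central container of the package: a phased diploid panel coded 0/1
#' relative to the ancestral state (0 = ancestral, 1 = derived). Rows
#' `2i - 1` and `2i` of `hap_matrix` are the two haplotypes of sample `i`.
#'
#' @param snp_ids character vector of SNP identifiers.
#' @param chrom single chromosome label.
#' @param positions_bp strictly increasing 1-based physical positions.
#' @param genetic_pos_cM non-decreasing genetic-map positions in centimorgans.
#' @param alleles data.frame with columns `ancestral` and `derived`, one row
#'   per SNP.
#' @param hap_matrix integer matrix (haplotypes x SNPs) with entries in
#'   \{0, 1\} (NA allowed for missing real-data genotypes).
#' @param sample_ids one identifier per diploid sample (half the number of
#'   haplotype rows).
#' @param population population label.
#' @param founder_flags logical per sample; founders are used for
#'   Hardy-Weinberg testing. Defaults to all `TRUE`.
#'
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(snp_ids, chrom, positions_bp, genetic_pos_cM,
                            alleles, hap_matrix, sample_ids,
                            population = "POP", founder_flags = NULL) {
  hap_matrix <- as.matrix(hap_matrix)
  storage.mode(hap_matrix) <- "integer"
  n_snp <- length(snp_ids)
  if (is.null(founder_flags)) founder_flags <- rep(TRUE, length(sample_ids))
  obj <- structure(list(
    snp_ids = as.character(snp_ids),
    chrom = as.character(chrom)[1],
    positions_bp = as.integer(positions_bp),
    genetic_pos_cM = as.numeric(genetic_pos_cM),
    alleles = alleles,
    hap_matrix = hap_matrix,
    sample_ids = as.character(sample_ids),
    population = as.character(population)[1],
    founder_flags = as.logical(founder_flags)
  ), class = "haplotype_panel")
  validate_panel(obj)
  obj
}

validate_panel <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  h <- panel$hap_matrix
  n_snp <- length(panel$snp_ids)
  if (ncol(h) != n_snp)
    stop("hap_matrix has ", ncol(h), " columns but ", n_snp, " SNP ids")
  if (nrow(h) %% 2L != 0L)
    stop("hap_matrix must have an even number of rows (2 per diploid)")
  if (nrow(h) != 2L * length(panel$sample_ids))
    stop("hap_matrix rows must equal 2 x sample count")
  if (length(panel$positions_bp) != n_snp ||
      length(panel$genetic_pos_cM) != n_snp)
    stop("positions and genetic map must match SNP count")
  if (n_snp > 1 && any(diff(panel$positions_bp) <= 0))
    stop("positions_bp must be strictly increasing")
  if (n_snp > 1 && any(diff(panel$genetic_pos_cM) < 0))
    stop("genetic_pos_cM must be non-decreasing")
  vals <- h[!is.na(h)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    stop("hap_matrix entries must be 0 (ancestral) or 1 (derived)")
  if (length(panel$founder_flags) != length(panel$sample_ids))
    stop("founder_flags must have one entry per sample")
  invisible(panel)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", length(x$sample_ids), "samples x",
      length(x$snp_ids), "SNPs, chrom", x$chrom,
      paste0("(", x$population, ")"), "\n")
  cat("  span:", min(x$positions_bp), "-", max(x$positions_bp), "bp;",
      sprintf("%.3f", diff(range(x$genetic_pos_cM))), "cM\n")
  invisible(x)
}

#' Number of samples / SNPs in a panel
#' @param panel a `haplotype_panel`.
#' @return integer count.
#' @export
n_samples <- function(panel) length(panel$sample_ids)

#' @rdname n_samples
#' @export
n_snps <- function(panel) length(panel$snp_ids)

#' Per-sample derived-allele dosage matrix
#'
#' Collapses the two haplotypes of each sample into a 0/1/2 dosage.
#'
#' @param panel a `haplotype_panel`.
#' @return integer matrix, samples x SNPs (NA where either haplotype is
#'   missing).
#' @export
dosage_matrix <- function(panel) {
  h <- panel$hap_matrix
  idx <- seq_len(nrow(h) %/% 2L)
  d <- h[2L * idx - 1L, , drop = FALSE] + h[2L * idx, , drop = FALSE]
  rownames(d) <- panel$sample_ids
  colnames(d) <- panel$snp_ids
  d
}

#' Derived allele frequency per SNP
#' @param panel a `haplotype_panel`.
#' @return numeric vector of derived-allele frequencies.
#' @export
derived_freq <- function(panel) colMeans(panel$hap_matrix, na.rm = TRUE)

#' Minor allele frequency per SNP
#' @param panel a `haplotype_panel`.
#' @return numeric vector of minor-allele frequencies.
#' @export
minor_freq <- function(panel) {
  p <- derived_freq(panel)
  pmin(p, 1 - p)
}

#' Restrict a panel to a subset of SNPs
#' @param panel a `haplotype_panel`.
#' @param keep logical or integer index over SNPs.
#' @return the restricted `haplotype_panel`.
#' @export
subset_snps <- function(panel, keep) {
  haplotype_panel(
    snp_ids = panel$snp_ids[keep], chrom = panel$chrom,
    positions_bp = panel$positions_bp[keep],
    genetic_pos_cM = panel$genetic_pos_cM[keep],
    alleles = panel$alleles[keep, , drop = FALSE],
    hap_matrix = panel$hap_matrix[, keep, drop = FALSE],
    sample_ids = panel$sample_ids, population = panel$population,
    founder_flags = panel$founder_flags
  )
}
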