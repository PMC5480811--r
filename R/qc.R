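#' One-degree-of-freedom Hardy-Weinberg chi-square p value
#'
#' Standard goodness-of-fit chi-square of observed genotype counts against
#' Hardy-Weinberg expectations, 1 df. Monomorphic sites return p = 1.
#'
#' @param n_aa,n_ab,n_bb counts of the three genotype classes.
#' @return two-sided p value from the chi-square(1) tail.
#' @export
hwe_chisq_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  p <- (2 * n_aa + n_ab) / (2 * n)
  if (p == 0 || p == 1) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  x2 <- sum((c(n_aa, n_ab, n_bb) - e)^2 / e)
  pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Apply marker quality-control filters
#'
#' Removes SNPs with genotype call rate below `call_rate_min`, a
#' Hardy-Weinberg p value (computed on founder genotypes only) below
#' `hwe_p_min`, or minor allele frequency below `maf_min`. Filters are
#' applied in that order and a per-filter removal count is attached as the
#' `qc_report` attribute. The operation is idempotent.
#'
#' @param panel a [haplotype_panel()].
#' @param call_rate_min minimum per-SNP genotype call rate (default 0.95).
#' @param hwe_p_min minimum Hardy-Weinberg p value (default 1e-6).
#' @param maf_min minimum minor allele frequency (default 0.01; monomorphic
#'   SNPs always fail).
#' @return the filtered panel, with attribute `qc_report`.
#' @export
apply_qc_filters <- function(panel, call_rate_min = 0.95, hwe_p_min = 1e-6,
                             maf_min = 0.01) {
  validate_panel(panel)
  stopifnot(call_rate_min > 0, call_rate_min <= 1,
            hwe_p_min > 0, hwe_p_min < 1, maf_min > 0, maf_min < 1)
  dos <- dosage_matrix(panel)
  call_rate <- colMeans(!is.na(dos))
  fail_cr <- call_rate < call_rate_min

  fdos <- dos[panel$founder_flags, , drop = FALSE]
  hwe_p <- vapply(seq_len(ncol(fdos)), function(j) {
    g <- fdos[, j]
    g <- g[!is.na(g)]
    hwe_chisq_p(sum(g == 2L), sum(g == 1L), sum(g == 0L))
  }, numeric(1))
  fail_hwe <- !fail_cr & hwe_p < hwe_p_min

  p <- colMeans(panel$hap_matrix, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  fail_maf <- !fail_cr & !fail_hwe & maf < maf_min

  keep <- !(fail_cr | fail_hwe | fail_maf)
  if (!any(keep)) stop("all SNPs removed by QC filters")
  out <- subset_snps(panel, keep)
  attr(out, "qc_report") <- c(call_rate = sum(fail_cr), hwe = sum(fail_hwe),
                              maf = sum(fail_maf), kept = sum(keep))
  out
}
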