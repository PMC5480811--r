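#' Greedy LD pruning of a panel's SNPs
#'
#' Walks SNPs in position order, keeping a SNP only when its r^2 with
#' every already-kept SNP within `window_bp` is at or below `r2_max`.
#'
#' @param panel a [haplotype_panel()].
#' @param r2_max pruning threshold (default 0.2).
#' @param window_bp comparison window (default 500 kb).
#' @param candidates optional SNP indices to prune within (default all
#'   segregating SNPs).
#' @return integer indices of the kept SNPs.
#' @export
ld_prune <- function(panel, r2_max = 0.2, window_bp = 5e5,
                     candidates = NULL) {
  if (is.null(candidates))
    candidates <- which(minor_freq(panel) > 0)
  pos <- panel$positions_bp
  h <- panel$hap_matrix
  kept <- integer(0)
  for (i in candidates) {
    near <- kept[pos[i] - pos[kept] <= window_bp]
    if (length(near)) {
      r2 <- cor(h[, near, drop = FALSE], h[, i])^2
      if (max(r2, na.rm = TRUE) > r2_max) next
    }
    kept <- c(kept, i)
  }
  kept
}

#' Realized relationship matrix from LD-pruned SNPs
#'
#' Builds the allele-frequency-standardized kernel
#' K_jk = (1/m) sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))
#' over an LD-pruned SNP subset. To avoid proximal contamination, SNPs
#' inside any exclusion interval (padded by `exclude_window_bp`) or with
#' r^2 at or above `r2_excl` to any SNP inside those intervals are never
#' used.
#'
#' @param panel a QC'd [haplotype_panel()].
#' @param prune_r2 LD-pruning threshold (default 0.2).
#' @param exclude_intervals optional data.frame (`chrom`, `start`, `end`)
#'   of loci whose neighbourhood must not feed the kernel.
#' @param exclude_window_bp padding around exclusion intervals
#'   (default 1 Mb).
#' @param r2_excl LD threshold to excluded-locus SNPs (default 0.8).
#' @param min_snps minimum kernel SNPs before erroring (default 50).
#' @return list of class `grm`: `sample_ids`, `kernel` (n x n), `snps`
#'   (ids used), `m`.
#' @export
compute_grm <- function(panel, prune_r2 = 0.2, exclude_intervals = NULL,
                        exclude_window_bp = 1e6, r2_excl = 0.8,
                        min_snps = 50) {
  validate_panel(panel)
  pos <- panel$positions_bp
  seg <- which(minor_freq(panel) > 0)
  drop <- rep(FALSE, n_snps(panel))
  if (!is.null(exclude_intervals) && nrow(exclude_intervals)) {
    inside <- rep(FALSE, n_snps(panel))
    for (k in seq_len(nrow(exclude_intervals))) {
      iv <- exclude_intervals[k, ]
      if (!identical(as.character(iv$chrom), panel$chrom)) next
      inside <- inside | (pos >= iv$start & pos <= iv$end)
      drop <- drop | (pos >= iv$start - exclude_window_bp &
                      pos <= iv$end + exclude_window_bp)
    }
    in_seg <- which(inside & minor_freq(panel) > 0)
    out_seg <- setdiff(seg, which(drop))
    if (length(in_seg) && length(out_seg)) {
      r2 <- cor(panel$hap_matrix[, out_seg, drop = FALSE],
                panel$hap_matrix[, in_seg, drop = FALSE])^2
      drop[out_seg[apply(r2, 1, max, na.rm = TRUE) >= r2_excl]] <- TRUE
    }
  }
  cand <- setdiff(seg, which(drop))
  kept <- ld_prune(panel, r2_max = prune_r2, candidates = cand)
  m <- length(kept)
  if (m < min_snps)
    stop("only ", m, " SNPs left for the relationship kernel (need >= ",
         min_snps, ")")
  x <- dosage_matrix(panel)[, kept, drop = FALSE]
  p <- colMeans(x) / 2
  z <- sweep(x, 2, 2 * p)
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(z) / m
  structure(list(sample_ids = panel$sample_ids, kernel = K,
                 snps = panel$snp_ids[kept], m = m), class = "grm")
}
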