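#' Haplotype-based linkage disequilibrium
#'
#' For phased 0/1 haplotypes the Pearson correlation between two SNP
#' columns equals D / sqrt(p1 q1 p2 q2), so r^2 is exactly
#' D^2 / (p1 q1 p2 q2) with D the haplotype-frequency covariance.
#'
#' @param panel a [haplotype_panel()].
#' @param snp_i,snp_j SNP ids or indices.
#' @return squared correlation in [0, 1].
#' @export
ld_r2 <- function(panel, snp_i, snp_j) {
  i <- resolve_snp(panel, snp_i)
  j <- resolve_snp(panel, snp_j)
  x <- panel$hap_matrix[, i]
  y <- panel$hap_matrix[, j]
  if (sd(x) == 0 || sd(y) == 0) stop("monomorphic SNP: r2 undefined")
  cor(x, y)^2
}

#' Pairwise LD matrix over a SNP set
#'
#' @param panel a [haplotype_panel()].
#' @param snps SNP ids or indices (position order preserved).
#' @param stat `"r2"` (squared correlation, default) or `"r"` (signed).
#' @return symmetric matrix with unit diagonal.
#' @export
ld_matrix <- function(panel, snps, stat = c("r2", "r")) {
  stat <- match.arg(stat)
  idx <- vapply(snps, resolve_snp, integer(1), panel = panel)
  X <- panel$hap_matrix[, idx, drop = FALSE]
  if (any(apply(X, 2, sd) == 0)) stop("monomorphic SNP: LD undefined")
  r <- cor(X)
  dimnames(r) <- list(panel$snp_ids[idx], panel$snp_ids[idx])
  if (stat == "r2") r^2 else r
}

#' First eigenvector of an LD matrix
#'
#' Unit eigenvector of the largest eigenvalue, used downstream as the
#' random-effect loading that absorbs a gene's dominant LD structure.
#' Sign is fixed by making the largest-magnitude component positive; exact
#' eigenvalue ties are broken towards the eigenvector whose leading
#' component has the lowest index.
#'
#' @param ld_matrix symmetric matrix (finite entries).
#' @return unit-norm numeric vector.
#' @export
first_ld_eigenvector <- function(ld_matrix) {
  if (any(!is.finite(ld_matrix))) stop("LD matrix has non-finite entries")
  eg <- eigen(ld_matrix, symmetric = TRUE)
  tied <- which(eg$values >= eg$values[1] - 1e-12 * max(1, abs(eg$values[1])))
  lead <- vapply(tied, function(k) which.max(abs(eg$vectors[, k])), integer(1))
  v <- eg$vectors[, tied[which.min(lead)]]
  if (v[which.max(abs(v))] < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Greedy contiguous LD blocks
#'
#' Position-ordered SNPs are segmented greedily: the current block is
#' extended while the next SNP has r^2 at or above `r2_block` with any SNP
#' already in the block, otherwise a new block starts. Labels form a
#' partition, contiguous in position.
#'
#' @param ld_matrix pairwise r^2 matrix of position-ordered SNPs.
#' @param r2_block block-extension threshold (default 0.7).
#' @return integer block label per SNP (1-based, non-decreasing).
#' @export
define_ld_blocks <- function(ld_matrix, r2_block = 0.7) {
  m <- nrow(ld_matrix)
  if (m == 0) return(integer(0))
  lab <- integer(m)
  lab[1] <- 1L
  start <- 1L
  for (i in seq_len(m)[-1]) {
    if (max(ld_matrix[i, start:(i - 1)]) >= r2_block) {
      lab[i] <- lab[i - 1]
    } else {
      lab[i] <- lab[i - 1] + 1L
      start <- i
    }
  }
  lab
}
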