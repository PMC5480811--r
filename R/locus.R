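#' Resolve a gene's SNP set and LD summaries
#'
#' Implements the locus-definition rule: every SNP inside the gene
#' interval is included; flanking SNPs within `flank_bp` beyond either
#' gene end are included only when their r^2 with at least one genic SNP
#' exceeds `r2_link`. When an intergenic `index_snp` is supplied, that SNP
#' and its `flank_bp` neighbourhood SNPs with r^2 > `r2_link` *to the
#' index SNP* are unioned in. The gene ends anchor the flanks (a proxy for
#' UTR coordinates when only one interval per gene is annotated).
#'
#' @param panel a [haplotype_panel()].
#' @param gene_interval list or one-row data.frame with `gene`, `chrom`,
#'   `start`, `end` (1-based inclusive).
#' @param flank_bp flank width beyond the gene ends (default 5000).
#' @param r2_link LD threshold for flank/index linkage (default 0.7,
#'   strict inequality).
#' @param index_snp optional id of an intergenic index SNP.
#' @return a `gene_locus` list: `gene`, `chrom`, `start`, `end`,
#'   `snp_idx`, `snp_ids`, `n_genic`, `n_flank`, `ld` (r^2 matrix),
#'   `first_eigvec`, `blocks`, `index_snp`.
#' @export
extract_locus_snps <- function(panel, gene_interval, flank_bp = 5000,
                               r2_link = 0.7, index_snp = NULL) {
  gi <- as.list(gene_interval)
  pos <- panel$positions_bp
  genic <- which(pos >= gi$start & pos <= gi$end)
  if (!length(genic))
    stop("gene with zero panel SNPs: ", gi$gene)
  flank <- which((pos >= gi$start - flank_bp & pos < gi$start) |
                 (pos > gi$end & pos <= gi$end + flank_bp))
  seg <- minor_freq(panel) > 0
  flank <- flank[seg[flank]]
  keep_flank <- integer(0)
  if (length(flank)) {
    gseg <- genic[seg[genic]]
    if (length(gseg)) {
      r2 <- cor(panel$hap_matrix[, flank, drop = FALSE],
                panel$hap_matrix[, gseg, drop = FALSE])^2
      keep_flank <- flank[apply(r2, 1, max, na.rm = TRUE) > r2_link]
    }
  }
  idx <- sort(unique(c(genic, keep_flank)))
  if (!is.null(index_snp)) {
    ii <- resolve_snp(panel, index_snp)
    near <- which(abs(pos - pos[ii]) <= flank_bp & seg)
    near <- near[near != ii]
    link <- if (length(near) && seg[ii]) {
      r2i <- cor(panel$hap_matrix[, near, drop = FALSE],
                 panel$hap_matrix[, ii])^2
      near[as.numeric(r2i) > r2_link]
    } else integer(0)
    idx <- sort(unique(c(idx, ii, link)))
  }
  poly <- idx[seg[idx]]
  ld <- if (length(poly) >= 2)
    cor(panel$hap_matrix[, poly, drop = FALSE])^2 else
    matrix(1, length(poly), length(poly))
  structure(list(
    gene = gi$gene, chrom = gi$chrom, start = gi$start, end = gi$end,
    snp_idx = idx, snp_ids = panel$snp_ids[idx],
    n_genic = length(genic), n_flank = length(setdiff(idx, genic)),
    poly_idx = poly, ld = ld,
    first_eigvec = if (length(poly) >= 2) first_ld_eigenvector(ld) else
      rep(1, length(poly)),
    blocks = define_ld_blocks(ld),
    index_snp = index_snp), class = "gene_locus")
}

#' Draw length-matched random genes
#'
#' Samples `n` genes without replacement from `annotation`, each with bp
#' length within `length_tol` (relative) of the target locus, excluding
#' `exclude_genes`. If fewer than `n` candidates exist the tolerance is
#' doubled once before erroring.
#'
#' @param target_locus a `gene_locus` (or list with `start`, `end`).
#' @param annotation data.frame of genome genes (`gene`, `chrom`, `start`,
#'   `end`).
#' @param n number of genes to draw (default 100).
#' @param length_tol relative length tolerance (default 0.2).
#' @param seed integer seed.
#' @param exclude_genes gene names never drawn (e.g. the disease panel).
#' @return data.frame of the drawn gene intervals.
#' @export
match_random_genes <- function(target_locus, annotation, n = 100,
                               length_tol = 0.2, seed = 1,
                               exclude_genes = character(0)) {
  L <- target_locus$end - target_locus$start + 1
  len <- annotation$end - annotation$start + 1
  pool <- annotation[abs(len - L) <= length_tol * L &
                     !(annotation$gene %in% exclude_genes), ]
  if (nrow(pool) < n) {
    length_tol <- 2 * length_tol
    pool <- annotation[abs(len - L) <= length_tol * L &
                       !(annotation$gene %in% exclude_genes), ]
    if (nrow(pool) < n)
      stop("only ", nrow(pool), " length-matched genes available for n = ",
           n, " (after doubling tolerance)")
  }
  set.seed(seed)
  pool[sample.int(nrow(pool), n), , drop = FALSE]
}
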