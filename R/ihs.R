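#' Raw iHS scan
#'
#' Computes per-SNP integrated haplotype homozygosity for carriers of the
#' ancestral (iHH_A) and derived (iHH_D) core alleles and the raw
#' integrated haplotype score `ihs_raw = ln(iHH_A / iHH_D)`. SNPs with
#' minor allele frequency below `maf_min` (default 5%), SNPs whose EHH
#' is still at or above `cutoff` at a chromosome end, SNPs spanning a
#' physical gap larger than `max_gap_bp`, and SNPs with a zero-length
#' integral are flagged undefined with a reason code instead of a score.
#'
#' @param panel a QC'd [haplotype_panel()].
#' @param cutoff EHH cutoff for curve truncation and integration
#'   (default 0.05).
#' @param max_gap_bp maximum physical gap between adjacent markers
#'   (default 200 kb).
#' @param maf_min minor-allele-frequency exclusion threshold
#'   (default 0.05).
#' @return data.frame with columns `snp_id`, `chrom`, `pos`, `daf`,
#'   `ihh_a`, `ihh_d`, `ihs_raw`, `reason` ("ok", "maf", "chrom_end",
#'   "gap", "zero_ihh").
#' @export
ihs_scan <- function(panel, cutoff = 0.05, max_gap_bp = 2e5, maf_min = 0.05) {
  validate_panel(panel)
  if (anyNA(panel$hap_matrix))
    stop("ihs_scan requires complete haplotypes; apply QC first")
  res <- cpp_ihs_scan(panel$hap_matrix, panel$genetic_pos_cM,
                      as.numeric(panel$positions_bp), cutoff, max_gap_bp,
                      maf_min)
  reason <- c("ok", "maf", "chrom_end", "gap", "zero_ihh")[res$reason + 1L]
  data.frame(snp_id = panel$snp_ids, chrom = panel$chrom,
             pos = panel$positions_bp, daf = res$daf, ihh_a = res$ihh_a,
             ihh_d = res$ihh_d, ihs_raw = res$ihs_raw, reason = reason,
             stringsAsFactors = FALSE)
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' Within each DAF bin of width `bin_width`, subtracts the bin mean and
#' divides by the bin sample SD, emulating the empirical genome-wide
#' standardization of iHS against SNPs of similar derived allele
#' frequency; adds a two-sided standard-normal nominal p value. Bins with
#' fewer than 2 defined scores (or zero SD) have their scores flagged
#' undefined with reason "bin".
#'
#' When a `reference` score set is supplied (e.g. a genome-wide or
#' matched neutral scan), the bin means and SDs come from the reference
#' rather than from `scores` itself — the usual situation in a real scan,
#' where a locus is standardized against the genome-wide distribution in
#' which selected regions are a negligible fraction.
#'
#' @param scores output of [ihs_scan()].
#' @param bin_width DAF bin width (default 0.025).
#' @param reference optional [ihs_scan()] output supplying the bin
#'   means/SDs.
#' @return `scores` with added columns `daf_bin`, `ihs_std`, `nominal_p`.
#' @export
standardize_ihs <- function(scores, bin_width = 0.025, reference = NULL) {
  ok <- scores$reason == "ok" & !is.na(scores$ihs_raw)
  bin_of <- function(daf)
    as.integer(pmin(floor(daf / bin_width), floor(1 / bin_width) - 1e-9))
  scores$daf_bin <- bin_of(scores$daf)
  scores$ihs_std <- NA_real_
  scores$nominal_p <- NA_real_
  if (is.null(reference)) {
    ref_raw <- scores$ihs_raw
    ref_bin <- scores$daf_bin
    ref_ok <- ok
  } else {
    ref_raw <- reference$ihs_raw
    ref_bin <- bin_of(reference$daf)
    ref_ok <- reference$reason == "ok" & !is.na(reference$ihs_raw)
  }
  degenerate <- 0L
  for (b in unique(scores$daf_bin[ok])) {
    i <- which(ok & scores$daf_bin == b)
    r <- ref_raw[ref_ok & ref_bin == b]
    if (length(r) < 2 || sd(r) == 0) {
      scores$reason[i] <- "bin"
      degenerate <- degenerate + 1L
      next
    }
    scores$ihs_std[i] <- (scores$ihs_raw[i] - mean(r)) / sd(r)
  }
  if (degenerate)
    warning(degenerate, " DAF bin(s) with < 2 scores or zero spread; ",
            "their SNPs flagged undefined")
  def <- !is.na(scores$ihs_std)
  scores$nominal_p[def] <- 2 * pnorm(-abs(scores$ihs_std[def]))
  scores
}

#' Permutation p values for standardized iHS
#'
#' For each defined SNP, `n_perm` scores are drawn uniformly with
#' replacement from the genome-wide pool of standardized scores in the
#' same DAF class, and `permuted_p = (1 + #draws with |iHS| >= target) /
#' (n_perm + 1)`. Since draws are i.i.d., the count of exceedances is
#' drawn directly as Binomial(n_perm, pool exceedance fraction), which is
#' distributionally identical to looping over draws. DAF classes with
#' fewer than `min_class` SNPs are widened to their neighbours with a
#' warning. When `reference` (a standardized genome-wide scan) is given,
#' the score pool comes from the reference rather than from `scores`
#' itself.
#'
#' @param scores output of [standardize_ihs()].
#' @param n_perm number of permutation draws (default 10000).
#' @param seed integer seed.
#' @param min_class minimum DAF-class size before widening (default 10).
#' @param reference optional [standardize_ihs()] output supplying the
#'   genome-wide score pool.
#' @return `scores` with an added `permuted_p` column.
#' @export
permute_ihs_p <- function(scores, n_perm = 10000, seed = 1, min_class = 10,
                          reference = NULL) {
  if (is.null(scores$ihs_std)) stop("standardize_ihs must run first")
  if (is.null(reference)) reference <- scores
  if (is.null(reference$ihs_std)) stop("reference must be standardized")
  set.seed(seed)
  def <- which(!is.na(scores$ihs_std))
  rdef <- which(!is.na(reference$ihs_std))
  scores$permuted_p <- NA_real_
  abs_std <- abs(scores$ihs_std)
  rabs <- abs(reference$ihs_std)
  bins <- sort(unique(scores$daf_bin[def]))
  widened <- 0L
  for (b in bins) {
    tgt <- def[scores$daf_bin[def] == b]
    pool <- rabs[rdef[reference$daf_bin[rdef] == b]]
    w <- 0L
    while (length(pool) < min_class) {
      w <- w + 1L
      nb <- rdef[abs(reference$daf_bin[rdef] - b) <= w]
      pool <- rabs[nb]
      if (w > length(bins)) break
    }
    if (w > 0) widened <- widened + 1L
    spool <- sort(pool)
    m <- length(spool)
    if (m == 0) next
    # exceedance fraction by binary search over the sorted pool
    frac <- (m - findInterval(abs_std[tgt] - 1e-12, spool)) / m
    cnt <- rbinom(length(tgt), n_perm, frac)
    scores$permuted_p[tgt] <- (1 + cnt) / (n_perm + 1)
  }
  if (widened)
    warning(widened, " DAF class(es) below ", min_class,
            " SNPs widened to neighbours")
  scores
}

#' Call candidate selection signals within gene loci
#'
#' A SNP is a candidate when |standardized iHS| > `ihs_min`, its permuted
#' p value is below `p_max`, and at least `cluster_k` other SNPs within
#' `cluster_window_bp` also have |iHS| > `ihs_min` (the cluster rule).
#' Candidates inside a gene locus are grouped into signals by window
#' adjacency; each signal reports its apex (maximum |iHS|) SNP and a
#' magnitude class ("2-3", "3-4", ">4" by apex value).
#'
#' @param scores output of [permute_ihs_p()].
#' @param gene_loci list of [extract_locus_snps()] results (or any list
#'   with `gene` and `snp_ids` elements).
#' @param ihs_min |iHS| threshold (default 2).
#' @param p_max permuted-p threshold (default 0.05).
#' @param cluster_k required number of other elevated SNPs in the window
#'   (default 2).
#' @param cluster_window_bp cluster window (default 50 kb).
#' @param population label attached to the calls (default from scores).
#' @return data.frame of signals: `gene`, `population`, `signal`,
#'   `n_members`, `apex_snp`, `apex_ihs`, `permuted_p`, `magnitude_class`.
#' @export
call_candidate_signals <- function(scores, gene_loci, ihs_min = 2,
                                   p_max = 0.05, cluster_k = 2,
                                   cluster_window_bp = 5e4,
                                   population = "POP") {
  if (is.null(scores$permuted_p)) stop("permute_ihs_p must run first")
  elevated <- !is.na(scores$ihs_std) & abs(scores$ihs_std) > ihs_min
  pos <- scores$pos
  # cluster support: count of *other* elevated SNPs within the window
  ev_pos <- sort(pos[elevated])
  support <- findInterval(pos + cluster_window_bp, ev_pos) -
    findInterval(pos - cluster_window_bp - 1e-9, ev_pos) - elevated
  candidate <- elevated & scores$permuted_p < p_max & support >= cluster_k

  out <- list()
  for (locus in gene_loci) {
    idx <- which(candidate & scores$snp_id %in% locus$snp_ids)
    if (!length(idx)) next
    idx <- idx[order(pos[idx])]
    gap_new <- c(TRUE, diff(pos[idx]) > cluster_window_bp)
    sig_id <- cumsum(gap_new)
    for (s in unique(sig_id)) {
      mem <- idx[sig_id == s]
      apex <- mem[which.max(abs(scores$ihs_std[mem]))]
      av <- abs(scores$ihs_std[apex])
      out[[length(out) + 1L]] <- data.frame(
        gene = locus$gene, population = population, signal = s,
        n_members = length(mem), apex_snp = scores$snp_id[apex],
        apex_ihs = av, permuted_p = scores$permuted_p[apex],
        magnitude_class = if (av > 4) ">4" else if (av > 3) "3-4" else "2-3",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene = character(), population = character(),
                      signal = integer(), n_members = integer(),
                      apex_snp = character(), apex_ihs = numeric(),
                      permuted_p = numeric(), magnitude_class = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
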