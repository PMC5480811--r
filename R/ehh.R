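#' Extended haplotype homozygosity curve from a core SNP
#'
#' EHH at marker m is the probability that two randomly chosen haplotypes
#' carrying the core allele are identical over the interval from the core
#' to m: sum over distinct extended haplotypes h of C(n_h, 2) / C(n_c, 2).
#' The curve starts at (0 cM, 1) at the core and is returned out to the
#' first marker where EHH falls below `cutoff` (that marker included) or
#' the chromosome end. Computed by incremental prefix-partition refinement,
#' linear in markers; [ehh_curve_brute()] is the quadratic reference.
#'
#' @param panel a [haplotype_panel()].
#' @param core_snp SNP id or index of the core SNP.
#' @param core_allele `"ancestral"` or `"derived"`.
#' @param direction `"left"` or `"right"` along the chromosome.
#' @param cutoff EHH value below which the walk stops (default 0.05).
#' @return data.frame of class `ehh_curve` with columns `marker`
#'   (SNP index), `distance_cM`, `ehh`; attributes `core_snp`,
#'   `core_allele`, `direction`, `hit_end` (chromosome end reached with
#'   EHH still at or above `cutoff`).
#' @export
ehh_curve <- function(panel, core_snp, core_allele = c("derived", "ancestral"),
                      direction = c("right", "left"), cutoff = 0.05) {
  core_allele <- match.arg(core_allele)
  direction <- match.arg(direction)
  core <- resolve_snp(panel, core_snp)
  want <- if (core_allele == "derived") 1L else 0L
  carriers <- which(panel$hap_matrix[, core] == want)
  if (length(carriers) < 2)
    stop("EHH undefined: fewer than 2 carriers of the ", core_allele,
         " allele at ", panel$snp_ids[core])
  res <- cpp_ehh_curve(panel$hap_matrix, carriers - 1L, core - 1L,
                       if (direction == "right") 1L else -1L,
                       panel$genetic_pos_cM, cutoff)
  out <- data.frame(marker = res$marker + 1L,
                    distance_cM = res$distance_cM, ehh = res$ehh)
  structure(out, class = c("ehh_curve", "data.frame"),
            core_snp = panel$snp_ids[core], core_allele = core_allele,
            direction = direction, hit_end = res$hit_end,
            positions_bp = panel$positions_bp[out$marker])
}

#' Brute-force EHH curve (reference implementation)
#'
#' Enumerates all pairs of core-allele carriers and checks identity of the
#' full interval between core and marker. Exact but quadratic; used as the
#' oracle the optimized scan is tested against.
#'
#' @inheritParams ehh_curve
#' @return same shape as [ehh_curve()].
#' @export
ehh_curve_brute <- function(panel, core_snp,
                            core_allele = c("derived", "ancestral"),
                            direction = c("right", "left"), cutoff = 0.05) {
  core_allele <- match.arg(core_allele)
  direction <- match.arg(direction)
  core <- resolve_snp(panel, core_snp)
  want <- if (core_allele == "derived") 1L else 0L
  h <- panel$hap_matrix
  carriers <- which(h[, core] == want)
  nc <- length(carriers)
  if (nc < 2) stop("EHH undefined: fewer than 2 carriers")
  npair <- nc * (nc - 1) / 2
  step <- if (direction == "right") 1L else -1L
  m <- core
  out_m <- core; out_d <- 0; out_e <- 1
  hit_end <- FALSE
  e <- 1
  while (e >= cutoff) {
    m <- m + step
    if (m < 1L || m > ncol(h)) { hit_end <- TRUE; break }
    span <- if (step > 0) core:m else m:core
    ident <- 0L
    for (i in seq_len(nc - 1)) for (j in (i + 1):nc) {
      if (all(h[carriers[i], span] == h[carriers[j], span]))
        ident <- ident + 1L
    }
    e <- ident / npair
    out_m <- c(out_m, m)
    out_d <- c(out_d, abs(panel$genetic_pos_cM[m] - panel$genetic_pos_cM[core]))
    out_e <- c(out_e, e)
  }
  out <- data.frame(marker = out_m, distance_cM = out_d, ehh = out_e)
  structure(out, class = c("ehh_curve", "data.frame"),
            core_snp = panel$snp_ids[core], core_allele = core_allele,
            direction = direction, hit_end = hit_end,
            positions_bp = panel$positions_bp[out_m])
}

#' Integrate EHH curves into iHH
#'
#' Trapezoid integration of EHH over genetic distance, truncated at the
#' last marker with EHH at or above `cutoff` (no interpolation), summed
#' over the left and right curves. Returns `NA` (with a `reason`
#' attribute) when either direction reached the chromosome end with EHH
#' still at or above `cutoff`, or when adjacent markers are separated by
#' more than `max_gap_bp`.
#'
#' @param curve_left,curve_right [ehh_curve()] objects sharing the core
#'   SNP and allele.
#' @param cutoff integration cutoff (default 0.05).
#' @param max_gap_bp maximum tolerated physical gap between adjacent
#'   markers (default 200 kb).
#' @return iHH (non-negative), or `NA_real_` with attribute `reason` in
#'   `"chrom_end"` or `"gap"`.
#' @export
integrate_ihh <- function(curve_left, curve_right, cutoff = 0.05,
                          max_gap_bp = 2e5) {
  if (!identical(attr(curve_left, "core_snp"), attr(curve_right, "core_snp")) ||
      !identical(attr(curve_left, "core_allele"),
                 attr(curve_right, "core_allele")))
    stop("curves must share the core SNP and core allele")
  one <- function(cv) {
    if (nrow(cv) < 1) stop("empty EHH curve")
    if (isTRUE(attr(cv, "hit_end")))
      return(structure(NA_real_, reason = "chrom_end"))
    pos <- attr(cv, "positions_bp")
    acc <- 0
    if (nrow(cv) >= 2) for (i in 2:nrow(cv)) {
      if (abs(pos[i] - pos[i - 1]) > max_gap_bp)
        return(structure(NA_real_, reason = "gap"))
      if (cv$ehh[i] < cutoff) break
      acc <- acc + (cv$ehh[i] + cv$ehh[i - 1]) / 2 *
        (cv$distance_cM[i] - cv$distance_cM[i - 1])
    }
    acc
  }
  l <- one(curve_left)
  r <- one(curve_right)
  if (is.na(l)) return(l)
  if (is.na(r)) return(r)
  l + r
}

#' @noRd
resolve_snp <- function(panel, snp) {
  if (is.character(snp)) {
    i <- match(snp, panel$snp_ids)
    if (is.na(i)) stop("SNP not in panel: ", snp)
    i
  } else {
    i <- as.integer(snp)
    if (i < 1 || i > n_snps(panel)) stop("SNP index out of range: ", i)
    i
  }
}
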