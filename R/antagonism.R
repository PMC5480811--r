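#' Harmonize GWAS and fitness records onto one effect allele
#'
#' Re-signs the fitness (LRS) effect onto the GWAS effect allele. Allele
#' pairs compatible after swapping are sign-flipped; pairs compatible
#' after strand complementation are resolved by complementing; palindromic
#' A/T and C/G SNPs are strand-ambiguous and excluded (status
#' "palindromic") unless `allow_palindromic`.
#'
#' @param gwas_rec list/row with `snp_id`, `effect_allele`, `other_allele`,
#'   `ln_or`, `p`.
#' @param fitness_rec list/row with `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `p`.
#' @param allow_palindromic keep A/T, C/G SNPs (default FALSE).
#' @return list: `snp_id`, `effect_allele`, `cad_lnor`, `cad_p`,
#'   `lrs_beta`, `lrs_p`, `status` ("ok" or "palindromic").
#' @export
harmonize_alleles <- function(gwas_rec, fitness_rec,
                              allow_palindromic = FALSE) {
  g <- as.list(gwas_rec)
  f <- as.list(fitness_rec)
  if (!identical(as.character(g$snp_id), as.character(f$snp_id)))
    stop("records refer to different SNPs: ", g$snp_id, " vs ", f$snp_id)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  ga <- toupper(c(g$effect_allele, g$other_allele))
  fa <- toupper(c(f$effect_allele, f$other_allele))
  palindromic <- ga[1] == comp[ga[2]]
  if (palindromic && !allow_palindromic)
    return(list(snp_id = g$snp_id, effect_allele = ga[1],
                cad_lnor = NA_real_, cad_p = NA_real_, lrs_beta = NA_real_,
                lrs_p = NA_real_, status = "palindromic"))
  beta <- if (identical(fa, ga)) {
    f$beta
  } else if (identical(fa, rev(ga))) {
    -f$beta
  } else if (identical(unname(comp[fa]), ga)) {
    f$beta
  } else if (identical(unname(comp[fa]), rev(ga))) {
    -f$beta
  } else {
    stop("incompatible alleles for ", g$snp_id, ": ",
         paste(ga, collapse = "/"), " vs ", paste(fa, collapse = "/"))
  }
  list(snp_id = g$snp_id, effect_allele = ga[1], cad_lnor = g$ln_or,
       cad_p = g$p, lrs_beta = beta, lrs_p = f$p, status = "ok")
}

#' Classify antagonistic pleiotropy for one harmonized SNP
#'
#' A call is made only for SNPs that are genome-wide-significant disease
#' index SNPs (membership in `index_snps`) *and* significant for LRS
#' (`lrs_p < alpha`). The call is "antagonistic" when, for the shared
#' effect allele, the LRS effect and the disease log odds have the same
#' sign (the allele that raises fitness also raises risk), otherwise
#' "concordant". All other SNPs are "not_applicable".
#'
#' @param pair a [harmonize_alleles()] result.
#' @param index_snps character vector of genome-wide-significant index
#'   SNP ids.
#' @param alpha LRS significance threshold (default 0.05).
#' @return list: `snp_id`, `effect_allele`, `lrs_beta`, `lrs_p`,
#'   `cad_lnor`, `cad_p`, `both_significant`, `label`.
#' @export
classify_antagonism <- function(pair, index_snps, alpha = 0.05) {
  both <- !is.na(pair$lrs_p) && pair$status == "ok" &&
    pair$lrs_p < alpha && pair$snp_id %in% index_snps
  label <- if (!both) "not_applicable"
    else if (sign(pair$lrs_beta) == sign(pair$cad_lnor)) "antagonistic"
    else "concordant"
  list(snp_id = pair$snp_id, effect_allele = pair$effect_allele,
       lrs_beta = pair$lrs_beta, lrs_p = pair$lrs_p,
       cad_lnor = pair$cad_lnor, cad_p = pair$cad_p,
       both_significant = both, label = label)
}

#' Cross-reference GWAS index SNPs with fitness results
#'
#' Harmonizes and classifies every index SNP present in both tables.
#'
#' @param gwas GWAS summary data.frame (see [read_gwas_summary()]).
#' @param fitness data.frame with `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `nominal_p` (e.g. from [lmm_assoc()] joined
#'   with panel alleles).
#' @param index_snps genome-wide-significant index SNP ids.
#' @param alpha LRS significance threshold (default 0.05).
#' @return data.frame of [classify_antagonism()] calls.
#' @export
antagonism_calls <- function(gwas, fitness, index_snps, alpha = 0.05) {
  shared <- intersect(intersect(gwas$snp_id, fitness$snp_id), index_snps)
  rows <- lapply(shared, function(s) {
    g <- gwas[gwas$snp_id == s, ][1, ]
    f <- fitness[fitness$snp_id == s, ][1, ]
    pair <- harmonize_alleles(
      list(snp_id = s, effect_allele = g$effect_allele,
           other_allele = g$other_allele, ln_or = g$ln_or, p = g$p),
      list(snp_id = s, effect_allele = f$effect_allele,
           other_allele = f$other_allele, beta = f$beta, p = f$nominal_p))
    as.data.frame(classify_antagonism(pair, index_snps, alpha),
                  stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(snp_id = character(), effect_allele = character(),
                      lrs_beta = numeric(), lrs_p = numeric(),
                      cad_lnor = numeric(), cad_p = numeric(),
                      both_significant = logical(), label = character()))
  do.call(rbind, rows)
}

#' Expand an index SNP to its high-LD proxies
#'
#' Returns the index SNP plus every panel SNP within `window_bp` whose
#' r^2 with the index reaches `r2_min`.
#'
#' @param panel a [haplotype_panel()].
#' @param index_snp SNP id or index (must be in the panel).
#' @param r2_min proxy LD threshold (default 0.8, inclusive).
#' @param window_bp proxy window (default 1 Mb).
#' @return character vector of SNP ids, index SNP first.
#' @export
expand_proxies <- function(panel, index_snp, r2_min = 0.8,
                           window_bp = 1e6) {
  i <- resolve_snp(panel, index_snp)
  if (sd(panel$hap_matrix[, i]) == 0)
    stop("index SNP is monomorphic in the panel")
  near <- which(abs(panel$positions_bp - panel$positions_bp[i]) <= window_bp)
  near <- near[near != i]
  near <- near[apply(panel$hap_matrix[, near, drop = FALSE], 2, sd) > 0]
  keep <- if (length(near)) {
    r2 <- as.numeric(cor(panel$hap_matrix[, near, drop = FALSE],
                         panel$hap_matrix[, i])^2)
    near[r2 >= r2_min]
  } else integer(0)
  c(panel$snp_ids[i], panel$snp_ids[sort(keep)])
}
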